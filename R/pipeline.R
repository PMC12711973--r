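# Orchestration of the two-phase framework: sweep the robustness
# parameter alpha and the patient-mix weights beta over a grid, solve the
# advance stage per specialty and the allocation stage per block, and
# select the configuration minimizing the overall objective
#   Z = (scheduling costs of unscheduled patients)
#     + sum over blocks of the expected recourse cost.

#' Overall objective of a complete surgical schedule
#'
#' @param advance_solutions List of `advance_solution` objects (one per
#'   specialty) from [solve_advance_all()].
#' @param allocation_reports Named list, keyed by `block_key(or, day)`,
#'   of `allocation_solution` objects or plain expected costs, covering
#'   at least every block that received patients.
#' @return `Z` in cost units.
#' @export
overall_Z <- function(advance_solutions, allocation_reports) {
  unsched <- sum(vapply(advance_solutions,
                        function(s) s$unsched_cost, numeric(1)))
  covered <- names(allocation_reports)
  for (s in advance_solutions) {
    if (is.null(s$assignment) || !nrow(s$assignment)) next
    need <- unique(block_key(s$assignment$or_id, s$assignment$day))
    miss <- setdiff(need, covered)
    if (length(miss))
      stop("allocation report missing for block(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  costs <- vapply(allocation_reports, function(r)
    if (is.numeric(r)) r else r$expected_cost, numeric(1))
  unsched + sum(costs)
}

#' Inpatient/outpatient mix metrics of an advance schedule
#'
#' Per-block Gini impurity `GI = 1 - (n_in/|I|)^2 - (n_out/|I|)^2`
#' (0 = single-class block, 0.5 = perfectly mixed), its average over
#' non-empty blocks, the upper bound `GI_max = 1 - f_in^2 - f_out^2`
#' attained when every block mirrors the overall scheduled class shares,
#' and the normalized index `GI_hat = GI_avg / GI_max`.
#'
#' @param advance_solutions One `advance_solution` or a list of them.
#' @param patients The instance waiting list.
#' @return List with `f_in`, `f_out`, `gi_blocks` (named per block),
#'   `gi_avg`, `gi_max`, `gi_hat`.
#' @export
mix_metrics <- function(advance_solutions, patients) {
  if (inherits(advance_solutions, "advance_solution"))
    advance_solutions <- list(advance_solutions)
  asg <- do.call(rbind, lapply(advance_solutions, function(s) s$assignment))
  if (is.null(asg) || !nrow(asg))
    return(list(f_in = NA_real_, f_out = NA_real_, gi_blocks = numeric(0),
                gi_avg = NA_real_, gi_max = NA_real_, gi_hat = NA_real_))
  type <- patients$patient_type[match(asg$patient_id, patients$id)]
  f_in <- mean(type == "inpatient")
  f_out <- 1 - f_in
  key <- block_key(asg$or_id, asg$day)
  gi <- vapply(split(type, key), function(tt) {
    1 - mean(tt == "inpatient")^2 - mean(tt == "outpatient")^2
  }, numeric(1))
  gi_max <- 1 - f_in^2 - f_out^2
  list(f_in = f_in, f_out = f_out, gi_blocks = gi, gi_avg = mean(gi),
       gi_max = gi_max,
       gi_hat = if (gi_max > 0) mean(gi) / gi_max else NA_real_)
}

#' Solve the allocation stage for every block of an advance schedule
#'
#' Method per block: the configured [allocation_config()] method, or
#' `"auto"` (the default policy: N-fold SAA for blocks with at most
#' `saa_max_patients` patients, BRKGA for larger ones).
#'
#' @param advance_solutions List of `advance_solution` objects.
#' @param instance An `or_instance`.
#' @param sample Full `scenario_sample` (fitness, folds and the reported
#'   expected costs all derive from it).
#' @param alloc An [allocation_config()] or the string `"auto"`.
#' @param brkga A [brkga_config()].
#' @param saa_max_patients Size threshold of the auto policy (default 6).
#' @return Named list (block key) of `allocation_solution` objects; every
#'   MSS block appears, empty blocks with a zero-patient schedule.
#' @export
allocate_blocks <- function(advance_solutions, instance, sample,
                            alloc = "auto", brkga = brkga_config(),
                            saa_max_patients = 6) {
  by_block <- assignment_by_block(advance_solutions, instance)
  mss <- instance$mss
  keys <- block_key(mss$or_id, mss$day)
  out <- list()
  for (b in seq_len(nrow(mss))) {
    key <- keys[b]
    patients <- by_block[[key]]
    if (is.null(patients) || !nrow(patients)) {
      sched <- block_schedule(mss[b, ], instance$waiting_list[0, ],
                              numeric(0))
      out[[key]] <- structure(
        list(schedule = sched,
             expected_cost = expected_cost(sched, sample,
                                           instance$config),
             objective = NA_real_, gap = NA_real_, status = "optimal",
             method = "empty"),
        class = "allocation_solution")
      next
    }
    method <- if (identical(alloc, "auto")) {
      if (nrow(patients) <= saa_max_patients) "nfold" else "brkga"
    } else alloc$method
    out[[key]] <- switch(
      method,
      saa = solve_saa(mss[b, ], patients, sample, instance$config,
                      if (identical(alloc, "auto"))
                        allocation_config("saa") else alloc),
      nfold = solve_nfold_saa(mss[b, ], patients, sample,
                              instance$config,
                              if (identical(alloc, "auto"))
                                allocation_config("nfold") else alloc),
      brkga = brkga_evolve(mss[b, ], patients, sample, instance$config,
                           brkga),
      stop("unknown allocation method: ", method, call. = FALSE))
  }
  out
}

#' Sweep the (alpha, beta) configuration grid
#'
#' For each configuration: solve the advance stage per specialty on the
#' shared training sample, solve the allocation stage per block, and
#' assemble `Z`.  Failures in a configuration are recorded and the sweep
#' continues.  The default grid is `alpha in {0.05, 0.10, 0.15}` crossed
#' with the three unit beta vectors (IDs A1..C3).
#'
#' @param instance An `or_instance`.
#' @param alphas Numeric vector of robustness levels.
#' @param betas List of length-3 weight vectors.
#' @param sample_size Scenario sample size shared by all stages.
#' @param seed Integer master seed.
#' @param advance_time_limit,alloc_time_limit Solver budgets (seconds).
#' @param alloc `"auto"` or an [allocation_config()].
#' @param brkga A [brkga_config()].
#' @return A `sweep_result`: `records` data.frame (one row per
#'   configuration with the five cost components and `Z`), `details`
#'   (advance + allocation solutions), `best` (index of the minimal-`Z`
#'   configuration), `sample_size`, `seed`.
#' @export
run_sweep <- function(instance,
                      alphas = c(0.05, 0.10, 0.15),
                      betas = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      sample_size = 1000, seed = 1,
                      advance_time_limit = 300, alloc_time_limit = 300,
                      alloc = "auto", brkga = brkga_config(seed = seed)) {
  if (!length(alphas) || !length(betas))
    stop("alphas and betas must be nonempty", call. = FALSE)
  sample <- sample_scenarios(instance, sample_size, seed)
  grid <- expand.grid(bi = seq_along(betas), alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  records <- NULL; details <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    alpha <- grid$alpha[g]; beta <- betas[[grid$bi[g]]]
    rec <- data.frame(alpha = alpha,
                      beta = paste(beta, collapse = ","),
                      advance_objective = NA_real_, sched_cost = NA_real_,
                      canc_cost = NA_real_, wait_cost = NA_real_,
                      idle_cost = NA_real_, over_cost = NA_real_,
                      Z = NA_real_, status = "failed")
    res <- tryCatch({
      acfg <- advance_config(alpha = alpha, beta = beta,
                             cc_sample_size = sample_size,
                             time_limit = advance_time_limit)
      adv <- solve_advance_all(instance, acfg, sample)
      if (identical(alloc, "auto")) {
        al <- allocation_config("nfold", time_limit = alloc_time_limit)
      } else al <- alloc
      allocs <- allocate_blocks(adv, instance, sample,
                                alloc = if (identical(alloc, "auto"))
                                  "auto" else al,
                                brkga = brkga)
      comp <- vapply(allocs, function(r) {
        res_b <- evaluate_block_sample(r$schedule, sample,
                                       instance$config)
        c(canc = mean(res_b$canc_cost), wait = mean(res_b$wait_cost),
          idle = mean(res_b$idle_cost), over = mean(res_b$over_cost))
      }, numeric(4))
      rec$advance_objective <- sum(vapply(adv, `[[`, numeric(1),
                                          "objective"))
      rec$sched_cost <- sum(vapply(adv, `[[`, numeric(1), "unsched_cost"))
      rec$canc_cost <- sum(comp["canc", ])
      rec$wait_cost <- sum(comp["wait", ])
      rec$idle_cost <- sum(comp["idle", ])
      rec$over_cost <- sum(comp["over", ])
      rec$Z <- overall_Z(adv, allocs)
      rec$status <- "ok"
      list(advance = adv, allocations = allocs)
    }, error = function(e) {
      rec$status <<- paste0("failed: ", conditionMessage(e))
      NULL
    })
    records <- rbind(records, rec)
    details[[g]] <- res
  }
  ok <- which(records$status == "ok")
  best <- if (length(ok)) ok[which.min(records$Z[ok])] else NA_integer_
  structure(list(records = records, details = details, best = best,
                 sample_size = sample_size, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result over", nrow(x$records), "configurations\n")
  print(x$records[, c("alpha", "beta", "sched_cost", "Z", "status")])
  if (!is.na(x$best))
    cat(sprintf("best: alpha = %g, beta = (%s), Z = %.4f\n",
                x$records$alpha[x$best], x$records$beta[x$best],
                x$records$Z[x$best]))
  invisible(x)
}

#' Write a sweep report
#'
#' Writes `<stem>.csv` with columns `alpha, beta, sched_cost, canc_cost,
#' wait_cost, idle_cost, over_cost, Z, best` (the cost decomposition of
#' every configuration, best row flagged) and `<stem>.json` with a
#' machine-readable summary.
#'
#' @param sweep A `sweep_result`.
#' @param stem Output path stem.
#' @export
report_sweep <- function(sweep, stem) {
  r <- sweep$records
  out <- data.frame(alpha = r$alpha, beta = r$beta,
                    sched_cost = r$sched_cost, canc_cost = r$canc_cost,
                    wait_cost = r$wait_cost, idle_cost = r$idle_cost,
                    over_cost = r$over_cost, Z = r$Z,
                    best = seq_len(nrow(r)) == sweep$best)
  utils::write.csv(out, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(records = out,
         best = if (is.na(sweep$best)) NULL else
           as.list(out[sweep$best, c("alpha", "beta", "Z")]),
         sample_size = sweep$sample_size, seed = sweep$seed),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
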