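# Discrete-event evaluation of a complete weekly schedule.  Bernoulli
# mode draws at most one emergency per block (the modeling assumption)
# and reuses the recourse kernel scenario-for-scenario; Poisson mode
# relaxes the assumption, drawing a Poisson number of emergencies per
# block with the same mean and inserting each as soon as possible in
# arrival order (FIFO at the assigned OR).  Electives follow the same
# real-time policies in both modes.

#' Evaluate a weekly schedule by simulation
#'
#' @param schedules Named list of [block_schedule()] objects, keyed by
#'   `block_key(or, day)` (as produced by [allocate_blocks()] /
#'   [run_sweep()]).  MSS blocks without an entry are simulated empty
#'   (idle plus any emergency work).
#' @param instance An `or_instance`.
#' @param n Number of scenarios.
#' @param mode `"bernoulli"` or `"poisson"`.
#' @param seed Integer seed; elective realizations are shared between the
#'   two modes under the same seed, so comparisons are paired.
#' @return An `evaluation_report`: mean per-block cost components
#'   (`over_cost`, `idle_cost`, `canc_cost`, `wait_cost`), their sum
#'   `objective`, `mean_emergency_wait` (minutes), per-class summaries
#'   (see [class_metrics()]), `per_block` data.frame, `per_scenario`
#'   (block-averaged cost of each scenario, for paired comparisons),
#'   `n_scenarios`, `mode`.
#' @export
evaluate_schedule <- function(schedules, instance, n, mode = "bernoulli",
                              seed = 1) {
  if (!mode %in% c("bernoulli", "poisson"))
    stop("unknown mode: ", mode, call. = FALSE)
  mss <- instance$mss
  cfg <- instance$config
  sample <- sample_scenarios(instance, n, seed)
  keys <- block_key(mss$or_id, mss$day)
  comp <- matrix(0, nrow(mss), 4,
                 dimnames = list(keys, c("over_cost", "idle_cost",
                                         "canc_cost", "wait_cost")))
  scen_tot <- numeric(n)       # per-scenario block-average cost
  em_wait_sum <- 0; em_wait_n <- 0L
  per_patient <- list()
  for (b in seq_len(nrow(mss))) {
    key <- keys[b]
    sched <- schedules[[key]]
    if (is.null(sched))
      sched <- block_schedule(mss[b, ], instance$waiting_list[0, ], numeric(0))
    if (mode == "poisson") {
      pe <- sample_poisson_emergencies(instance, mss[b, ], n, seed)
      res <- evaluate_block_sample(sched, sample, cfg,
                                   em_arr = pe$arrival, em_dur = pe$duration)
    } else {
      res <- evaluate_block_sample(sched, sample, cfg)
    }
    comp[b, ] <- c(mean(res$over_cost), mean(res$idle_cost),
                   mean(res$canc_cost), mean(res$wait_cost))
    scen_tot <- scen_tot + res$cost / nrow(mss)
    waits <- res$em_wait[!is.na(res$em_wait)]
    em_wait_sum <- em_wait_sum + sum(waits)
    em_wait_n <- em_wait_n + length(waits)
    np <- nrow(sched$patients)
    if (np) {
      present <- sample$theta[, as.character(sched$patients$id),
                              drop = FALSE] == 1
      per_patient[[key]] <- data.frame(
        patient_type = rep(sched$patients$patient_type, each = n),
        scheduled_start = rep(sched$start_times, each = n),
        waiting = as.vector(res$a),
        cancelled = as.integer(as.vector(res$y) == 0),
        present = as.integer(as.vector(present)))
    }
  }
  means <- colMeans(comp)
  pp <- if (length(per_patient)) do.call(rbind, per_patient) else NULL
  structure(list(over_cost = means[["over_cost"]],
                 idle_cost = means[["idle_cost"]],
                 canc_cost = means[["canc_cost"]],
                 wait_cost = means[["wait_cost"]],
                 objective = sum(means),
                 mean_emergency_wait = if (em_wait_n) em_wait_sum / em_wait_n
                                       else NA_real_,
                 class_summary = if (!is.null(pp)) class_metrics(pp)
                                 else NULL,
                 per_block = data.frame(block = keys, comp,
                                        row.names = NULL),
                 per_scenario = scen_tot,
                 n_scenarios = n, mode = mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s, %d scenarios)\n", x$mode,
              x$n_scenarios))
  cat(sprintf("  o.f. %.4f = over %.4f + idle %.4f + canc %.4f + wait %.4f\n",
              x$objective, x$over_cost, x$idle_cost, x$canc_cost,
              x$wait_cost))
  cat(sprintf("  mean emergency wait: %.2f min\n", x$mean_emergency_wait))
  invisible(x)
}

#' Per-class (inpatient/outpatient) schedule metrics
#'
#' Summarizes realized outcomes by patient class: mean scheduled start
#' time, mean direct waiting time of executed surgeries, and cancellation
#' probability (cancellations among present patients).
#'
#' @param per_patient A data.frame with one row per (patient, scenario)
#'   and columns `patient_type`, `scheduled_start`, `waiting`,
#'   `cancelled` (0/1), `present` (0/1).
#' @return A data.frame with one row per class (`inpatient`,
#'   `outpatient`); classes with no patients carry NA and `n = 0`.
#' @export
class_metrics <- function(per_patient) {
  out <- lapply(c("inpatient", "outpatient"), function(cl) {
    d <- per_patient[per_patient$patient_type == cl, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(class = cl, n = 0L,
                        mean_scheduled_start = NA_real_,
                        mean_waiting = NA_real_,
                        cancellation_probability = NA_real_))
    pres <- d$present == 1
    data.frame(class = cl, n = nrow(d),
               mean_scheduled_start = mean(d$scheduled_start),
               mean_waiting = mean(d$waiting),
               cancellation_probability = if (any(pres))
                 mean(d$cancelled[pres]) else NA_real_)
  })
  do.call(rbind, out)
}
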