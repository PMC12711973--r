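# Allocation scheduling (sequencing + timing) for one OR block: a
# two-stage stochastic MILP in extensive form.  First stage: immediate-
# successor binaries o[i, i'] and scheduled start times t[i].  Second
# stage, one copy per scenario: the realized timeline under the real-time
# policies, linearized so that for a fixed first stage every recourse
# variable is pinned to the value the algorithmic simulation computes
# (the two routes are cross-checked in the test suite).
#
# Linearization notes (all big-M constants are per-scenario horizon
# bounds, M = L + H + sum(rho * theta) + delta + tau):
#  * actual/auxiliary start q = max(completion of predecessor, t): the
#    lower side uses indicator-to-big-M on o, the upper side one extra
#    binary per (patient, scenario) selecting which branch of the max
#    binds;
#  * cancellation iff expected completion exceeds L + H: two-sided big-M
#    with a strict-inequality epsilon on the cancel side;
#  * emergency insertion point: located on the auxiliary (emergency-free)
#    timeline, whose prefix equals the actual one up to the insertion;
#  * emergency start idle-vs-busy case split: one binary per scenario
#    comparing the arrival with the predecessor's auxiliary completion.

EPS_CANCEL <- 1e-6  # strictness margin of the cancellation inequality

#' Configuration of the allocation stage
#'
#' @param method `"saa"` (single sample average approximation MILP),
#'   `"nfold"` (solve on N disjoint folds, re-evaluate each incumbent on
#'   the full sample via the algorithmic recourse, keep the best) or
#'   `"brkga"` (genetic algorithm, see [brkga_config()]).
#' @param N Number of folds for `"nfold"` (default 10).
#' @param time_limit Total solver budget per block in seconds (default
#'   300); split evenly across folds for `"nfold"`.
#' @param mip_rel_gap Relative MIP gap tolerance (default 1e-6).
#' @return Object of class `allocation_config`.
#' @export
allocation_config <- function(method = c("nfold", "saa", "brkga"), N = 10,
                              time_limit = 300, mip_rel_gap = 1e-6) {
  method <- match.arg(method)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  structure(list(method = method, N = as.integer(N),
                 time_limit = time_limit, mip_rel_gap = mip_rel_gap),
            class = "allocation_config")
}

# Per-block scenario constants used by the extensive form.
block_scenario_data <- function(block, patients, sample) {
  sl <- schedule_scenario_slices(
    structure(list(block = as.list(block), patients = patients),
              class = "block_schedule"),
    sample)
  list(rt = sl$rho * sl$theta, theta = sl$theta,
       delta = ifelse(is.na(sl$em_dur[, 1]), 0, sl$em_dur[, 1]),
       tau = ifelse(is.na(sl$em_arr[, 1]), 0, sl$em_arr[, 1]))
}

#' Build the extensive-form SAA MILP for one block
#'
#' @param block One MSS row.
#' @param patients Waiting-list rows assigned to the block.
#' @param sample A `scenario_sample`.
#' @param config Instance configuration (idle/overtime costs).
#' @param fixed Optional list `(order, start_times)` fixing the first
#'   stage (`order` = patient ids in sequence); used for oracle checks.
#' @return List with the `milp_model` and decode bookkeeping.
#' @keywords internal
build_saa_milp <- function(block, patients, sample, config,
                           fixed = NULL) {
  n <- nrow(patients); S <- sample$size
  stopifnot(n >= 1)
  L <- block$length; H <- block$max_overtime
  sd <- block_scenario_data(block, patients, sample)
  mu <- patients$mu
  if (sum(mu) > L + 1e-9)
    stop("assigned EOTs exceed block length", call. = FALSE)
  m <- milp_new()

  # ---- first stage ----
  t <- milp_add_vars(m, n, lb = 0, ub = pmax(0, L - mu))
  o <- matrix(0L, n, n)   # o[i, ip] = 1 iff ip immediately follows i
  if (n > 1) {
    for (i in seq_len(n)) for (ip in seq_len(n)) if (i != ip)
      o[i, ip] <- milp_add_vars(m, 1, lb = 0, ub = 1, integer = TRUE)
    for (i in seq_len(n)) {
      pred <- o[-i, i]
      # t_i <= (L - mu_i) * sum(pred): first in sequence starts at 0
      milp_add_con(m, c(t[i], pred), c(1, rep(-(L - mu[i]), n - 1)), ub = 0)
      milp_add_con(m, o[i, -i], rep(1, n - 1), ub = 1)   # out-degree
      milp_add_con(m, o[-i, i], rep(1, n - 1), ub = 1)   # in-degree
      for (ip in seq_len(n)) if (i != ip)
        # t_i + mu_i <= t_ip + (1 - o) * L
        milp_add_con(m, c(t[i], t[ip], o[i, ip]), c(1, -1, L),
                     ub = L - mu[i])
    }
    milp_add_con(m, o[o > 0], rep(1, n * (n - 1)), lb = n - 1, ub = n - 1)
  } else {
    milp_add_con(m, t[1], 1, ub = 0)
  }
  if (!is.null(fixed)) {
    pos <- match(fixed$order, patients$id)
    stopifnot(!anyNA(pos), length(pos) == n)
    tv <- numeric(n); tv[pos] <- fixed$start_times
    for (i in seq_len(n))
      milp_add_con(m, t[i], 1, lb = tv[i], ub = tv[i])
    if (n > 1) {
      ov <- matrix(0, n, n)
      for (k in seq_len(n - 1)) ov[pos[k], pos[k + 1]] <- 1
      for (i in seq_len(n)) for (ip in seq_len(n)) if (i != ip)
        milp_add_con(m, o[i, ip], 1, lb = ov[i, ip], ub = ov[i, ip])
    }
  }

  # ---- second stage, one copy per scenario ----
  for (w in seq_len(S)) {
    rt <- sd$rt[w, ]; th <- sd$theta[w, ]
    delta <- sd$delta[w]; tau <- sd$tau[w]
    em <- delta > 0
    M <- L + H + sum(rt) + delta + tau + 1
    wgt <- 1 / S

    q <- milp_add_vars(m, n, lb = 0, ub = M)
    # actual-timeline starts: separate copies only needed with emergency
    qh <- if (em) milp_add_vars(m, n, lb = 0, ub = M) else q
    y <- milp_add_vars(m, n, lb = 0, ub = 1, integer = TRUE,
                       obj = -patients$c_canc * wgt)
    const_w <- sum(patients$c_canc) * wgt   # from c_canc * (1 - y)
    a <- milp_add_vars(m, n, lb = 0, ub = M, obj = patients$c_wait * wgt)
    hh <- milp_add_vars(m, 1, lb = 0, obj = config$c_over * wgt)
    gg <- milp_add_vars(m, 1, lb = 0, obj = config$c_idle * wgt)
    CC <- milp_add_vars(m, 1, lb = 0, ub = M)
    wq <- milp_add_vars(m, n, lb = 0, ub = 1, integer = TRUE)
    wqh <- if (em) milp_add_vars(m, n, lb = 0, ub = 1, integer = TRUE)
           else wq
    if (em) {
      e <- milp_add_vars(m, n, lb = 0, ub = 1, integer = TRUE)
      z <- milp_add_vars(m, n, lb = 0, ub = M)
      v <- milp_add_vars(m, n, lb = 0, ub = 1, integer = TRUE)
    }

    for (i in seq_len(n)) {
      if (th[i] == 0) {
        # no-show can never be cancelled
        milp_add_con(m, y[i], 1, lb = 1, ub = 1)
      } else {
        # cancel iff expected completion q̂ + mu exceeds L + H (strictly)
        milp_add_con(m, c(qh[i], y[i]), c(1, M), ub = L + H - mu[i] + M)
        milp_add_con(m, c(qh[i], y[i]), c(1, M),
                     lb = L + H + EPS_CANCEL - mu[i])
        # waiting of executed patients: a >= q̂ - t - M(1 - y)
        milp_add_con(m, c(a[i], qh[i], t[i], y[i]), c(1, -1, 1, -M),
                     lb = -M)
      }
      # no anticipation; first in sequence pinned to 0
      milp_add_con(m, c(q[i], t[i]), c(1, -1), lb = 0)
      if (em) milp_add_con(m, c(qh[i], t[i]), c(1, -1), lb = 0)
      if (n == 1) {
        milp_add_con(m, q[i], 1, ub = 0)     # single surgery starts at 0
        if (em) milp_add_con(m, qh[i], 1, ub = 0)
      }
      if (n > 1) {
        pred <- o[-i, i]
        milp_add_con(m, c(q[i], pred), c(1, rep(-M, n - 1)), ub = 0)
        if (em)
          milp_add_con(m, c(qh[i], pred), c(1, rep(-M, n - 1)), ub = 0)
        # q_i <= t_i when wq = 1
        milp_add_con(m, c(q[i], t[i], wq[i]), c(1, -1, M), ub = M)
        if (em)
          milp_add_con(m, c(qh[i], t[i], wqh[i]), c(1, -1, M), ub = M)
      }
      # C >= q̂ + rho y + z + delta e - (1 - y) M   (present patients)
      if (th[i] == 1) {
        ind <- c(CC, qh[i], y[i])
        cf <- c(1, -1, -sd$rt[w, i] - M)
        if (em) { ind <- c(ind, z[i], e[i]); cf <- c(cf, -1, -delta) }
        milp_add_con(m, ind, cf, lb = -M)
      } else if (em) {
        milp_add_con(m, c(CC, z[i], e[i]), c(1, -1, -delta), lb = 0)
      }
    }
    # chaining between consecutive surgeries
    if (n > 1) {
      for (i in seq_len(n)) for (ip in seq_len(n)) {
        if (i == ip) next
        # auxiliary: q_ip >= q_i + rt_i y_i - M (1 - o)
        milp_add_con(m, c(q[ip], q[i], y[i], o[i, ip]),
                     c(1, -1, -rt[i], -M), lb = -M)
        # auxiliary upper: q_ip <= q_i + rt y + M (1 - o) + M wq_ip
        milp_add_con(m, c(q[ip], q[i], y[i], o[i, ip], wq[ip]),
                     c(1, -1, -rt[i], M, -M), ub = M)
        if (em) {
          # actual: q̂_ip >= q̂_i + rt y + z + delta e - M (1 - o)
          milp_add_con(m, c(qh[ip], qh[i], y[i], z[i], e[i], o[i, ip]),
                       c(1, -1, -rt[i], -1, -delta, -M), lb = -M)
          milp_add_con(m, c(qh[ip], qh[i], y[i], z[i], e[i], o[i, ip],
                            wqh[ip]),
                       c(1, -1, -rt[i], -1, -delta, M, -M), ub = M)
          # insertion interval on the auxiliary timeline:
          # e_i = 1 and o_iip = 1  =>  tau <= q_ip
          milp_add_con(m, c(q[ip], e[i], o[i, ip]), c(1, -M, -M),
                       lb = tau - 2 * M)
        }
      }
    }
    if (em) {
      milp_add_con(m, e, rep(1, n), lb = 1, ub = 1)         # insert once
      milp_add_con(m, c(CC), 1, lb = tau + delta)           # em completion
      for (i in seq_len(n)) {
        milp_add_con(m, c(q[i], e[i]), c(1, M), ub = tau + M) # q_i <= tau
        milp_add_con(m, c(z[i], e[i]), c(1, -M), ub = 0)      # z <= M e
        # z pinned to max(0, tau - (q_i + rt y_i)) when e_i = 1:
        milp_add_con(m, c(z[i], q[i], y[i], e[i]), c(1, 1, rt[i], -M),
                     lb = tau - M)
        milp_add_con(m, c(z[i], q[i], y[i], e[i], v[i]),
                     c(1, 1, rt[i], M, M), ub = tau + 2 * M)
        milp_add_con(m, c(z[i], v[i]), c(1, -M), ub = 0)
        # v = 1 iff OR idle at arrival: q_i + rt y_i <= tau
        milp_add_con(m, c(q[i], y[i], v[i]), c(1, rt[i], M), ub = tau + M)
        milp_add_con(m, c(q[i], y[i], v[i]), c(1, rt[i], M), lb = tau)
      }
    }
    # overtime and idle
    milp_add_con(m, c(hh, CC), c(1, -1), lb = -L)
    milp_add_con(m, c(gg, y), c(1, rt), lb = L - delta)
    milp_add_con(m, c(gg, CC, y), c(1, -1, rt), lb = -delta)

    m$const <- (if (is.null(m$const)) 0 else m$const) + const_w
  }
  list(model = m, t = t, o = o, n = n, const = m$const)
}

# Decode first-stage variables into a block_schedule.
decode_first_stage <- function(xsol, built, block, patients) {
  n <- built$n
  tv <- xsol[built$t]
  if (n == 1) {
    ord <- 1L
  } else {
    ov <- matrix(0, n, n)
    ov[built$o > 0] <- round(xsol[built$o[built$o > 0]])
    succ <- apply(ov, 1, function(r) { j <- which(r == 1); if (length(j)) j else NA })
    first <- which(colSums(ov) == 0)
    if (length(first) != 1) first <- order(tv)[1]  # numeric safety net
    ord <- integer(n); ord[1] <- first
    for (k in seq_len(n - 1)) ord[k + 1] <- succ[ord[k]]
  }
  tt <- tv[ord]
  tt[1] <- 0
  if (n > 1) {   # snap solver round-off onto a feasible timing vector
    mu <- patients$mu[ord]
    for (k in 2:n) tt[k] <- max(tt[k], tt[k - 1] + mu[k - 1])
    tt <- pmin(tt, block$length - mu)
    for (k in 2:n) tt[k] <- max(tt[k], tt[k - 1] + mu[k - 1])
  }
  block_schedule(block, patients[ord, , drop = FALSE], tt)
}

#' Solve the allocation SMIP for one block by SAA
#'
#' Builds the extensive-form MILP on the given sample, solves it within
#' the time budget, decodes the incumbent into a [block_schedule()] and
#' re-evaluates its expected cost on `eval_sample` (defaults to the
#' training sample) with the algorithmic recourse.
#'
#' @param block One MSS row.
#' @param patients Waiting-list rows assigned to the block.
#' @param sample Training `scenario_sample`.
#' @param config Instance configuration (costs).
#' @param alloc An [allocation_config()].
#' @param eval_sample Sample for the reported expected cost (default
#'   `sample`).
#' @return An `allocation_solution`: `schedule`, `expected_cost`,
#'   `objective` (SAA objective of the incumbent), `gap`, `status`
#'   (`optimal`, `feasible` or `infeasible_within_limit`), `method`.
#' @export
solve_saa <- function(block, patients, sample, config,
                      alloc = allocation_config("saa"),
                      eval_sample = sample) {
  built <- build_saa_milp(block, patients, sample, config)
  res <- milp_solve(built$model, time_limit = alloc$time_limit,
                    mip_rel_gap = alloc$mip_rel_gap)
  if (is.null(res$x))
    return(structure(list(schedule = NULL, expected_cost = NA_real_,
                          objective = NA_real_, gap = NA_real_,
                          status = "infeasible_within_limit",
                          method = "saa"),
                     class = "allocation_solution"))
  schedule <- decode_first_stage(res$x, built, block, patients)
  structure(list(schedule = schedule,
                 expected_cost = expected_cost(schedule, eval_sample,
                                               config),
                 objective = res$objective + built$const,
                 gap = res$gap,
                 status = if (res$status == "optimal") "optimal"
                          else "feasible",
                 method = "saa"),
            class = "allocation_solution")
}

#' Solve the allocation SMIP for one block by N-fold SAA
#'
#' Partitions the sample into `N` folds, solves the SAA MILP on each fold
#' with budget `time_limit / N`, re-evaluates every fold incumbent on the
#' entire sample via the algorithmic recourse and returns the best
#' (lowest fold index wins ties).  Folds without an incumbent are
#' skipped; if all fail the status is `infeasible_within_limit`.
#'
#' @inheritParams solve_saa
#' @return An `allocation_solution` (with `fold_costs` attached).
#' @export
solve_nfold_saa <- function(block, patients, sample, config,
                            alloc = allocation_config("nfold")) {
  folds <- partition_folds(sample, alloc$N)
  models <- lapply(folds, function(f)
    build_saa_milp(block, patients, f, config))
  res <- milp_solve_batch(lapply(models, `[[`, "model"),
                          time_limit = alloc$time_limit / alloc$N,
                          mip_rel_gap = alloc$mip_rel_gap)
  best <- NULL; fold_costs <- rep(NA_real_, alloc$N)
  for (k in seq_along(folds)) {
    if (is.null(res[[k]]$x)) next
    sched <- decode_first_stage(res[[k]]$x, models[[k]], block, patients)
    cost <- expected_cost(sched, sample, config)   # full-sample value
    fold_costs[k] <- cost
    if (is.null(best) || cost < best$expected_cost - 1e-12)
      best <- list(schedule = sched, expected_cost = cost,
                   objective = res[[k]]$objective + models[[k]]$const,
                   gap = res[[k]]$gap,
                   status = if (res[[k]]$status == "optimal") "optimal"
                            else "feasible")
  }
  if (is.null(best))
    return(structure(list(schedule = NULL, expected_cost = NA_real_,
                          objective = NA_real_, gap = NA_real_,
                          status = "infeasible_within_limit",
                          method = "nfold", fold_costs = fold_costs),
                     class = "allocation_solution"))
  structure(c(best, list(method = "nfold", fold_costs = fold_costs)),
            class = "allocation_solution")
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat(sprintf("allocation_solution (%s): status %s", x$method, x$status))
  if (!is.null(x$schedule))
    cat(sprintf(", expected cost %.4f, %d patients",
                x$expected_cost, nrow(x$schedule$patients)))
  cat("\n")
  invisible(x)
}
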