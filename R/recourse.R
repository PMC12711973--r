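# Second-stage (recourse) evaluation of a block schedule under realized
# scenarios.  Implements the real-time policies algorithmically:
#   * surgeries run in the planned sequence, never before their scheduled
#     start time;
#   * a no-show is revealed at the scheduled moment and its slot collapses;
#   * a surgery is cancelled iff its expected completion (actual start +
#     EOT) would exceed L + H;
#   * an emergency is inserted as soon as possible after the elective whose
#     start interval contains its arrival: immediately if the OR is idle,
#     at the end of the in-progress surgery otherwise; emergencies are
#     never cancelled and may run past L + H.
# The same kernel serves as BRKGA fitness, N-fold SAA re-evaluator, DES
# engine and as the algorithmic twin of the second-stage MILP.

#' Construct a block schedule
#'
#' A block schedule fixes the sequence and the scheduled start times of the
#' patients assigned to one OR block.  Start times are minutes from block
#' start; the first surgery starts at 0; consecutive planned completions
#' may not overlap (`t_i + mu_i <= t_{i+1}`) and every planned completion
#' must fit in the ordinary block length (`t_i + mu_i <= L`).
#'
#' @param block One MSS row (`or_id`, `day`, `specialty`, `length`,
#'   `max_overtime`).
#' @param patients Waiting-list rows of the scheduled patients, given in
#'   sequence order.
#' @param start_times Numeric vector of scheduled start times, aligned
#'   with `patients`.
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(block, patients, start_times) {
  n <- nrow(patients)
  stopifnot(length(start_times) == n)
  if (n > 0) {
    L <- block$length
    if (abs(start_times[1]) > 1e-9)
      stop("first scheduled start time must be 0", call. = FALSE)
    if (any(start_times + patients$mu > L + 1e-6))
      stop("planned completion exceeds block length", call. = FALSE)
    if (n > 1 &&
        any(start_times[-n] + patients$mu[-n] > start_times[-1] + 1e-6))
      stop("scheduled start times overlap planned completions",
           call. = FALSE)
  }
  structure(list(block = as.list(block[c("or_id", "day", "specialty",
                                         "length", "max_overtime")]),
                 patients = patients, start_times = as.numeric(start_times)),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("block_schedule OR%d day %d (%s): %d patients\n",
              x$block$or_id, x$block$day, x$block$specialty,
              nrow(x$patients)))
  if (nrow(x$patients))
    print(data.frame(id = x$patients$id, t = x$start_times,
                     mu = x$patients$mu))
  invisible(x)
}

# Vectorized realization of a block timeline over many scenarios.
#
# t, mu, c_canc, c_wait: per-patient (sequence order); rho, theta: S x n;
# em_arr, em_dur: S x m (NA = no emergency; arrivals sorted within a row).
# Returns per-scenario cost components and per-patient matrices.
sim_block_core <- function(t, mu, L, H, rho, theta, em_arr, em_dur,
                           c_canc, c_wait, c_idle, c_over) {
  n <- length(t)
  S <- if (n) nrow(rho) else nrow(em_arr)
  m <- ncol(em_arr)
  cur <- numeric(S)                 # OR-free time on the actual timeline
  Cmax <- numeric(S)                # completion of last executed work
  pending <- !is.na(em_arr)
  em_start <- matrix(NA_real_, S, m)
  em_after <- matrix(NA_integer_, S, m)  # elective position preceding em
  qhat <- chat <- a <- matrix(0, S, n)
  y <- matrix(1L, S, n)
  exec <- matrix(FALSE, S, n)
  tot_em <- numeric(S)

  insert_em <- function(limit) {
    # insert pending emergencies arriving strictly before `limit` (vector);
    # limit = +Inf flushes the queue after the last elective
    for (j in seq_len(m)) {
      ins <- pending[, j] & (em_arr[, j] < limit)
      if (!any(ins)) next
      st <- pmax(em_arr[ins, j], cur[ins])
      em_start[ins, j] <<- st
      cur[ins] <<- st + em_dur[ins, j]
      Cmax[ins] <<- pmax(Cmax[ins], cur[ins])
      tot_em[ins] <<- tot_em[ins] + em_dur[ins, j]
      pending[ins, j] <<- FALSE
      if (!is.infinite(limit[1])) limit <- pmax(cur, limit)
    }
  }

  for (i in seq_len(n)) {
    if (m) {
      # recompute the candidate start after each insertion shifts it
      repeat {
        before <- pending
        insert_em(pmax(cur, t[i]))
        if (identical(before, pending)) break
      }
      if (any(!is.na(em_start))) {
        newly <- !pending & is.na(em_after)
        em_after[newly & !is.na(em_start)] <- i - 1L
      }
    }
    qhat[, i] <- pmax(cur, t[i])
    present <- theta[, i] == 1
    cancel <- present & (qhat[, i] + mu[i] > L + H)
    y[, i] <- ifelse(cancel, 0L, 1L)
    ex <- present & !cancel
    exec[, i] <- ex
    chat[, i] <- qhat[, i] + ifelse(ex, rho[, i], 0)
    a[, i] <- ifelse(ex, qhat[, i] - t[i], 0)
    Cmax <- ifelse(ex, pmax(Cmax, chat[, i]), Cmax)
    cur <- chat[, i]
  }
  if (m && any(pending)) {
    insert_em(rep(Inf, S))
    newly <- !pending & is.na(em_after)
    em_after[newly & !is.na(em_start)] <- n
  }

  tot_exec <- if (n) rowSums(rho * exec) else numeric(S)
  g <- pmax(L, Cmax) - tot_exec - tot_em
  h <- pmax(0, Cmax - L)
  canc_cost <- if (n) as.vector((1 - y) %*% c_canc) else numeric(S)
  wait_cost <- if (n) as.vector(a %*% c_wait) else numeric(S)
  over_cost <- c_over * h
  idle_cost <- c_idle * g
  list(cost = over_cost + idle_cost + canc_cost + wait_cost,
       over_cost = over_cost, idle_cost = idle_cost,
       canc_cost = canc_cost, wait_cost = wait_cost,
       overtime = h, idle = g, C = Cmax,
       qhat = qhat, chat = chat, y = y, a = a, exec = exec,
       em_start = em_start, em_after = em_after,
       em_wait = em_start - em_arr)
}

# Scenario matrices restricted to one schedule's patients and block.
schedule_scenario_slices <- function(schedule, sample) {
  ids <- as.character(schedule$patients$id)
  miss <- setdiff(ids, colnames(sample$rho))
  if (length(miss))
    stop("scenario sample lacks patient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- block_key(schedule$block$or_id, schedule$block$day)
  if (!key %in% colnames(sample$em_duration))
    stop("scenario sample lacks block ", key, call. = FALSE)
  dur <- sample$em_duration[, key]
  arr <- sample$em_arrival[, key]
  arr[dur <= 0] <- NA
  dur[dur <= 0] <- NA
  list(rho = sample$rho[, ids, drop = FALSE],
       theta = sample$theta[, ids, drop = FALSE],
       em_arr = matrix(arr, ncol = 1), em_dur = matrix(dur, ncol = 1))
}

# Full vectorized evaluation of a schedule on a sample; the workhorse
# behind simulate_block / expected_cost / DES.
evaluate_block_sample <- function(schedule, sample, config,
                                  em_arr = NULL, em_dur = NULL) {
  sl <- schedule_scenario_slices(schedule, sample)
  if (is.null(em_arr)) { em_arr <- sl$em_arr; em_dur <- sl$em_dur }
  sim_block_core(t = schedule$start_times, mu = schedule$patients$mu,
                 L = schedule$block$length, H = schedule$block$max_overtime,
                 rho = sl$rho, theta = sl$theta,
                 em_arr = em_arr, em_dur = em_dur,
                 c_canc = schedule$patients$c_canc,
                 c_wait = schedule$patients$c_wait,
                 c_idle = config$c_idle, c_over = config$c_over)
}

#' Realize a block schedule under one scenario
#'
#' Applies the real-time policies to a single joint realization and
#' returns the full timeline: actual start/completion of every elective,
#' execution indicators, waiting times, the emergency insertion point, and
#' the block-level overtime, idle time and cost.
#'
#' @param schedule A [block_schedule()].
#' @param scen One scenario as returned by [scenario()], or a full
#'   `scenario_sample` with `w` selecting the realization.
#' @param config An [instance_config()] supplying the idle/overtime costs.
#' @param w Scenario index when `scen` is a `scenario_sample`.
#' @return An object of class `scenario_outcome`: list with `patients`
#'   (data.frame: `id`, `t`, `qhat`, `chat`, `y`, `executed`, `waiting`,
#'   `z`, `e`), `C`, `overtime`, `idle`, `cost`, cost components, and
#'   `em_arrival`, `em_duration`, `em_start` (NA if no emergency).
#' @export
simulate_block <- function(schedule, scen, config = instance_config(),
                           w = 1) {
  if (inherits(scen, "scenario_sample")) scen <- scenario(scen, w)
  ids <- as.character(schedule$patients$id)
  miss <- setdiff(ids, names(scen$rho))
  if (length(miss))
    stop("scenario lacks patient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- block_key(schedule$block$or_id, schedule$block$day)
  dur <- scen$em_duration[[key]]
  arr <- scen$em_arrival[[key]]
  if (is.null(dur)) stop("scenario lacks block ", key, call. = FALSE)
  has_em <- !is.na(dur) && dur > 0
  res <- sim_block_core(
    t = schedule$start_times, mu = schedule$patients$mu,
    L = schedule$block$length, H = schedule$block$max_overtime,
    rho = matrix(scen$rho[ids], 1), theta = matrix(scen$theta[ids], 1),
    em_arr = matrix(if (has_em) arr else NA_real_, 1),
    em_dur = matrix(if (has_em) dur else NA_real_, 1),
    c_canc = schedule$patients$c_canc, c_wait = schedule$patients$c_wait,
    c_idle = config$c_idle, c_over = config$c_over)
  n <- nrow(schedule$patients)
  z <- numeric(n); e <- integer(n)
  chat <- as.vector(res$chat)
  if (has_em) {
    pos <- res$em_after[1, 1]
    if (pos >= 1) {
      e[pos] <- 1L
      z[pos] <- res$em_start[1, 1] - chat[pos]
      chat[pos] <- chat[pos] + z[pos] + dur   # trailing emergency included
    }
  }
  structure(list(
    patients = data.frame(id = schedule$patients$id,
                          t = schedule$start_times,
                          qhat = as.vector(res$qhat), chat = chat,
                          y = as.vector(res$y),
                          executed = as.vector(res$exec),
                          waiting = as.vector(res$a), z = z, e = e),
    C = res$C[1], overtime = res$overtime[1], idle = res$idle[1],
    cost = res$cost[1],
    over_cost = res$over_cost[1], idle_cost = res$idle_cost[1],
    canc_cost = res$canc_cost[1], wait_cost = res$wait_cost[1],
    em_arrival = if (has_em) arr else NA_real_,
    em_duration = if (has_em) dur else NA_real_,
    em_start = if (has_em) res$em_start[1, 1] else NA_real_),
    class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf("scenario_outcome: cost %.4f (over %.4f idle %.4f canc %.4f wait %.4f)\n",
              x$cost, x$over_cost, x$idle_cost, x$canc_cost, x$wait_cost))
  invisible(x)
}

#' Expected (sample-average) cost of a block schedule
#'
#' Arithmetic mean over the scenario sample of the realized block cost
#' (overtime + idle + cancellation + waiting costs), i.e. the Monte Carlo
#' approximation of the recourse expectation used as BRKGA fitness and for
#' N-fold re-evaluation.
#'
#' @param schedule A [block_schedule()].
#' @param sample A `scenario_sample` covering the schedule's patients.
#' @param config An [instance_config()].
#' @return A single number (cost units).
#' @export
expected_cost <- function(schedule, sample, config = instance_config()) {
  if (!inherits(sample, "scenario_sample") || sample$size < 1)
    stop("sample must be a non-empty scenario_sample", call. = FALSE)
  mean(evaluate_block_sample(schedule, sample, config)$cost)
}

#' Waiting time of the emergency patient in a realized block
#'
#' Time from the emergency arrival to its actual surgery start: 0 when the
#' OR was idle at arrival, otherwise the residual of the in-progress
#' surgery.
#'
#' @param outcome A `scenario_outcome` from [simulate_block()].
#' @return Minutes (>= 0).
#' @export
emergency_wait <- function(outcome) {
  if (is.na(outcome$em_start))
    stop("no emergency surgery in this scenario", call. = FALSE)
  outcome$em_start - outcome$em_arrival
}

#' Dump realized outcomes to CSV (debugging aid)
#'
#' @param schedule A [block_schedule()].
#' @param sample A `scenario_sample`.
#' @param config An [instance_config()].
#' @param stem Output path stem; writes `<stem>_patients.csv` and
#'   `<stem>_block.csv`.
#' @export
write_outcomes_csv <- function(schedule, sample, config, stem) {
  res <- evaluate_block_sample(schedule, sample, config)
  n <- nrow(schedule$patients)
  pat <- data.frame(scenario = rep(seq_len(sample$size), n),
                    patient_id = rep(schedule$patients$id,
                                     each = sample$size),
                    qhat = as.vector(res$qhat), chat = as.vector(res$chat),
                    y = as.vector(res$y), waiting = as.vector(res$a))
  utils::write.csv(pat, paste0(stem, "_patients.csv"), row.names = FALSE)
  blk <- data.frame(scenario = seq_len(sample$size),
                    overtime = res$overtime, idle = res$idle, C = res$C,
                    cost = res$cost)
  utils::write.csv(blk, paste0(stem, "_block.csv"), row.names = FALSE)
  invisible(stem)
}
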