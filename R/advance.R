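# Advance scheduling (assignment procedure): one chance-constrained
# integer program per specialty.  The chance constraint bounds, per OR
# block, the probability that realized elective load plus the emergency
# surgery exceeds L + H; it is enforced on a Monte Carlo sample via
# per-(block, scenario) overload indicator binaries with a budget of
# floor(alpha * |S|) violated scenarios.

#' Configuration of the advance-scheduling model
#'
#' @param alpha Robustness level in (0, 1): the per-block probability of
#'   exceeding `L + H` (estimated on the training sample) may not exceed
#'   `alpha`.
#' @param beta Length-3 nonnegative weight vector over the patient-mix
#'   proxies (cancellation-cost balance, waiting-cost balance, utilization
#'   balance); must sum to 1.
#' @param cc_sample_size Scenarios used for the Monte Carlo approximation
#'   of the chance constraint (default 1000).
#' @param time_limit Solver wall-clock budget in seconds per specialty
#'   (default 300).
#' @param mip_gap_tol Relative MIP gap tolerance (default 1e-6).
#' @return An object of class `advance_config`.
#' @export
advance_config <- function(alpha = 0.1, beta = c(0, 0, 1),
                           cc_sample_size = 1000, time_limit = 300,
                           mip_gap_tol = 1e-6) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (length(beta) != 3 || any(beta < 0) || any(beta > 1) ||
      abs(sum(beta) - 1) > 1e-9)
    stop("beta must be three weights in [0, 1] summing to 1", call. = FALSE)
  structure(list(alpha = alpha, beta = as.numeric(beta),
                 cc_sample_size = cc_sample_size, time_limit = time_limit,
                 mip_gap_tol = mip_gap_tol),
            class = "advance_config")
}

#' Hierarchy and standardization coefficients of the advance model
#'
#' The objective puts the total scheduling cost at the top level and the
#' weighted proxies at the bottom level.  `m_s` bounds the number of
#' patients per block; `b2` and `b3` bring the three proxies to the same
#' order of magnitude (worst-case ratios); `b1` scales the whole proxy
#' term below one scheduling-cost grid step so proxies can never override
#' the scheduling-cost level.
#'
#' @param patients Waiting-list rows of one specialty (nonempty).
#' @param blocks MSS rows of the same specialty (nonempty).
#' @param delta_sched Scheduling-cost grid step.
#' @return List with `m_s`, `b1`, `b2`, `b3`.
#' @export
hierarchy_coefficients <- function(patients, blocks, delta_sched = 10) {
  if (!nrow(patients) || !nrow(blocks))
    stop("patients and blocks must be nonempty", call. = FALSE)
  max_cw <- max(patients$c_wait)
  if (max_cw <= 0)
    stop("invalid instance: maximum waiting cost is zero", call. = FALSE)
  max_L <- max(blocks$length)
  max_cc <- max(patients$c_canc)
  m_s <- floor(max_L / min(patients$mu))
  list(m_s = m_s,
       b1 = delta_sched / (1 + m_s * max_cc),
       b2 = max_cc / max_cw,
       b3 = (m_s * max_cc) / (nrow(blocks) * max_L / 2))
}

# Scenario load matrices for one specialty: list with `load` (S x n_p,
# theta * rho) and `em` (S x n_b).
specialty_slices <- function(patients, blocks, sample) {
  ids <- as.character(patients$id)
  keys <- block_key(blocks$or_id, blocks$day)
  list(load = sample$rho[, ids, drop = FALSE] *
         sample$theta[, ids, drop = FALSE],
       em = sample$em_duration[, keys, drop = FALSE])
}

#' Build the advance-scheduling MILP for one specialty
#'
#' Assignment binaries `x[i, b]`; per-(block, scenario) overload binaries
#' with tightest-valid big-M and a budget of `floor(alpha * |S|)` violated
#' scenarios per block; epigraph variables for the cancellation- and
#' waiting-cost balance proxies; absolute-value splits for the
#' utilization-balance proxy around the sample-average utilizations.
#'
#' @param patients Waiting-list rows of one specialty.
#' @param blocks MSS rows of that specialty.
#' @param sample A `scenario_sample` (training sample).
#' @param config An [advance_config()].
#' @param coef Output of [hierarchy_coefficients()]; computed if NULL.
#' @return List with the `milp_model` and the index bookkeeping needed to
#'   decode a solution.
#' @keywords internal
build_advance_milp <- function(patients, blocks, sample, config,
                               coef = NULL) {
  np <- nrow(patients); nb <- nrow(blocks); S <- sample$size
  if (is.null(coef) && np > 0)
    coef <- hierarchy_coefficients(patients, blocks)
  sl <- specialty_slices(patients, blocks, sample)
  m <- milp_new()
  if (np == 0)
    return(list(model = m, x = matrix(integer(0), 0, nb),
                const = 0, coef = coef))

  b1 <- coef$b1; b2 <- coef$b2; b3 <- coef$b3
  beta <- config$beta
  x <- matrix(milp_add_vars(m, np * nb, lb = 0, ub = 1, integer = TRUE,
                            obj = rep(-patients$c_sched, nb)),
              np, nb)                      # x[i,b]; obj: -c_sched per assign
  const <- sum(patients$c_sched)           # Sum c_sched (1 - Sum x) offset

  for (i in seq_len(np))                   # at most one block per patient
    milp_add_con(m, x[i, ], rep(1, nb), ub = 1)
  for (b in seq_len(nb))                   # deterministic capacity (EOT)
    milp_add_con(m, x[, b], patients$mu, ub = blocks$length[b])

  # chance constraints: overload indicators with tight big-M
  budget <- floor(config$alpha * S)
  tot_load <- rowSums(sl$load)
  for (b in seq_len(nb)) {
    cap <- blocks$length[b] + blocks$max_overtime[b]
    Mw <- pmax(0, sl$em[, b] + tot_load - cap)
    active <- which(Mw > 0)   # scenarios that can overload at all
    if (!length(active)) next
    v <- milp_add_vars(m, length(active), lb = 0, ub = 1, integer = TRUE)
    for (k in seq_along(active)) {
      w <- active[k]
      milp_add_con(m, c(x[, b], v[k]), c(sl$load[w, ], -Mw[w]),
                   ub = cap - sl$em[w, b])
    }
    milp_add_con(m, v, rep(1, length(active)), ub = budget)
  }

  # proxy 1 and 2: epigraph of the per-block cost sums
  gc <- milp_add_vars(m, 1, obj = b1 * beta[1])
  gw <- milp_add_vars(m, 1, obj = b1 * beta[2] * b2)
  for (b in seq_len(nb)) {
    milp_add_con(m, c(x[, b], gc), c(patients$c_canc, -1), ub = 0)
    milp_add_con(m, c(x[, b], gw), c(patients$c_wait, -1), ub = 0)
  }

  # proxy 3: |u_b - mean(u)| via split variables; u_b is the sample-average
  # utilization, an affine expression of x
  wbar <- colMeans(sl$load)                # E[theta * rho] per patient
  dbar <- colMeans(sl$em)                  # E[delta] per block
  dp <- milp_add_vars(m, nb, obj = b1 * beta[3] * b3)
  dm <- milp_add_vars(m, nb, obj = b1 * beta[3] * b3)
  for (b in seq_len(nb)) {
    # u_b - mean_b'(u_b') - dp_b + dm_b = mean(dbar) - dbar_b
    ind <- c(as.vector(x), dp[b], dm[b])
    cf <- matrix(rep(-wbar / nb, nb), np, nb)
    cf[, b] <- cf[, b] + wbar
    ind_cf <- c(as.vector(cf), -1, 1)
    milp_add_con(m, ind, ind_cf, lb = mean(dbar) - dbar[b],
                 ub = mean(dbar) - dbar[b])
  }
  list(model = m, x = x, const = const, coef = coef)
}

# Proxy values and utilizations implied by an assignment matrix.
advance_proxies <- function(xmat, patients, blocks, sample) {
  sl <- specialty_slices(patients, blocks, sample)
  u <- colMeans(sl$em) + as.vector(t(xmat) %*% colMeans(sl$load))
  list(gamma_canc = if (nrow(blocks)) max(t(xmat) %*% patients$c_canc) else 0,
       gamma_wait = if (nrow(blocks)) max(t(xmat) %*% patients$c_wait) else 0,
       gamma_time = sum(abs(u - mean(u))),
       utilization = u, mean_utilization = mean(u))
}

#' Empirical per-block overload probabilities of an assignment
#'
#' Recomputes, independently of the solver, the fraction of sample
#' scenarios in which the realized elective load plus the emergency
#' duration exceeds `L + H` for each block of the solution's specialty.
#'
#' @param solution An `advance_solution`.
#' @param instance The `or_instance` it was solved on.
#' @param sample The `scenario_sample` to audit against.
#' @return Named numeric vector of overload frequencies, one per block.
#' @export
overload_probabilities <- function(solution, instance, sample) {
  patients <- instance$waiting_list[instance$waiting_list$specialty ==
                                      solution$specialty, , drop = FALSE]
  blocks <- blocks_of(instance$mss, solution$specialty)
  sl <- specialty_slices(patients, blocks, sample)
  keys <- block_key(blocks$or_id, blocks$day)
  out <- numeric(nrow(blocks)); names(out) <- keys
  asg <- solution$assignment
  for (b in seq_len(nrow(blocks))) {
    ids <- asg$patient_id[asg$or_id == blocks$or_id[b] &
                            asg$day == blocks$day[b]]
    load <- sl$em[, b]
    if (length(ids))
      load <- load + rowSums(sl$load[, as.character(ids), drop = FALSE])
    cap <- blocks$length[b] + blocks$max_overtime[b]
    out[b] <- mean(load > cap)
  }
  out
}

#' Solve the advance-scheduling model for one specialty
#'
#' @param instance An `or_instance`.
#' @param config An [advance_config()].
#' @param sample Training `scenario_sample` (its size is the Monte Carlo
#'   sample size of the chance constraints).
#' @param specialty Specialty name.
#' @return An object of class `advance_solution`: `assignment`
#'   (data.frame `patient_id`, `or_id`, `day`), proxy values recomputed
#'   from the assignment, `objective` (top + bottom level),
#'   `lower_bound` (solver dual bound on the optimum), `sched_cost`
#'   (scheduling costs of scheduled patients), `unsched_cost`, `gap`,
#'   `status`, `overload` (post-hoc per-block audit).
#' @export
solve_advance <- function(instance, config, sample, specialty) {
  wl <- instance$waiting_list
  patients <- wl[wl$specialty == specialty, , drop = FALSE]
  blocks <- blocks_of(instance$mss, specialty)
  if (!nrow(blocks))
    stop("no MSS block for specialty ", specialty, call. = FALSE)
  if (!nrow(patients)) {
    sol <- structure(list(specialty = specialty,
                          assignment = data.frame(patient_id = integer(),
                                                  or_id = integer(),
                                                  day = integer()),
                          gamma_canc = 0, gamma_wait = 0, gamma_time = 0,
                          utilization = NULL, mean_utilization = NA_real_,
                          objective = 0, sched_cost = 0, unsched_cost = 0,
                          gap = 0, status = "optimal", overload = NULL),
                     class = "advance_solution")
    return(sol)
  }
  built <- build_advance_milp(patients, blocks, sample, config)
  res <- milp_solve(built$model, time_limit = config$time_limit,
                    mip_rel_gap = config$mip_gap_tol)
  if (is.null(res$x)) {
    status <- if (res$status == "infeasible") "infeasible" else
      "no_incumbent_within_limit"
    return(structure(list(specialty = specialty, assignment = NULL,
                          objective = NA_real_, gap = NA_real_,
                          status = status),
                     class = "advance_solution"))
  }
  xmat <- matrix(round(res$x[built$x]), nrow(patients), nrow(blocks))
  asg_idx <- which(xmat == 1, arr.ind = TRUE)
  assignment <- data.frame(
    patient_id = patients$id[asg_idx[, 1]],
    or_id = blocks$or_id[asg_idx[, 2]],
    day = blocks$day[asg_idx[, 2]])
  assignment <- assignment[order(assignment$or_id, assignment$day,
                                 assignment$patient_id), , drop = FALSE]
  rownames(assignment) <- NULL
  px <- advance_proxies(xmat, patients, blocks, sample)
  sched <- patients$id %in% assignment$patient_id
  b <- built$coef
  objective <- sum(patients$c_sched[!sched]) +
    b$b1 * (config$beta[1] * px$gamma_canc +
              config$beta[2] * b$b2 * px$gamma_wait +
              config$beta[3] * b$b3 * px$gamma_time)
  sol <- structure(list(specialty = specialty, assignment = assignment,
                        gamma_canc = px$gamma_canc,
                        gamma_wait = px$gamma_wait,
                        gamma_time = px$gamma_time,
                        utilization = px$utilization,
                        mean_utilization = px$mean_utilization,
                        objective = objective,
                        lower_bound = if (is.na(res$dual_bound)) NA_real_
                                      else res$dual_bound + built$const,
                        sched_cost = sum(patients$c_sched[sched]),
                        unsched_cost = sum(patients$c_sched[!sched]),
                        gap = res$gap,
                        status = if (res$status == "optimal") "optimal"
                                 else "feasible",
                        overload = NULL),
                   class = "advance_solution")
  sol$overload <- overload_probabilities(sol, instance, sample)
  if (any(sol$overload > config$alpha + 1e-12))
    warning("post-hoc audit: overload frequency exceeds alpha in block(s) ",
            paste(names(sol$overload)[sol$overload > config$alpha],
                  collapse = ", "))
  sol
}

#' @export
print.advance_solution <- function(x, ...) {
  cat(sprintf("advance_solution [%s] status %s\n", x$specialty, x$status))
  if (!is.null(x$assignment)) {
    cat(sprintf("  scheduled %d patients, sched_cost %.0f, objective %.4f (gap %.2g)\n",
                nrow(x$assignment), x$sched_cost, x$objective,
                if (is.na(x$gap)) Inf else x$gap))
    cat(sprintf("  proxies: canc %.3f wait %.5f time %.3f; max overload %.3f\n",
                x$gamma_canc, x$gamma_wait, x$gamma_time,
                max(x$overload)))
  }
  invisible(x)
}

#' Solve the advance stage for every specialty
#'
#' @inheritParams solve_advance
#' @return Named list of `advance_solution` objects, one per specialty
#'   present in the instance.
#' @export
solve_advance_all <- function(instance, config, sample) {
  specs <- intersect(SPECIALTIES, unique(instance$waiting_list$specialty))
  out <- lapply(specs, function(s) solve_advance(instance, config, sample, s))
  names(out) <- specs
  out
}

# Patients of each block from a set of advance solutions: named list
# (block key -> waiting-list rows).
assignment_by_block <- function(solutions, instance) {
  out <- list()
  wl <- instance$waiting_list
  for (sol in solutions) {
    if (is.null(sol$assignment) || !nrow(sol$assignment)) next
    a <- sol$assignment
    for (key in unique(block_key(a$or_id, a$day))) {
      ids <- a$patient_id[block_key(a$or_id, a$day) == key]
      out[[key]] <- wl[wl$id %in% ids, , drop = FALSE]
    }
  }
  out
}
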