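# Sampling of the joint random vector (rho, delta, tau, theta): elective
# real operating times, emergency durations and arrivals, and no-shows.
# One scenario_sample is generated per run and shared across all model
# configurations so comparisons are paired.

# Lognormal log-scale parameters from an arithmetic mean and SD
# (moment matching): s2 = log(1 + (sd/mean)^2), m = log(mean) - s2/2.
lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Truncated-lognormal draws by rejection: resample above `trunc` so the
# density below the cut keeps the lognormal shape (no atom at the bound).
rlnorm_trunc <- function(n, mean, sd, trunc) {
  p <- lnorm_pars(mean, sd)
  x <- stats::rlnorm(n, p$meanlog, p$sdlog)
  bad <- which(x > trunc)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), p$meanlog, p$sdlog)
    bad <- bad[x[bad] > trunc]
  }
  x
}

#' Sample a reusable set of scenarios
#'
#' Draws `n` independent joint realizations for every patient on the
#' waiting list and every OR block of the instance:
#' * `rho[w, i]` — real operating time of patient `i`, lognormal with
#'   arithmetic mean `mu_i` and SD `sigma_i`;
#' * `theta[w, i]` — presence indicator, Bernoulli(1 - no-show rate);
#' * `em_duration[w, b]` — emergency surgery duration in block `b`:
#'   with probability `p_em` a lognormal(mean `mu_em`, SD `sigma_em`)
#'   draw truncated at `em_truncation` by rejection, else 0 (no emergency);
#' * `em_arrival[w, b]` — arrival time of the emergency, uniform on
#'   `[0, L_b]` when an emergency exists, 0 otherwise.
#'
#' Each patient and each block has its own deterministic random substream
#' derived from `(seed, index)`, so enlarging the waiting list leaves the
#' draws of existing patients untouched.
#'
#' @param instance An `or_instance`.
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed.
#' @return An object of class `scenario_sample`: a list with matrices
#'   `rho`, `theta` (`n` x patients) and `em_duration`, `em_arrival`
#'   (`n` x blocks, columns keyed by `block_key(or, day)`), plus
#'   `patient_id`, `size`, `seed`.
#' @export
sample_scenarios <- function(instance, n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  wl <- instance$waiting_list
  mss <- instance$mss
  cfg <- instance$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  np <- nrow(wl)
  rho <- matrix(0, n, np)
  theta <- matrix(1L, n, np)
  for (i in seq_len(np)) {
    set.seed(substream_seed(seed, kind = 2L, index = wl$id[i]))
    p <- lnorm_pars(wl$mu[i], wl$sigma[i])
    rho[, i] <- stats::rlnorm(n, p$meanlog, p$sdlog)
    r <- wl$no_show_rate[i]
    theta[, i] <- if (r > 0) as.integer(stats::runif(n) >= r) else 1L
  }
  colnames(rho) <- colnames(theta) <- as.character(wl$id)

  nb <- nrow(mss)
  em_dur <- matrix(0, n, nb)
  em_arr <- matrix(0, n, nb)
  for (b in seq_len(nb)) {
    set.seed(substream_seed(seed, kind = 3L,
                            index = mss$or_id[b] * 100 + mss$day[b]))
    has <- stats::runif(n) < cfg$p_em
    k <- sum(has)
    if (k) {
      em_dur[has, b] <- rlnorm_trunc(k, cfg$mu_em, cfg$sigma_em,
                                     cfg$em_truncation)
      em_arr[has, b] <- stats::runif(k, 0, mss$length[b])
    }
  }
  colnames(em_dur) <- colnames(em_arr) <- block_key(mss$or_id, mss$day)

  structure(list(rho = rho, theta = theta,
                 em_duration = em_dur, em_arrival = em_arr,
                 patient_id = wl$id, size = n, seed = seed),
            class = "scenario_sample")
}

#' @export
print.scenario_sample <- function(x, ...) {
  cat(sprintf("scenario_sample: %d scenarios, %d patients, %d blocks\n",
              x$size, ncol(x$rho), ncol(x$em_duration)))
  invisible(x)
}

#' Extract one scenario
#'
#' @param sample A `scenario_sample`.
#' @param w Scenario index in `1..size`.
#' @return A list with vectors `rho`, `theta` (named by patient id) and
#'   `em_duration`, `em_arrival` (named by block key).
#' @export
scenario <- function(sample, w) {
  stopifnot(inherits(sample, "scenario_sample"), w >= 1, w <= sample$size)
  list(rho = sample$rho[w, ], theta = sample$theta[w, ],
       em_duration = sample$em_duration[w, ],
       em_arrival = sample$em_arrival[w, ])
}

# Subset a scenario_sample by scenario indices (used by fold partitioning
# and by per-block evaluation).
subset_scenarios <- function(sample, idx) {
  structure(list(rho = sample$rho[idx, , drop = FALSE],
                 theta = sample$theta[idx, , drop = FALSE],
                 em_duration = sample$em_duration[idx, , drop = FALSE],
                 em_arrival = sample$em_arrival[idx, , drop = FALSE],
                 patient_id = sample$patient_id, size = length(idx),
                 seed = sample$seed),
            class = "scenario_sample")
}

#' Partition a scenario sample into folds
#'
#' Splits the sample into `N` disjoint folds of size `size/N` (contiguous
#' scenario indices; when `N` does not divide the size, the last fold
#' absorbs the remainder).
#'
#' @param sample A `scenario_sample`.
#' @param N Number of folds, `1 <= N <= size`.
#' @return A list of `N` `scenario_sample` objects.
#' @export
partition_folds <- function(sample, N) {
  stopifnot(inherits(sample, "scenario_sample"))
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N > sample$size)
    stop("N must satisfy 1 <= N <= sample size", call. = FALSE)
  N <- as.integer(N)
  base <- sample$size %/% N
  starts <- (seq_len(N) - 1L) * base + 1L
  ends <- starts + base - 1L
  ends[N] <- sample$size
  lapply(seq_len(N), function(f) subset_scenarios(sample, starts[f]:ends[f]))
}

#' Sample Poisson emergency arrivals for one block
#'
#' Relaxes the at-most-one-emergency assumption: the number of emergencies
#' per block scenario follows a Poisson distribution with the same mean
#' `p_em` as the Bernoulli indicator; arrivals are i.i.d. uniform on
#' `[0, L]` and sorted in increasing order; durations follow the same
#' truncated lognormal as the Bernoulli case.
#'
#' @param instance An `or_instance`.
#' @param block One row of the MSS (data.frame with `or_id`, `day`,
#'   `length`).
#' @param n Number of scenarios.
#' @param seed Integer seed.
#' @return A list with `count` (integer vector, length `n`) and matrices
#'   `arrival`, `duration` (`n` x max count, NA-padded, arrivals
#'   nondecreasing within a row).
#' @export
sample_poisson_emergencies <- function(instance, block, n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  cfg <- instance$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, kind = 4L,
                          index = block$or_id * 100 + block$day))
  count <- stats::rpois(n, cfg$p_em)
  mx <- max(count, 1L)
  arr <- matrix(NA_real_, n, mx)
  dur <- matrix(NA_real_, n, mx)
  tot <- sum(count)
  if (tot) {
    a <- stats::runif(tot, 0, block$length)
    d <- rlnorm_trunc(tot, cfg$mu_em, cfg$sigma_em, cfg$em_truncation)
    pos <- 0L
    for (w in which(count > 0L)) {
      k <- count[w]
      take <- pos + seq_len(k)
      o <- order(a[take])
      arr[w, seq_len(k)] <- a[take][o]
      dur[w, seq_len(k)] <- d[take][o]
      pos <- pos + k
    }
  }
  list(count = count, arrival = arr, duration = dur)
}

#' Dump a scenario sample to CSV files
#'
#' Writes two CSVs: `<stem>_patients.csv` with columns
#' `(scenario, patient_id, rot, present)` and `<stem>_blocks.csv` with
#' `(scenario, or_id, day, em_duration, em_arrival)`.
#'
#' @param sample A `scenario_sample`.
#' @param stem Output path stem.
#' @export
write_scenarios_csv <- function(sample, stem) {
  np <- ncol(sample$rho)
  pat <- data.frame(
    scenario = rep(seq_len(sample$size), np),
    patient_id = rep(sample$patient_id, each = sample$size),
    rot = as.vector(sample$rho),
    present = as.vector(sample$theta))
  utils::write.csv(pat, paste0(stem, "_patients.csv"), row.names = FALSE)
  keys <- colnames(sample$em_duration)
  ord <- do.call(rbind, strsplit(sub("^OR", "", keys), ":d"))
  blk <- data.frame(
    scenario = rep(seq_len(sample$size), length(keys)),
    or_id = rep(as.integer(ord[, 1]), each = sample$size),
    day = rep(as.integer(ord[, 2]), each = sample$size),
    em_duration = as.vector(sample$em_duration),
    em_arrival = as.vector(sample$em_arrival))
  utils::write.csv(blk, paste0(stem, "_blocks.csv"), row.names = FALSE)
  invisible(stem)
}
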