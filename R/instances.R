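# Domain data model and synthetic problem-instance generation.
#
# An instance bundles a waiting list of elective patients, a master surgery
# schedule (MSS) assigning operating-room blocks to specialties, and the
# global stochastic/cost parameters shared by every downstream stage.

SPECIALTIES <- c("CARDIO", "GASTRO", "GYN", "ORTH", "URO")

# Threshold on sigma/mu separating the low- and high-variability procedure
# classes; midpoint between the two design coefficients of variation
# (0.151 and 0.202) used by the duration mixtures.
CV_SPLIT <- 0.175

#' Reference surgical procedure groups
#'
#' Returns the built-in catalogue of surgical procedure groups: for each of
#' the five specialties (CARDIO, GASTRO, GYN, ORTH, URO), the lognormal
#' duration components of the specialty's fitted mixture, with their within-
#' specialty sampling frequencies.  Durations are in minutes.  Each group is
#' labelled `"LCV"` (low coefficient of variation, roughly sigma/mu = 0.151)
#' or `"HCV"` (roughly 0.202) by the rule sigma/mu < 0.175.
#'
#' Frequencies are normalized to sum to exactly 1 within each specialty
#' (the printed three-decimal values can be off by 1e-3 in the sum).
#'
#' @return A data.frame with one row per procedure group and columns
#'   `specialty`, `group` (index within specialty), `frequency`,
#'   `mean_duration`, `sd_duration`, `cv_class`.
#' @export
#' @examples
#' pg <- default_procedure_groups()
#' table(pg$specialty)
default_procedure_groups <- function() {
  raw <- list(
    CARDIO = list(
      f  = c(0.047, 0.204, 0.172, 0.07, 0.272, 0.083, 0.151),
      mu = c(32.3, 53.4, 67.2, 85.9, 107.9, 136.3, 162.9),
      sd = c(4.9, 10.8, 13.6, 17.4, 21.8, 20.6, 24.6)),
    GASTRO = list(
      f  = c(0.016, 0.089, 0.224, 0.213, 0.243, 0.182, 0.033),
      mu = c(20.0, 41.6, 72.6, 108.7, 159.7, 234.0, 330.4),
      sd = c(4.0, 8.4, 14.7, 16.4, 24.1, 35.3, 49.8)),
    GYN = list(
      f  = c(0.206, 0.15, 0.271, 0.328, 0.045),
      mu = c(24.6, 43.8, 68.2, 124.2, 216.4),
      sd = c(5.0, 6.6, 10.3, 25.1, 32.6)),
    ORTH = list(
      f  = c(0.04, 0.126, 0.239, 0.535, 0.06),
      mu = c(32.9, 63.9, 108.3, 174.3, 243.6),
      sd = c(6.7, 9.6, 21.9, 26.3, 49.2)),
    URO = list(
      f  = c(0.158, 0.451, 0.36, 0.031),
      mu = c(32.1, 58.1, 94.7, 208.8),
      sd = c(6.5, 11.7, 19.1, 31.5)))
  out <- do.call(rbind, lapply(names(raw), function(s) {
    g <- raw[[s]]
    data.frame(
      specialty = s,
      group = seq_along(g$f),
      frequency = g$f / sum(g$f),
      mean_duration = g$mu,
      sd_duration = g$sd,
      stringsAsFactors = FALSE)
  }))
  out$cv_class <- ifelse(out$sd_duration / out$mean_duration < CV_SPLIT,
                         "LCV", "HCV")
  rownames(out) <- NULL
  out
}

#' Default master surgery schedule
#'
#' A fixed weekly MSS over 9 operating rooms and 5 weekdays (26 blocks).
#' The per-OR specialty multiset follows the reference pattern (OR1: one
#' GASTRO and two GYN blocks; OR2: open all five days; OR3: three CARDIO;
#' OR4: three URO; OR5: two ORTH and one URO; OR6: two ORTH; OR7: three
#' ORTH; OR8: two GASTRO; OR9: one GYN and one GASTRO, with Monday empty).
#' Day placement within an OR is a convention of this package: blocks fill
#' consecutive days from Monday, except OR9 which opens Tuesday and
#' Wednesday.  The MSS is a plain data.frame and fully overridable.
#'
#' @param block_length Ordinary block duration in minutes (default 480).
#' @param max_overtime Maximum overtime per block in minutes (default 60).
#' @return An object of class `mss`: a data.frame with columns `or_id`,
#'   `day` (1 = Monday, ..., 5 = Friday), `specialty`, `length`,
#'   `max_overtime`.
#' @export
default_mss <- function(block_length = 480, max_overtime = 60) {
  spec_by_or <- list(
    `1` = c("GASTRO", "GYN", "GYN"),
    `2` = c("GASTRO", "GYN", "GYN", "GYN", "GASTRO"),
    `3` = c("CARDIO", "CARDIO", "CARDIO"),
    `4` = c("URO", "URO", "URO"),
    `5` = c("ORTH", "ORTH", "URO"),
    `6` = c("ORTH", "ORTH"),
    `7` = c("ORTH", "ORTH", "ORTH"),
    `8` = c("GASTRO", "GASTRO"),
    `9` = c("GYN", "GASTRO"))
  rows <- lapply(names(spec_by_or), function(or) {
    sp <- spec_by_or[[or]]
    first_day <- if (or == "9") 2L else 1L
    data.frame(or_id = as.integer(or),
               day = seq.int(first_day, length.out = length(sp)),
               specialty = sp,
               length = block_length,
               max_overtime = max_overtime,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  validate_mss(m)
  class(m) <- c("mss", "data.frame")
  m
}

validate_mss <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("or_id", "day", "specialty", "length", "max_overtime")
                %in% names(m)))
  if (anyDuplicated(m[c("or_id", "day")]))
    stop("duplicate (or_id, day) pair in MSS", call. = FALSE)
  if (any(m$length <= 0)) stop("block length must be positive", call. = FALSE)
  if (any(m$max_overtime < 0)) stop("max_overtime must be >= 0", call. = FALSE)
  if (!all(m$specialty %in% SPECIALTIES))
    stop("unknown specialty in MSS: ",
         paste(setdiff(m$specialty, SPECIALTIES), collapse = ", "),
         call. = FALSE)
  invisible(m)
}

#' Instance-level stochastic and cost parameters
#'
#' @param p_em Probability that an emergency surgery is inserted in a given
#'   OR block on a given day (default 0.2).
#' @param mu_em,sigma_em Arithmetic mean and standard deviation (minutes) of
#'   the emergency surgery duration lognormal (defaults 93 and 60).
#' @param em_truncation Upper truncation of the emergency duration, minutes
#'   (default 240); applied by rejection so the density keeps its shape.
#' @param c_idle,c_over Idle and overtime cost per minute (defaults 1/9 and
#'   1/6; the facility-weighted alternative is 1/3 and 1/3).
#' @param delta_sched Grid step of the scheduling costs (default 10;
#'   scheduling costs are drawn uniformly from `{10, 20, ..., 100}`).
#' @param outpatient_share_lcv,outpatient_share_hcv Probability that a
#'   patient from a low-/high-variability procedure group is an outpatient
#'   (defaults 0.7 and 0.3).
#' @param no_show_inpatient,no_show_outpatient No-show rates by patient type
#'   (defaults 0.08 and 0.24).
#' @param specialty_weights Named probabilities of each specialty in the
#'   waiting list; defaults to the empirical case-mix shares
#'   (CARDIO 14.32%, GASTRO 18.76%, GYN 30.43%, ORTH 15.90%, URO 20.59%).
#' @return An object of class `instance_config` (a named list).
#' @export
instance_config <- function(p_em = 0.2, mu_em = 93, sigma_em = 60,
                            em_truncation = 240,
                            c_idle = 1 / 9, c_over = 1 / 6,
                            delta_sched = 10,
                            outpatient_share_lcv = 0.7,
                            outpatient_share_hcv = 0.3,
                            no_show_inpatient = 0.08,
                            no_show_outpatient = 0.24,
                            specialty_weights = c(CARDIO = 0.1432,
                                                  GASTRO = 0.1876,
                                                  GYN = 0.3043,
                                                  ORTH = 0.1590,
                                                  URO = 0.2059)) {
  probs <- c(p_em, outpatient_share_lcv, outpatient_share_hcv,
             no_show_inpatient, no_show_outpatient, specialty_weights)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(specialty_weights) - 1) > 1e-9)
    stop("specialty_weights must sum to 1", call. = FALSE)
  if (!setequal(names(specialty_weights), SPECIALTIES))
    stop("specialty_weights must be named after the five specialties",
         call. = FALSE)
  stopifnot(mu_em > 0, sigma_em > 0, em_truncation > 0,
            c_idle >= 0, c_over >= 0, delta_sched > 0)
  structure(list(p_em = p_em, mu_em = mu_em, sigma_em = sigma_em,
                 em_truncation = em_truncation,
                 c_idle = c_idle, c_over = c_over,
                 delta_sched = delta_sched,
                 outpatient_share_lcv = outpatient_share_lcv,
                 outpatient_share_hcv = outpatient_share_hcv,
                 no_show_inpatient = no_show_inpatient,
                 no_show_outpatient = no_show_outpatient,
                 specialty_weights = specialty_weights[SPECIALTIES]),
            class = "instance_config")
}

# Deterministic sub-seed for an indexed random stream.  Keeps draws for
# patient/block `index` unchanged when other indices are added or removed.
substream_seed <- function(seed, kind, index) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  base <- (as.double(seed) %% 2147483629) * 48271 + kind * 1299721 +
    as.double(index) * 15485863
  as.integer(base %% 2147483629)
}

#' Generate a synthetic elective waiting list
#'
#' Each patient independently draws a specialty from the configured
#' case-mix weights, a procedure group from the specialty's frequency
#' vector (which fixes the EOT `mu` and its standard deviation `sigma`),
#' a patient type (outpatient with probability 0.7 for low-variability
#' groups and 0.3 for high-variability ones), a scheduling cost uniform on
#' `{10, 20, ..., 100}`, a cancellation cost equal to 4x (inpatient) or
#' 2x (outpatient) the scheduling cost, and a per-minute waiting cost
#' uniform on `[1/360, 1/36]` (inpatient) or `[1/180, 1/18]` (outpatient).
#' No-show rates are 0.08 (inpatient) and 0.24 (outpatient).
#'
#' Generation is a pure function of `(n, config, seed)`.
#'
#' @param n Number of patients (>= 1).
#' @param config An [instance_config()].
#' @param seed Integer seed.
#' @param groups Procedure-group table; defaults to
#'   [default_procedure_groups()].
#' @return A data.frame of class `waiting_list`, one row per patient, with
#'   columns `id`, `specialty`, `group`, `patient_type`, `mu`, `sigma`,
#'   `cv_class`, `no_show_rate`, `c_sched`, `c_canc`, `c_wait`.
#' @export
generate_waiting_list <- function(n, config = instance_config(), seed = 1,
                                  groups = default_procedure_groups()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, kind = 1L, index = 0L))

  spec <- sample(SPECIALTIES, n, replace = TRUE,
                 prob = config$specialty_weights[SPECIALTIES])
  grp <- integer(n)
  for (s in SPECIALTIES) {
    idx <- which(spec == s)
    if (!length(idx)) next
    gs <- groups[groups$specialty == s, ]
    grp[idx] <- sample(gs$group, length(idx), replace = TRUE,
                       prob = gs$frequency)
  }
  key <- paste(spec, grp)
  gkey <- paste(groups$specialty, groups$group)
  gi <- match(key, gkey)
  cv <- groups$cv_class[gi]
  p_out <- ifelse(cv == "LCV", config$outpatient_share_lcv,
                  config$outpatient_share_hcv)
  type <- ifelse(stats::runif(n) < p_out, "outpatient", "inpatient")
  inp <- type == "inpatient"
  c_sched <- config$delta_sched * sample.int(10L, n, replace = TRUE)
  c_wait <- ifelse(inp,
                   stats::runif(n, 1 / 360, 1 / 36),
                   stats::runif(n, 1 / 180, 1 / 18))
  wl <- data.frame(
    id = seq_len(n),
    specialty = spec,
    group = grp,
    patient_type = type,
    mu = groups$mean_duration[gi],
    sigma = groups$sd_duration[gi],
    cv_class = cv,
    no_show_rate = ifelse(inp, config$no_show_inpatient,
                          config$no_show_outpatient),
    c_sched = c_sched,
    c_canc = ifelse(inp, 4, 2) * c_sched,
    c_wait = c_wait,
    stringsAsFactors = FALSE)
  class(wl) <- c("waiting_list", "data.frame")
  wl
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a surgical scheduling problem instance
#'
#' @param waiting_list A [generate_waiting_list()] data.frame (or compatible).
#' @param mss A [default_mss()] data.frame (or compatible).
#' @param config An [instance_config()].
#' @param seed Integer seed recorded with the instance.
#' @return An object of class `or_instance`.
#' @export
problem_instance <- function(waiting_list, mss = default_mss(),
                             config = instance_config(), seed = NA_integer_) {
  validate_mss(mss)
  need <- c("id", "specialty", "patient_type", "mu", "sigma",
            "no_show_rate", "c_sched", "c_canc", "c_wait")
  miss <- setdiff(need, names(waiting_list))
  if (length(miss))
    stop("waiting list lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(waiting_list$mu <= 0) || any(waiting_list$sigma <= 0))
    stop("patient durations mu, sigma must be positive", call. = FALSE)
  orphan <- setdiff(unique(waiting_list$specialty), unique(mss$specialty))
  if (length(orphan))
    stop("specialty without any MSS block: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  structure(list(waiting_list = waiting_list, mss = mss, config = config,
                 seed = seed),
            class = "or_instance")
}

#' Generate a complete synthetic instance
#'
#' Convenience wrapper: waiting list of size `n` from
#' [generate_waiting_list()] plus the default MSS and configuration.
#'
#' @inheritParams generate_waiting_list
#' @param mss Master surgery schedule (default [default_mss()]).
#' @return An `or_instance`.
#' @export
generate_instance <- function(n, config = instance_config(), seed = 1,
                              mss = default_mss()) {
  problem_instance(generate_waiting_list(n, config, seed), mss, config, seed)
}

#' @export
print.or_instance <- function(x, ...) {
  wl <- x$waiting_list
  cat("Surgical scheduling instance\n")
  cat(sprintf("  waiting list : %d patients (%d outpatient, %d inpatient)\n",
              nrow(wl), sum(wl$patient_type == "outpatient"),
              sum(wl$patient_type == "inpatient")))
  cat(sprintf("  MSS          : %d blocks, %d ORs, %d days\n",
              nrow(x$mss), length(unique(x$mss$or_id)),
              length(unique(x$mss$day))))
  cat(sprintf("  emergencies  : p = %.2f, lognormal(%g, %g) min, trunc %g\n",
              x$config$p_em, x$config$mu_em, x$config$sigma_em,
              x$config$em_truncation))
  invisible(x)
}

#' Write / read an instance as JSON
#'
#' The file has top-level keys `config`, `mss` and `patients` and
#' round-trips through [read_instance()] to an identical instance.
#'
#' @param instance An `or_instance`.
#' @param path File path.
#' @return `write_instance` returns `path` invisibly; `read_instance`
#'   returns the `or_instance`.
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "or_instance"))
  cfg <- unclass(instance$config)
  cfg$specialty_weights <- as.list(cfg$specialty_weights)  # keep names
  obj <- list(config = cfg,
              mss = as.data.frame(instance$mss),
              patients = as.data.frame(instance$waiting_list),
              seed = instance$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("config", "mss", "patients"))
    if (is.null(obj[[k]]))
      stop("instance file missing top-level field '", k, "'", call. = FALSE)
  cfgf <- obj$config
  need_cfg <- setdiff(names(formals(instance_config)), "specialty_weights")
  miss <- setdiff(need_cfg, names(cfgf))
  if (length(miss))
    stop("instance config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sw <- unlist(cfgf$specialty_weights)
  cfg <- do.call(instance_config,
                 c(cfgf[need_cfg], list(specialty_weights = sw)))
  mss <- as.data.frame(obj$mss)
  validate_mss(mss)
  class(mss) <- c("mss", "data.frame")
  wl <- as.data.frame(obj$patients)
  need_p <- c("id", "specialty", "patient_type", "mu", "sigma",
              "no_show_rate", "c_sched", "c_canc", "c_wait")
  miss <- setdiff(need_p, names(wl))
  if (length(miss))
    stop("patient records missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(wl) <- c("waiting_list", "data.frame")
  problem_instance(wl, mss, cfg,
                   seed = if (is.null(obj$seed)) NA_integer_ else obj$seed)
}

#' Export the waiting list as CSV (one row per patient)
#'
#' @param instance An `or_instance`.
#' @param path Output CSV path.
#' @export
write_patients_csv <- function(instance, path) {
  utils::write.csv(as.data.frame(instance$waiting_list), path,
                   row.names = FALSE)
  invisible(path)
}

# Blocks of one specialty, as a data.frame subset of the MSS.
blocks_of <- function(mss, specialty) {
  b <- mss[mss$specialty == specialty, , drop = FALSE]
  rownames(b) <- NULL
  b
}

# Stable key identifying a block.
block_key <- function(or_id, day) paste0("OR", or_id, ":d", day)
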