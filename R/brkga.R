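# Biased random-key genetic algorithm for the allocation stage.  A
# chromosome of length 2|I| encodes the full first stage of one block:
# the first |I| genes order the surgeries (increasing gene value), the
# second |I| genes split the scheduled idle time G = L - sum(mu) into
# slacks after each surgery (the last gene is the end-of-block slack).
# Every chromosome decodes to a feasible schedule, so the whole
# population explores the search space; fitness is the sample-average
# recourse cost.

#' BRKGA parameters
#'
#' Defaults follow a tuned configuration: population 50, elite fraction
#' 1/4, mutant fraction 1/5, elite gene inheritance probability 1/2.
#'
#' @param population Population size.
#' @param elite_fraction Fraction copied unchanged each generation.
#' @param mutant_fraction Fraction of fresh uniform individuals injected
#'   each generation.
#' @param inherit_prob Probability that an offspring gene comes from the
#'   elite parent.
#' @param max_generations Generation budget.
#' @param time_limit Optional wall-clock budget in seconds.
#' @param seed Integer seed.
#' @return Object of class `brkga_config`.
#' @export
brkga_config <- function(population = 50, elite_fraction = 1 / 4,
                         mutant_fraction = 1 / 5, inherit_prob = 1 / 2,
                         max_generations = 100, time_limit = Inf,
                         seed = 1) {
  if (elite_fraction + mutant_fraction >= 1)
    stop("elite_fraction + mutant_fraction must be < 1", call. = FALSE)
  if (inherit_prob <= 0 || inherit_prob >= 1)
    stop("inherit_prob must lie in (0, 1)", call. = FALSE)
  structure(list(population = as.integer(population),
                 elite_fraction = elite_fraction,
                 mutant_fraction = mutant_fraction,
                 inherit_prob = inherit_prob,
                 max_generations = as.integer(max_generations),
                 time_limit = time_limit, seed = seed),
            class = "brkga_config")
}

#' Decode a chromosome into a block schedule
#'
#' Surgeries are sequenced in increasing order of the first `|I|` genes
#' (ties broken by patient id, ascending).  The scheduled idle time
#' `G = L - sum(mu)` is split proportionally to the second `|I|` genes:
#' the slack after the k-th surgery in the sequence is
#' `gene_k / sum(all timing genes) * G`, the last share being the
#' end-of-block slack.  If all timing genes are zero the schedule is
#' back-to-back.  Decoded schedules always satisfy the first-stage
#' constraints (start at 0, no overlap, planned completions within `L`).
#'
#' @param chromosome Numeric vector in `[0, 1]` of length `2 * nrow(patients)`.
#' @param block One MSS row.
#' @param patients Waiting-list rows assigned to the block.
#' @return A [block_schedule()].
#' @export
decode_chromosome <- function(chromosome, block, patients) {
  n <- nrow(patients)
  if (length(chromosome) != 2 * n)
    stop("chromosome must have length 2 * |I|", call. = FALSE)
  if (any(chromosome < 0 | chromosome > 1))
    stop("genes must lie in [0, 1]", call. = FALSE)
  L <- block$length
  if (sum(patients$mu) > L + 1e-9)
    stop("assigned EOTs exceed block length", call. = FALSE)
  ord <- order(chromosome[seq_len(n)], patients$id)
  timing <- chromosome[n + seq_len(n)]
  G <- L - sum(patients$mu)
  tot <- sum(timing)
  slack <- if (tot > 0) timing / tot * G else rep(0, n)
  mu_seq <- patients$mu[ord]
  t <- numeric(n)
  if (n > 1)
    t[2:n] <- cumsum(mu_seq[-n] + slack[-n])
  block_schedule(block, patients[ord, , drop = FALSE], t)
}

#' Evolve a BRKGA over one block
#'
#' Standard biased random-key evolution: the initial population is
#' uniform on `[0, 1]^(2|I|)`; each generation copies the elites, injects
#' fresh mutants, and fills the remainder by biased crossover between a
#' uniformly drawn elite parent and a uniformly drawn non-elite parent
#' (each gene inherited from the elite with probability `inherit_prob`).
#' Fitness is the sample-average recourse cost of the decoded schedule.
#' Terminates on the generation budget or the time limit; deterministic
#' under the seed.
#'
#' @param block One MSS row.
#' @param patients Waiting-list rows assigned to the block.
#' @param sample `scenario_sample` used for fitness.
#' @param config Instance configuration (costs).
#' @param brkga A [brkga_config()].
#' @return An `allocation_solution` with `method = "brkga"`, the decoded
#'   best-ever schedule, its full-sample `expected_cost`, and the
#'   per-generation best-fitness `trace`.
#' @export
brkga_evolve <- function(block, patients, sample, config,
                         brkga = brkga_config()) {
  n <- nrow(patients)
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(brkga$seed, kind = 5L,
                          index = block$or_id * 100 + block$day))
  P <- brkga$population
  n_elite <- max(1L, as.integer(floor(P * brkga$elite_fraction)))
  n_mut <- as.integer(floor(P * brkga$mutant_fraction))
  n_cross <- P - n_elite - n_mut
  glen <- 2L * n

  fitness_of <- function(pop) {
    vapply(seq_len(nrow(pop)), function(k) {
      sched <- decode_chromosome(pop[k, ], block, patients)
      mean(evaluate_block_sample(sched, sample, config)$cost)
    }, numeric(1))
  }

  pop <- matrix(stats::runif(P * glen), P, glen)
  fit <- fitness_of(pop)
  ordP <- order(fit)
  pop <- pop[ordP, , drop = FALSE]; fit <- fit[ordP]
  best <- list(genes = pop[1, ], fitness = fit[1])
  trace <- numeric(brkga$max_generations + 1L)
  trace[1] <- fit[1]
  t0 <- proc.time()[["elapsed"]]
  gen <- 0L
  while (gen < brkga$max_generations &&
         proc.time()[["elapsed"]] - t0 < brkga$time_limit) {
    gen <- gen + 1L
    elites <- pop[seq_len(n_elite), , drop = FALSE]
    mutants <- matrix(stats::runif(n_mut * glen), n_mut, glen)
    ep <- sample.int(n_elite, n_cross, replace = TRUE)
    np_ <- n_elite + sample.int(P - n_elite, n_cross, replace = TRUE)
    inherit <- matrix(stats::runif(n_cross * glen) < brkga$inherit_prob,
                      n_cross, glen)
    offspring <- ifelse(inherit,
                        pop[ep, , drop = FALSE],
                        pop[np_, , drop = FALSE])
    newpop <- rbind(elites, mutants, offspring)
    newfit <- c(fit[seq_len(n_elite)],
                fitness_of(newpop[-seq_len(n_elite), , drop = FALSE]))
    ordP <- order(newfit)
    pop <- newpop[ordP, , drop = FALSE]; fit <- newfit[ordP]
    if (fit[1] < best$fitness) best <- list(genes = pop[1, ],
                                            fitness = fit[1])
    trace[gen + 1L] <- best$fitness
  }
  schedule <- decode_chromosome(best$genes, block, patients)
  structure(list(schedule = schedule,
                 expected_cost = expected_cost(schedule, sample, config),
                 objective = best$fitness, gap = NA_real_,
                 status = "feasible", method = "brkga",
                 generations = gen, trace = trace[seq_len(gen + 1L)]),
            class = "allocation_solution")
}
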