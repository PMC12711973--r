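# Shared fixtures and independent oracles for the test suite.

# Small instance restricted to one specialty and a reduced MSS, so MILPs
# stay tiny.  Patients are the first `n` of the given specialty from a
# generated waiting list.
micro_instance <- function(n_patients = 6, n_blocks = 2, seed = 1,
                           specialty = "URO", pool = 80,
                           smallest = FALSE) {
  base <- generate_instance(pool, seed = seed)
  wl <- base$waiting_list
  pats <- wl[wl$specialty == specialty, , drop = FALSE]
  if (smallest) pats <- pats[order(pats$mu), , drop = FALSE]
  pats <- pats[seq_len(n_patients), ]
  mss <- base$mss[base$mss$specialty == specialty, , drop = FALSE]
  mss <- mss[seq_len(min(n_blocks, nrow(mss))), , drop = FALSE]
  class(mss) <- c("mss", "data.frame")
  problem_instance(pats, mss, base$config, seed = seed)
}

# Degenerate scenario sample: rho = mu, everyone present, no emergencies.
degenerate_sample <- function(instance, n = 1) {
  s <- sample_scenarios(instance, n, seed = 1)
  s$rho <- matrix(rep(instance$waiting_list$mu, each = n), n,
                  dimnames = dimnames(s$rho))
  s$theta[] <- 1L
  s$em_duration[] <- 0
  s$em_arrival[] <- 0
  s
}

# Brute-force oracle for the advance CCIP: enumerates every assignment of
# patients to (none, block 1, ..., block nb), applies the capacity and
# sampled chance constraints directly, and evaluates the hierarchical
# objective from first principles.
brute_advance <- function(patients, blocks, sample, config) {
  np <- nrow(patients); nb <- nrow(blocks)
  coef <- hierarchy_coefficients(patients, blocks)
  ids <- as.character(patients$id)
  keys <- orsched:::block_key(blocks$or_id, blocks$day)
  load <- sample$rho[, ids, drop = FALSE] * sample$theta[, ids, drop = FALSE]
  em <- sample$em_duration[, keys, drop = FALSE]
  budget <- floor(config$alpha * sample$size)
  beta <- config$beta
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(0:nb), np)))
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    xmat <- matrix(0L, np, nb)
    for (i in seq_len(np)) if (asg[i] > 0) xmat[i, asg[i]] <- 1L
    ok <- TRUE
    for (b in seq_len(nb)) {
      sel <- xmat[, b] == 1
      if (sum(patients$mu[sel]) > blocks$length[b] + 1e-9) {
        ok <- FALSE; break
      }
      tot <- em[, b] +
        (if (any(sel)) rowSums(load[, sel, drop = FALSE]) else 0)
      cap <- blocks$length[b] + blocks$max_overtime[b]
      if (sum(tot > cap) > budget) { ok <- FALSE; break }
    }
    if (!ok) next
    px <- orsched:::advance_proxies(xmat, patients, blocks, sample)
    sched <- rowSums(xmat) > 0
    obj <- sum(patients$c_sched[!sched]) +
      coef$b1 * (beta[1] * px$gamma_canc +
                   beta[2] * coef$b2 * px$gamma_wait +
                   beta[3] * coef$b3 * px$gamma_time)
    if (obj < best) best <- obj
  }
  best
}

# All permutations of 1..n (small n).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Back-to-back schedule for a permutation of the patient rows.
btb_schedule <- function(block, patients, perm) {
  p <- patients[perm, , drop = FALSE]
  t <- c(0, cumsum(p$mu))[seq_len(nrow(p))]
  block_schedule(block, p, t)
}
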