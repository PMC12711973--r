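test_that("degenerate realization reproduces the planned timeline", {
  inst <- micro_instance(3, 1, seed = 2)
  blk <- inst$mss[1, ]
  pats <- inst$waiting_list
  sched <- btb_schedule(blk, pats, seq_len(3))
  s <- degenerate_sample(inst, 1)
  out <- simulate_block(sched, s, inst$config, w = 1)
  expect_equal(out$patients$waiting, rep(0, 3))
  expect_equal(out$overtime, 0)
  expect_equal(out$idle, blk$length - sum(pats$mu))
  expect_equal(out$cost, inst$config$c_idle * (blk$length - sum(pats$mu)))
  expect_true(all(out$patients$y == 1))
  expect_equal(out$C, sum(pats$mu))
})

test_that("a surgery that cannot finish within L + H is cancelled", {
  inst2 <- micro_instance(2, 1, seed = 3)
  p2 <- inst2$waiting_list
  p2$mu <- c(200, 270)
  p2$sigma <- c(20, 20)
  p2$no_show_rate <- 0
  inst2 <- problem_instance(p2, inst2$mss, inst2$config)
  sched2 <- btb_schedule(inst2$mss[1, ], p2, 1:2)
  s2 <- sample_scenarios(inst2, 1, seed = 1)
  s2$rho[1, ] <- c(480, 100)  # first runs the whole block + more
  s2$theta[] <- 1L
  s2$em_duration[] <- 0; s2$em_arrival[] <- 0
  out <- simulate_block(sched2, s2, inst2$config, w = 1)
  # second patient would start at 480, 480 + 270 > 540 => cancelled
  expect_equal(out$patients$y, c(1, 0))
  expect_equal(out$canc_cost, p2$c_canc[2])
  expect_equal(out$patients$waiting[2], 0)
  expect_equal(out$C, 480)
  # conservation: max(L, C) = executed work + idle
  expect_equal(max(480, out$C), unname(s2$rho[1, 1]) + out$idle)
})

test_that("no-shows collapse their slot without any cost", {
  inst <- micro_instance(3, 1, seed = 5)
  p <- inst$waiting_list
  p$no_show_rate <- 0
  inst <- problem_instance(p, inst$mss, inst$config)
  sched <- btb_schedule(inst$mss[1, ], p, 1:3)
  s <- degenerate_sample(inst, 1)
  s$theta[1, 2] <- 0L
  out <- simulate_block(sched, s, inst$config, w = 1)
  expect_equal(out$patients$y[2], 1)           # no-shows are never "cancelled"
  expect_equal(out$canc_cost, 0)
  expect_equal(out$patients$qhat[2], out$patients$chat[2])
  # the third surgery cannot be anticipated
  expect_equal(out$patients$qhat[3], sched$start_times[3])
  expect_equal(out$idle, inst$mss$length[1] - p$mu[1] - p$mu[3])
})

test_that("emergency insertion follows the as-soon-as-possible policy", {
  inst <- micro_instance(2, 1, seed = 6)
  p <- inst$waiting_list
  p$mu <- c(100, 100); p$no_show_rate <- 0
  inst <- problem_instance(p, inst$mss, inst$config)
  blk <- inst$mss[1, ]
  sched <- block_schedule(blk, p, c(0, 150))
  s <- degenerate_sample(inst, 1)
  key <- orsched:::block_key(blk$or_id, blk$day)

  # arrival mid-surgery: emergency waits for the running surgery
  s$em_duration[1, key] <- 60; s$em_arrival[1, key] <- 40
  out <- simulate_block(sched, s, inst$config, w = 1)
  expect_equal(out$em_start, 100)
  expect_equal(emergency_wait(out), 60)
  expect_equal(out$patients$e, c(1, 0))
  expect_equal(out$patients$z, c(0, 0))
  # second elective pushed to the emergency completion
  expect_equal(out$patients$qhat[2], 160)
  expect_equal(out$patients$waiting[2], 10)

  # arrival while the OR is idle: starts immediately, z > 0
  s$em_arrival[1, key] <- 120
  out2 <- simulate_block(sched, s, inst$config, w = 1)
  expect_equal(out2$em_start, 120)
  expect_equal(emergency_wait(out2), 0)
  expect_equal(out2$patients$z, c(20, 0))
  expect_equal(out2$patients$qhat[2], 180)

  # arrival after the last start: appended at the end
  s$em_arrival[1, key] <- 260
  out3 <- simulate_block(sched, s, inst$config, w = 1)
  expect_equal(out3$patients$e, c(0, 1))
  expect_equal(out3$em_start, 260)
  expect_equal(out3$C, 320)

  # no emergency => asking for its wait is an error
  s$em_duration[1, key] <- 0; s$em_arrival[1, key] <- 0
  out4 <- simulate_block(sched, s, inst$config, w = 1)
  expect_error(emergency_wait(out4), "no emergency")
})

test_that("conservation and monotonicity hold across random realizations", {
  inst <- micro_instance(4, 1, seed = 7)
  blk <- inst$mss[1, ]
  p <- inst$waiting_list
  sched <- btb_schedule(blk, p, order(p$mu))
  s <- sample_scenarios(inst, 300, seed = 8)
  res <- orsched:::evaluate_block_sample(sched, s, inst$config)
  tot_exec <- rowSums(s$rho[, as.character(sched$patients$id)] *
                        res$exec)
  key <- orsched:::block_key(blk$or_id, blk$day)
  em <- s$em_duration[, key] *
    as.integer(!is.na(res$em_after[, 1]))
  expect_equal(pmax(blk$length, res$C), tot_exec + em + res$idle,
               tolerance = 1e-9)
  expect_true(all(res$a >= -1e-12))
  expect_true(all(res$idle >= -1e-9))
  expect_true(all(res$overtime >= -1e-12))

  # increasing one rho never shortens the block
  w <- which(s$em_duration[, key] == 0)[1]
  for (fac in c(1.2, 1.6, 2.5)) {
    s2 <- s
    s2$rho[w, 1] <- s$rho[w, 1] * fac
    r2 <- orsched:::evaluate_block_sample(sched, s2, inst$config)
    expect_gte(r2$C[w], res$C[w] - 1e-9)
  }
})

test_that("expected cost is the arithmetic scenario mean", {
  inst <- micro_instance(3, 1, seed = 9)
  sched <- btb_schedule(inst$mss[1, ], inst$waiting_list, 1:3)
  s <- sample_scenarios(inst, 2, seed = 10)
  c1 <- simulate_block(sched, s, inst$config, w = 1)$cost
  c2 <- simulate_block(sched, s, inst$config, w = 2)$cost
  expect_equal(expected_cost(sched, s, inst$config), (c1 + c2) / 2)
  # identical scenarios: the mean is the single-scenario cost
  s1 <- orsched:::subset_scenarios(s, c(1, 1, 1))
  expect_equal(expected_cost(sched, s1, inst$config), c1)
  expect_error(expected_cost(sched, list()), "scenario_sample")
})

test_that("algorithmic recourse equals the second-stage MILP optimum", {
  # spot equivalence here (the 200-case audit lives in the acceptance
  # suite): random schedules and scenarios, with and without emergencies
  inst <- micro_instance(3, 1, seed = 11)
  blk <- inst$mss[1, ]
  p <- inst$waiting_list
  s <- sample_scenarios(inst, 12, seed = 12)
  set.seed(99)
  sched <- decode_chromosome(runif(6), blk, p)
  models <- list(); costs <- numeric(0)
  for (w in seq_len(12)) {
    sub <- orsched:::subset_scenarios(s, w)
    built <- orsched:::build_saa_milp(
      blk, sched$patients, sub, inst$config,
      fixed = list(order = sched$patients$id,
                   start_times = sched$start_times))
    models[[w]] <- built
    costs[w] <- simulate_block(sched, s, inst$config, w = w)$cost
  }
  res <- orsched:::milp_solve_batch(lapply(models, `[[`, "model"),
                                    mip_rel_gap = 1e-9)
  milp_costs <- vapply(seq_len(12), function(w)
    res[[w]]$objective + models[[w]]$const, numeric(1))
  expect_equal(milp_costs, costs, tolerance = 1e-6)
})
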