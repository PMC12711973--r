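test_that("hierarchy coefficients follow their defining formulas", {
  pats <- data.frame(id = 1:3, mu = c(20, 60, 100), sigma = c(3, 9, 15),
                     c_sched = c(10, 50, 100), c_canc = c(40, 200, 400),
                     c_wait = c(1 / 36, 1 / 18, 1 / 100))
  blocks <- data.frame(or_id = 1:2, day = 1, length = c(480, 480),
                       max_overtime = 60)
  hc <- hierarchy_coefficients(pats, blocks, delta_sched = 10)
  expect_equal(hc$m_s, 24)                       # floor(480 / 20)
  expect_equal(hc$b2, 400 / (1 / 18))            # 7200
  expect_equal(hc$b3, 24 * 400 / (2 * 480 / 2))
  expect_equal(hc$b1, 10 / (1 + 24 * 400))
  pats$c_wait <- 0
  expect_error(hierarchy_coefficients(pats, blocks), "waiting cost")
  expect_error(hierarchy_coefficients(pats[0, ], blocks), "nonempty")
})

test_that("degenerate scenarios make the chance constraint redundant", {
  inst <- micro_instance(4, 2, seed = 21)
  s <- degenerate_sample(inst, 20)
  cfg <- advance_config(alpha = 0.05, beta = c(1, 0, 0), time_limit = 60)
  sol <- solve_advance(inst, cfg, s, "URO")
  expect_identical(sol$status, "optimal")
  # deterministic load mu <= L <= L + H in every scenario: no overloads
  expect_true(all(sol$overload == 0))
  # with ample capacity everyone is scheduled
  expect_equal(nrow(sol$assignment), 4)
  expect_equal(sol$unsched_cost, 0)
})

test_that("advance MILP optimum matches exhaustive enumeration", {
  for (sd_ in 1:3) {
    inst <- micro_instance(5, 2, seed = 30 + sd_)
    s <- sample_scenarios(inst, 50, seed = 60 + sd_)
    cfg <- advance_config(alpha = 0.1, beta = c(0.2, 0.3, 0.5),
                          time_limit = 60)
    sol <- solve_advance(inst, cfg, s, "URO")
    bf <- brute_advance(inst$waiting_list,
                        orsched:::blocks_of(inst$mss, "URO"), s, cfg)
    expect_equal(sol$objective, bf, tolerance = 1e-8)
  }
})

test_that("relaxing alpha can only improve the optimum", {
  inst <- micro_instance(7, 2, seed = 41)
  s <- sample_scenarios(inst, 60, seed = 42)
  objs <- vapply(c(0.05, 0.15), function(a) {
    solve_advance(inst, advance_config(alpha = a, beta = c(0, 0, 1),
                                       time_limit = 60), s,
                  "URO")$objective
  }, numeric(1))
  expect_lte(objs[2], objs[1] + 1e-9)
})

test_that("the hierarchy makes beta irrelevant to the scheduled set when unique", {
  # capacity for all patients: the unique min-cost set schedules everyone,
  # so the top level is identical across the three unit beta vectors
  inst <- micro_instance(5, n_blocks = 3, seed = 44, smallest = TRUE)
  s <- sample_scenarios(inst, 40, seed = 45)
  sc <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(b) {
    solve_advance(inst, advance_config(alpha = 0.15, beta = b,
                                       time_limit = 60), s,
                  "URO")$sched_cost
  }, numeric(1))
  expect_equal(sc[1], sc[2])
  expect_equal(sc[1], sc[3])
})

test_that("each proxy is minimized when its weight is enabled", {
  inst <- micro_instance(6, 2, seed = 47)
  s <- sample_scenarios(inst, 40, seed = 48)
  sols <- lapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(b)
    solve_advance(inst, advance_config(alpha = 0.15, beta = b,
                                       time_limit = 60), s, "URO"))
  expect_lte(sols[[1]]$gamma_canc,
             min(sols[[2]]$gamma_canc, sols[[3]]$gamma_canc) + 1e-8)
  expect_lte(sols[[2]]$gamma_wait,
             min(sols[[1]]$gamma_wait, sols[[3]]$gamma_wait) + 1e-8)
  expect_lte(sols[[3]]$gamma_time,
             min(sols[[1]]$gamma_time, sols[[2]]$gamma_time) + 1e-8)
})

test_that("the post-hoc audit respects alpha on the training sample", {
  inst <- micro_instance(8, 2, seed = 51)
  s <- sample_scenarios(inst, 100, seed = 52)
  cfg <- advance_config(alpha = 0.1, beta = c(0, 0, 1), time_limit = 60)
  sol <- solve_advance(inst, cfg, s, "URO")
  audit <- overload_probabilities(sol, inst, s)
  expect_true(all(audit <= 0.1 + 1e-12))
  # assignment satisfies the deterministic EOT capacity too
  blocks <- orsched:::blocks_of(inst$mss, "URO")
  for (b in seq_len(nrow(blocks))) {
    ids <- sol$assignment$patient_id[
      sol$assignment$or_id == blocks$or_id[b] &
        sol$assignment$day == blocks$day[b]]
    expect_lte(sum(inst$waiting_list$mu[inst$waiting_list$id %in% ids]),
               blocks$length[b] + 1e-9)
  }
})
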