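test_that("single-surgery blocks start at zero with the scenario cost", {
  inst <- micro_instance(1, 1, seed = 61)
  blk <- inst$mss[1, ]
  s <- sample_scenarios(inst, 1, seed = 62)
  sol <- solve_saa(blk, inst$waiting_list, s, inst$config,
                   allocation_config("saa", time_limit = 30))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$schedule$start_times, 0)
  expect_equal(sol$objective,
               simulate_block(sol$schedule, s, inst$config, w = 1)$cost,
               tolerance = 1e-6)
})

test_that("the SAA objective equals the recourse mean of its incumbent", {
  inst <- micro_instance(3, 1, seed = 63)
  s <- sample_scenarios(inst, 10, seed = 64)
  sol <- solve_saa(inst$mss[1, ], inst$waiting_list, s, inst$config,
                   allocation_config("saa", time_limit = 90))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, sol$expected_cost, tolerance = 1e-6)
  # the optimum lower-bounds every back-to-back permutation
  perms <- permutations(3)
  for (k in seq_len(nrow(perms))) {
    sc <- btb_schedule(inst$mss[1, ], inst$waiting_list, perms[k, ])
    expect_lte(sol$objective, expected_cost(sc, s, inst$config) + 1e-6)
  }
})

test_that("degenerate SAA reproduces the deterministic optimum", {
  inst <- micro_instance(4, 1, seed = 65)
  p <- inst$waiting_list; p$no_show_rate <- 0
  inst <- problem_instance(p, inst$mss, inst$config)
  s <- degenerate_sample(inst, 1)
  sol <- solve_saa(inst$mss[1, ], p, s, inst$config,
                   allocation_config("saa", time_limit = 90))
  expect_identical(sol$status, "optimal")
  # closed form: all surgeries run as planned, cost = idle only
  expect_equal(sol$objective,
               inst$config$c_idle * (inst$mss$length[1] - sum(p$mu)),
               tolerance = 1e-6)
  # brute force over permutations agrees
  perms <- permutations(4)
  brute <- min(vapply(seq_len(nrow(perms)), function(k)
    expected_cost(btb_schedule(inst$mss[1, ], p, perms[k, ]), s,
                  inst$config), numeric(1)))
  expect_equal(sol$objective, brute, tolerance = 1e-6)
})

test_that("N-fold SAA returns the best full-sample re-evaluation", {
  inst <- micro_instance(3, 1, seed = 66)
  s <- sample_scenarios(inst, 20, seed = 67)
  sol <- solve_nfold_saa(inst$mss[1, ], inst$waiting_list, s,
                         inst$config,
                         allocation_config("nfold", N = 4,
                                           time_limit = 120))
  expect_true(sol$status %in% c("optimal", "feasible"))
  ok <- !is.na(sol$fold_costs)
  expect_true(any(ok))
  expect_equal(sol$expected_cost, min(sol$fold_costs[ok]))
  # reported value is the recourse re-evaluation on the whole sample
  expect_equal(sol$expected_cost,
               expected_cost(sol$schedule, s, inst$config))
  # N = 1 coincides with plain SAA under the same budget
  sol1 <- solve_nfold_saa(inst$mss[1, ], inst$waiting_list, s,
                          inst$config,
                          allocation_config("nfold", N = 1,
                                            time_limit = 60))
  saa <- solve_saa(inst$mss[1, ], inst$waiting_list, s, inst$config,
                   allocation_config("saa", time_limit = 60))
  expect_equal(sol1$expected_cost, saa$expected_cost, tolerance = 1e-6)
})

test_that("an exhausted budget degrades gracefully, never crashes", {
  inst <- micro_instance(6, 1, seed = 68, pool = 150, smallest = TRUE)
  s <- sample_scenarios(inst, 60, seed = 69)
  sol <- solve_saa(inst$mss[1, ], inst$waiting_list, s, inst$config,
                   allocation_config("saa", time_limit = 0.05))
  expect_true(sol$status %in% c("optimal", "feasible",
                                "infeasible_within_limit"))
  if (sol$status == "infeasible_within_limit") {
    expect_null(sol$schedule)
    expect_true(is.na(sol$expected_cost))
  }
})

test_that("more overtime can only lower the SAA optimum", {
  inst <- micro_instance(3, 1, seed = 71)
  s <- sample_scenarios(inst, 10, seed = 72)
  objs <- vapply(c(0, 60), function(H) {
    mssH <- inst$mss; mssH$max_overtime <- H
    solve_saa(mssH[1, ], inst$waiting_list, s, inst$config,
              allocation_config("saa", time_limit = 90))$objective
  }, numeric(1))
  expect_lte(objs[2], objs[1] + 1e-6)
})
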