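make_schedules <- function(inst, seed = 1) {
  # deterministic schedules: assigned greedily per block, uniform slack
  set.seed(seed)
  wl <- inst$waiting_list
  mss <- inst$mss
  scheds <- list()
  used <- integer(0)
  for (b in seq_len(nrow(mss))) {
    pool <- wl[wl$specialty == mss$specialty[b] & !(wl$id %in% used), ]
    take <- integer(0); tot <- 0
    for (i in seq_len(nrow(pool))) {
      if (tot + pool$mu[i] <= mss$length[b]) {
        take <- c(take, pool$id[i]); tot <- tot + pool$mu[i]
      }
    }
    if (!length(take)) next
    p <- wl[wl$id %in% take, ]
    key <- orsched:::block_key(mss$or_id[b], mss$day[b])
    scheds[[key]] <- decode_chromosome(
      c(runif(nrow(p)), rep(0.5, nrow(p))), mss[b, ], p)
    used <- c(used, take)
  }
  scheds
}

test_that("Bernoulli-mode evaluation agrees with the recourse kernel", {
  inst <- generate_instance(40, seed = 91)
  scheds <- make_schedules(inst)
  n <- 200
  rep_ <- evaluate_schedule(scheds, inst, n, "bernoulli", seed = 92)
  s <- sample_scenarios(inst, n, seed = 92)
  # recompute one scheduled block by hand with the recourse kernel
  key <- names(scheds)[1]
  res <- orsched:::evaluate_block_sample(scheds[[key]], s, inst$config)
  row <- rep_$per_block[rep_$per_block$block == key, ]
  expect_equal(row$over_cost, mean(res$over_cost))
  expect_equal(row$idle_cost, mean(res$idle_cost))
  expect_equal(row$canc_cost, mean(res$canc_cost))
  expect_equal(row$wait_cost, mean(res$wait_cost))
  # objective is the sum of the four component means
  expect_equal(rep_$objective,
               rep_$over_cost + rep_$idle_cost + rep_$canc_cost +
                 rep_$wait_cost, tolerance = 1e-9)
  expect_error(evaluate_schedule(scheds, inst, 10, "weird"), "mode")
})

test_that("Poisson mode with p_em = 0 reduces to no emergencies", {
  inst <- generate_instance(30, seed = 93)
  inst$config$p_em <- 0
  scheds <- make_schedules(inst)
  a <- evaluate_schedule(scheds, inst, 100, "bernoulli", seed = 94)
  b <- evaluate_schedule(scheds, inst, 100, "poisson", seed = 94)
  expect_equal(a$objective, b$objective, tolerance = 1e-12)
  expect_true(is.na(a$mean_emergency_wait))
})

test_that("queued emergencies wait for one another (FIFO insertion)", {
  inst <- generate_instance(10, seed = 95)
  wl <- inst$waiting_list[1, , drop = FALSE]
  wl$mu <- 200; wl$sigma <- 10; wl$no_show_rate <- 0
  inst <- problem_instance(wl, inst$mss[inst$mss$specialty ==
                                          wl$specialty, ], inst$config)
  blk <- inst$mss[1, ]
  sched <- block_schedule(blk, wl, 0)
  s <- degenerate_sample(inst, 1)
  sl <- orsched:::schedule_scenario_slices(sched, s)
  # two emergencies arriving during the elective surgery: the second
  # starts only after the first completes
  res <- orsched:::sim_block_core(
    t = 0, mu = 200, L = blk$length, H = blk$max_overtime,
    rho = sl$rho, theta = sl$theta,
    em_arr = matrix(c(50, 60), 1), em_dur = matrix(c(30, 40), 1),
    c_canc = wl$c_canc, c_wait = wl$c_wait,
    c_idle = inst$config$c_idle, c_over = inst$config$c_over)
  expect_equal(res$em_start[1, ], c(200, 230))
  expect_equal(res$em_wait[1, ], c(150, 170))
  expect_gte(res$em_wait[1, 2], res$em_wait[1, 1])
  # conservation with two emergencies
  expect_equal(pmax(blk$length, res$C), 200 + 30 + 40 + res$idle)
})

test_that("per-class metrics match a hand-computed fixture", {
  pp <- data.frame(
    patient_type = c("inpatient", "inpatient", "outpatient", "outpatient"),
    scheduled_start = c(0, 0, 100, 200),
    waiting = c(10, 0, 30, 0),
    cancelled = c(0, 0, 0, 1),
    present = c(1, 0, 1, 1))
  cm <- class_metrics(pp)
  inp <- cm[cm$class == "inpatient", ]
  out <- cm[cm$class == "outpatient", ]
  expect_equal(inp$mean_scheduled_start, 0)
  expect_equal(inp$mean_waiting, 5)
  expect_equal(inp$cancellation_probability, 0)   # only the present count
  expect_equal(out$mean_scheduled_start, 150)
  expect_equal(out$mean_waiting, 15)
  expect_equal(out$cancellation_probability, 0.5)
  # single-class input flags the other class as absent
  cm1 <- class_metrics(pp[pp$patient_type == "inpatient", ])
  expect_equal(cm1[cm1$class == "outpatient", ]$n, 0)
  expect_true(is.na(cm1[cm1$class == "outpatient",
                        ]$cancellation_probability))
  expect_true(all(cm$cancellation_probability >= 0 &
                    cm$cancellation_probability <= 1, na.rm = TRUE))
})
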