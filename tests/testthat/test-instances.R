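test_that("procedure group catalogue matches the reference mixtures", {
  pg <- default_procedure_groups()
  expect_equal(nrow(pg), 28)
  expect_equal(unname(table(pg$specialty)[c("CARDIO", "GASTRO", "GYN",
                                            "ORTH", "URO")]),
               c(7L, 7L, 5L, 5L, 4L), ignore_attr = TRUE)
  uro <- pg[pg$specialty == "URO", ]
  expect_equal(uro$mean_duration, c(32.1, 58.1, 94.7, 208.8))
  for (s in unique(pg$specialty))
    expect_equal(sum(pg$frequency[pg$specialty == s]), 1, tolerance = 1e-12)
  # classification by the coefficient of variation
  expect_true(all((pg$sd_duration / pg$mean_duration < 0.175) ==
                    (pg$cv_class == "LCV")))
  # the long LCV urology group sits below the split
  g4 <- uro[uro$mean_duration == 208.8, ]
  expect_identical(g4$cv_class, "LCV")
})

test_that("default MSS has 26 blocks with the reference per-OR pattern", {
  m <- default_mss()
  expect_equal(nrow(m), 26)
  expect_equal(length(unique(m$or_id)), 9)
  expect_true(all(m$day %in% 1:5))
  expect_true(all(m$specialty[m$or_id == 3] == "CARDIO"))
  expect_equal(nrow(m[m$or_id == 2, ]), 5)
  expect_equal(nrow(m[m$or_id == 9 & m$day == 1, ]), 0)  # OR9 Monday empty
  expect_false(anyDuplicated(m[c("or_id", "day")]) > 0)
  counts <- table(m$specialty)
  expect_equal(counts[["ORTH"]], 7)
  expect_equal(counts[["CARDIO"]], 3)
})

test_that("waiting-list generation follows the population sampling rules", {
  cfg <- instance_config()
  wl <- generate_waiting_list(10000, cfg, seed = 42)
  expect_equal(nrow(wl), 10000)
  # scheduling costs uniform on {10,...,100}: mean 55 within MC noise
  expect_gt(mean(wl$c_sched), 53)
  expect_lt(mean(wl$c_sched), 57)
  expect_true(all(wl$c_sched %in% seq(10, 100, 10)))
  inp <- wl$patient_type == "inpatient"
  expect_true(all(wl$c_canc[inp] == 4 * wl$c_sched[inp]))
  expect_true(all(wl$c_canc[!inp] == 2 * wl$c_sched[!inp]))
  expect_true(all(wl$no_show_rate[inp] == 0.08))
  expect_true(all(wl$no_show_rate[!inp] == 0.24))
  expect_true(all(wl$c_wait[inp] >= 1 / 360 & wl$c_wait[inp] <= 1 / 36))
  expect_true(all(wl$c_wait[!inp] >= 1 / 180 & wl$c_wait[!inp] <= 1 / 18))
  # EOT/SD inherited from the group table
  pg <- default_procedure_groups()
  gi <- match(paste(wl$specialty, wl$group),
              paste(pg$specialty, pg$group))
  expect_equal(wl$mu, pg$mean_duration[gi])
  expect_equal(wl$sigma, pg$sd_duration[gi])
})

test_that("specialty mix and outpatient share match their analytic values", {
  cfg <- instance_config()
  wl <- generate_waiting_list(1e5, cfg, seed = 7)
  tab <- table(factor(wl$specialty, levels = names(cfg$specialty_weights)))
  chi <- suppressWarnings(
    stats::chisq.test(tab, p = cfg$specialty_weights))
  expect_gt(chi$p.value, 0.01)
  # P(outpatient) = 0.7 P(LCV) + 0.3 P(HCV), P(LCV) from the group table
  pg <- default_procedure_groups()
  p_lcv <- sum(vapply(names(cfg$specialty_weights), function(s) {
    g <- pg[pg$specialty == s, ]
    cfg$specialty_weights[[s]] * sum(g$frequency[g$cv_class == "LCV"])
  }, numeric(1)))
  p_out <- 0.7 * p_lcv + 0.3 * (1 - p_lcv)
  se <- sqrt(p_out * (1 - p_out) / 1e5)
  expect_lt(abs(mean(wl$patient_type == "outpatient") - p_out), 3 * se)
})

test_that("generation is deterministic and validates its arguments", {
  a <- generate_waiting_list(50, seed = 3)
  b <- generate_waiting_list(50, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_waiting_list(50, seed = 4)))
  expect_error(generate_waiting_list(0), "n must be")
})

test_that("instance JSON round-trips and rejects malformed files", {
  inst <- generate_instance(20, seed = 2)
  f <- tempfile(fileext = ".json")
  write_instance(inst, f)
  back <- read_instance(f)
  expect_equal(back$waiting_list, inst$waiting_list, ignore_attr = TRUE)
  expect_equal(as.data.frame(back$mss), as.data.frame(inst$mss),
               ignore_attr = TRUE)
  expect_equal(unclass(back$config), unclass(inst$config),
               ignore_attr = TRUE)

  # drop a patient cost field
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$patients$c_canc <- NULL
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_instance(f2), "c_canc")

  # negative block length
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$mss$length[1] <- -480
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f3, auto_unbox = TRUE, digits = NA)
  expect_error(read_instance(f3), "length")
})

test_that("instances reject specialties with no MSS block", {
  inst <- generate_instance(30, seed = 1)
  mss <- inst$mss[inst$mss$specialty != "URO", ]
  wl <- inst$waiting_list
  if (!any(wl$specialty == "URO")) wl$specialty[1] <- "URO"
  expect_error(problem_instance(wl, mss, inst$config), "URO")
})
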