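test_that("stage initialization returns the fixed predefined points", {
  cfg <- algorithm_config()
  ring <- init_stage("ring", cfg)
  expect_length(ring, 3)
  expect_equal(vapply(ring, `[[`, numeric(1), "coord1"), c(0.5, 1.5, 2.5))
  expect_equal(vapply(ring, `[[`, numeric(1), "amplitude"), c(1.5, 2.5, 1.5))
  dir <- init_stage("directional", cfg)
  expect_length(dir, 4)
  expect_equal(vapply(dir, `[[`, numeric(1), "coord1"), c(0, 90, 180, 270))
  expect_error(init_stage("spiral", cfg))
  expect_error(algorithm_config(predefined_ring = init_stage("ring", cfg)[1:2]),
               "exactly 3")
})

test_that("suggestions maximize distance under uniform scores", {
  cfg <- algorithm_config()
  m <- score_map("ring")
  for (p in init_stage("ring", cfg)) m <- update_map(m, p, 2.0)
  sug <- suggest_next(m, 0, cfg)
  # oracle: brute-force argmax of nearest-explored distance over the lattice
  best_d <- -Inf; best <- NULL
  for (c1 in m$coord1_grid) for (a in m$amp_grid) {
    d <- min(vapply(seq_len(nrow(m$obs)), function(k) {
      sqrt(((c1 - m$obs$coord1[k]) / 3)^2 +
             ((a - m$obs$amplitude[k]) / diff(cfg$amp_range))^2)
    }, numeric(1)))
    if (d > best_d + 1e-12) { best_d <- d; best <- c(c1, a) }
  }
  expect_equal(c(sug$coord1, sug$amplitude), best)
})

test_that("pure exploitation suggests the map minimum", {
  cfg <- algorithm_config(beta0 = 0)
  m <- score_map("ring")
  for (p in init_stage("ring", cfg)) m <- update_map(m, p, 2.0)
  m <- update_map(m, exploration_point("ring", 0.9, 3.5), 0.4)
  sug <- suggest_next(m, 0, cfg)
  expect_equal(c(sug$coord1, sug$amplitude), c(0.9, 3.5))
})

test_that("side-effect caps exclude the map minimum from suggestions", {
  cfg <- algorithm_config(beta0 = 0)
  m <- score_map("ring")
  for (p in init_stage("ring", cfg)) m <- update_map(m, p, 2.0)
  m <- update_map(m, exploration_point("ring", 0.9, 3.5), 0.4,
                  side_effect = TRUE)
  sug <- suggest_next(m, 0, cfg)
  # the capped column blocks amplitudes >= 3.4 around coord 0.9
  expect_false(abs(sug$coord1 - 0.9) <= 0.5 && sug$amplitude >= 3.4)
})

test_that("convergence compares suggested-to-explored distance to the threshold", {
  cfg <- algorithm_config()
  m <- update_map(score_map("ring"), exploration_point("ring", 1.5, 3.0), 2)
  expect_true(check_convergence(exploration_point("ring", 1.5, 3.0), m, cfg))
  expect_true(check_convergence(exploration_point("ring", 1.6, 3.1), m, cfg))
  expect_false(check_convergence(exploration_point("ring", 3.0, 5.5), m, cfg))
})

test_that("a capped stage returns the best of the predefined points", {
  pat <- make_patient(7, "easy")
  spec <- patient_spec(pat)
  cfg <- algorithm_config(max_steps_per_stage = 3L)
  st <- run_stage(patient_responder(pat), "ring", spec, cfg)
  expect_equal(nrow(st$steps), 3L)
  expect_equal(st$best$score, min(st$steps$total_score))
  expect_false(st$converged)
})

test_that("sessions are deterministic and respect bounds", {
  pat <- make_patient(11, "clinical")
  spec <- patient_spec(pat)
  cfg <- algorithm_config()
  r1 <- run_hemisphere(patient_responder(pat), spec, cfg)
  r2 <- run_hemisphere(patient_responder(pat), spec, cfg)
  expect_identical(r1$steps, r2$steps)
  expect_true(all(r1$steps$amplitude >= cfg$amp_range[1] &
                    r1$steps$amplitude <= cfg$amp_range[2]))
  expect_true(all(table(r1$steps$stage) <= cfg$max_steps_per_stage))
  expect_identical(r1$steps$step, seq_len(nrow(r1$steps)))
})

test_that("best-so-far score is non-increasing over steps", {
  for (seed in c(3, 14, 25)) {
    pat <- make_patient(seed, "clinical")
    rec <- run_hemisphere(patient_responder(pat), patient_spec(pat))
    ok <- !rec$steps$side_effect
    best_so_far <- cummin(ifelse(ok, rec$steps$total_score, Inf))
    expect_true(all(diff(best_so_far) <= 0))
    expect_lte(rec$final$score, min(rec$steps$total_score[ok]) + 1e-12)
  }
})

test_that("the directional stage runs only when segments carry current", {
  for (seed in 1:8) {
    pat <- make_patient(seed, "clinical")
    rec <- run_hemisphere(patient_responder(pat), patient_spec(pat))
    seg_on <- any(rec$stages$ring$best$setting$percents[2:7] > 0)
    expect_identical(rec$directional_stage, seg_on)
    if (seg_on) {
      expect_equal(rec$stages$directional$base_vertical,
                   setting_to_point(rec$stages$ring$best$setting)$p)
    }
  }
})

test_that("burden report separates convergence from optimization burden", {
  pat <- make_patient(5, "easy")
  rec <- run_hemisphere(patient_responder(pat), patient_spec(pat))
  b <- burden_report(rec)
  expect_equal(b$steps_to_convergence, nrow(rec$steps))
  expect_equal(b$steps_to_best, rec$final$step)
  expect_lte(b$steps_to_best, b$steps_to_convergence)
  rec0 <- rec; rec0$steps <- rec0$steps[0, ]
  expect_error(burden_report(rec0), "empty")
})
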