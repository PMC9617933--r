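test_that("ring-stage fractionalization reproduces published patterns", {
  cases <- list(
    list(p = 0.3, a = 5.1, pct = c(E1 = 70, E2 = 10, E3 = 10, E4 = 10)),
    list(p = 0.0, a = 3.0, pct = c(E1 = 100)),
    list(p = 2.0, a = 2.3, pct = c(E5 = 34, E6 = 33, E7 = 33)),
    list(p = 0.6, a = 4.5, pct = c(E1 = 40, E2 = 20, E3 = 20, E4 = 20)),
    list(p = 3.0, a = 1.0, pct = c(E8 = 100))
  )
  for (cs in cases) {
    s <- ring_point_to_setting(exploration_point("ring", cs$p, cs$a))
    expect_equal(s$percents[s$percents > 0], cs$pct)
    expect_equal(sum(s$percents), 100L)
    expect_equal(sum(setting_to_vector(s)[1:8]), -1)
    expect_equal(s$amplitude, cs$a)
  }
})

test_that("directional-stage fractionalization interpolates angle and level", {
  s <- directional_point_to_setting(exploration_point("directional", 0, 2), 1.0)
  expect_equal(s$percents[s$percents > 0], c(E2 = 100))

  s <- directional_point_to_setting(exploration_point("directional", 60, 2), 1.5)
  expect_equal(s$percents[s$percents > 0],
               c(E2 = 25, E3 = 25, E5 = 25, E6 = 25))

  s <- directional_point_to_setting(exploration_point("directional", 0, 2), 0.6)
  expect_equal(s$percents[s$percents > 0], c(E1 = 40, E2 = 60))

  # angles normalize modulo 360
  s1 <- directional_point_to_setting(exploration_point("directional", 390, 2), 1)
  s2 <- directional_point_to_setting(exploration_point("directional", 30, 2), 1)
  expect_identical(s1$percents, s2$percents)
})

test_that("setting_to_vector orders E1..E8 with the case last", {
  s <- pct_setting(c(E1 = 100), 3)
  expect_equal(setting_to_vector(s), c(-1, 0, 0, 0, 0, 0, 0, 0, 1))
  s <- pct_setting(c(E1 = 70, E2 = 10, E3 = 10, E4 = 10), 3.7)
  expect_equal(setting_to_vector(s),
               c(-0.7, -0.1, -0.1, -0.1, 0, 0, 0, 0, 1))
  z <- stim_setting(0, rep(0, 9))
  expect_equal(setting_to_vector(z), rep(0, 9))
})

test_that("coordinate round trip holds on the exploration lattice", {
  for (p in seq(0, 3, by = 0.1)) {
    s <- ring_point_to_setting(exploration_point("ring", p, 2))
    expect_lt(abs(setting_to_point(s)$p - p), 0.02)
  }
  for (base_p in c(0.5, 1.0, 1.5, 2.0, 2.5)) {
    for (theta in seq(0, 348, by = 12)) {
      s <- directional_point_to_setting(
        exploration_point("directional", theta, 2), base_p)
      got <- setting_to_point(s)
      expect_lt(abs(got$p - base_p), 0.02)
      dth <- abs((got$theta - theta) %% 360)
      expect_lt(min(dth, 360 - dth), 3)
    }
  }
})

test_that("increasing the vertical fraction strictly steers current upward", {
  prev <- NULL
  for (p in seq(1, 2, by = 0.05)) {
    s <- ring_point_to_setting(exploration_point("ring", p, 2))
    upper <- sum(s$percents[5:7])
    if (!is.null(prev)) expect_gt(upper, prev)
    prev <- upper
  }
})

test_that("domain and safety errors are raised", {
  expect_error(exploration_point("ring", 3.2, 1), "\\[0, 3\\]")
  expect_error(ring_point_to_setting(exploration_point("ring", 1, 6)),
               "safety")
  expect_error(directional_point_to_setting(
    exploration_point("directional", 0, 1), base_vertical = 3.5), "\\[0, 3\\]")
  expect_error(stim_setting(2, c(-0.5, rep(0, 7), 1)), "sum to -1")
  expect_error(exploration_point("ring", 1, -0.5), ">= 0")
})

test_that("electrode-configuration strings parse and round-trip", {
  pct <- parse_electrode_config("E1: -70%, E2, E3, E4: -10%")
  expect_equal(pct[pct > 0], c(E1 = 70L, E2 = 10L, E3 = 10L, E4 = 10L))
  # unicode minus as printed in journals
  expect_identical(parse_electrode_config("E5: −60%, E8: −40%"),
                   parse_electrode_config("E5: -60%, E8: -40%"))
  tbl <- utils::read.csv(table1_path(), stringsAsFactors = FALSE)
  for (txt in tbl$electrode_configuration) {
    pct <- parse_electrode_config(txt)
    expect_equal(sum(pct), 100L)
    expect_identical(parse_electrode_config(format_electrode_config(pct)), pct)
  }
  expect_error(parse_electrode_config("E1: -50%, E2: -49%"), "sum to 100")
  expect_error(parse_electrode_config("E9: -100%"), "unknown electrode")
})

test_that("every published configuration is reachable from the coordinate space", {
  tbl <- utils::read.csv(table1_path(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tbl))) {
    pct <- parse_electrode_config(tbl$electrode_configuration[i])
    hit <- find_point_for_config(pct)
    expect_lte(hit$max_dev, 1)
  }
})
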