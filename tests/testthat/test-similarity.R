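test_that("amplitude ratio is min over max", {
  expect_equal(amp_ratio(3.7, 3.8), 3.7 / 3.8)
  expect_equal(amp_ratio(2, 2), 1)
  expect_equal(amp_ratio(1, 4), 0.25)
  expect_equal(amp_ratio(4, 1), 0.25)
  expect_error(amp_ratio(0, 2), "positive")
})

test_that("electrode-configuration distance normalizes to the bipolar swap", {
  v <- setting_to_vector(pct_setting(c(E1 = 100), 3))
  expect_equal(norm_elec_conf_dist(v, v), 0)
  w <- setting_to_vector(pct_setting(c(E1 = 70, E2 = 10, E3 = 10, E4 = 10), 3))
  expect_equal(norm_elec_conf_dist(v, w), sqrt(0.12) / sqrt(8))
  # full polarity swap between E1 and the case
  swap <- c(1, 0, 0, 0, 0, 0, 0, 0, -1)
  expect_equal(norm_elec_conf_dist(v, swap), 1)
  expect_error(norm_elec_conf_dist(v[1:8], v), "length 9")
})

test_that("setting similarity reproduces the published 0.85 case", {
  soc <- setting_from_config("E1: -100%", 3.8)
  agp <- setting_from_config("E1: -70%, E2, E3, E4: -10%", 3.7)
  expect_equal(setting_similarity(soc, agp), 0.85)
  expect_equal(setting_similarity(soc, soc), 1)
  a2 <- pct_setting(c(E1 = 100), 2); a4 <- pct_setting(c(E1 = 100), 4)
  expect_equal(setting_similarity(a2, a4), 0.5)
})

test_that("the voxel VTA stand-in has the right geometry", {
  s <- pct_setting(c(E1 = 100), 3.0)
  v <- vta_model(s, voxel_mm = 0.25, encapsulation_mm = -1)  # no exclusion
  r <- 1.3 * sqrt(3.0)
  expect_lt(abs(v$volume_mm3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.1)

  expect_equal(vta_model(stim_setting(0, rep(0, 9)))$volume_mm3, 0)

  v1 <- vta_model(pct_setting(c(E2 = 100), 2))
  v2 <- vta_model(pct_setting(c(E2 = 100), 4))
  expect_gt(v2$volume_mm3, v1$volume_mm3)
  expect_equal(jaccard_index(v1, v2), v1$volume_mm3 / v2$volume_mm3) # nested
})

test_that("jaccard index handles identity, disjointness and nesting", {
  mk <- function(ids) dbsteer:::new_voxel_vta(as.character(ids), 0.25)
  expect_equal(jaccard_index(mk(1:10), mk(1:10)), 1)
  expect_equal(jaccard_index(mk(1:10), mk(11:20)), 0)
  expect_equal(jaccard_index(mk(1:5), mk(1:10)), 0.5)
  expect_error(jaccard_index(mk(integer(0)), mk(integer(0))), "empty")
  expect_error(jaccard_index(mk(1:3), dbsteer:::new_voxel_vta("1", 0.5)),
               "grids")
})

test_that("score similarity spans identical to maximally different", {
  expect_equal(score_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(score_similarity(rep(0, 5), rep(4, 5)), 0)
  expect_equal(score_similarity(2, 0), 0.5)
  expect_error(score_similarity(1:3, 1:2), "length")
})

test_that("metrics are symmetric, bounded and identity-discriminating", {
  set.seed(20240917)
  for (i in 1:400) {
    # random monopolar cathodic percent patterns
    k <- sample(1:4, 1)
    idx <- sample(1:8, k)
    pct <- stats::setNames(dbsteer:::largest_remainder(runif(k), 100L),
                           paste0("E", idx))
    s1 <- pct_setting(pct[pct > 0], runif(1, 0.5, 5.5))
    k2 <- sample(1:4, 1)
    idx2 <- sample(1:8, k2)
    pct2 <- stats::setNames(dbsteer:::largest_remainder(runif(k2), 100L),
                            paste0("E", idx2))
    s2 <- pct_setting(pct2[pct2 > 0], runif(1, 0.5, 5.5))
    a <- setting_similarity(s1, s2, digits = NA)
    expect_equal(a, setting_similarity(s2, s1, digits = NA))
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(setting_similarity(s1, s1, digits = NA), 1)

    sc1 <- round(runif(4, 0, 4), 1); sc2 <- round(runif(4, 0, 4), 1)
    ss <- score_similarity(sc1, sc2)
    expect_equal(ss, score_similarity(sc2, sc1))
    expect_gte(ss, 0); expect_lte(ss, 1)
    if (!isTRUE(all.equal(sc1, sc2))) expect_lt(ss, 1)
  }
})

test_that("jaccard distance obeys the triangle inequality", {
  set.seed(7)
  mk <- function() dbsteer:::new_voxel_vta(
    as.character(sample(1:30, sample(5:25, 1))), 0.25)
  for (i in 1:300) {
    a <- mk(); b <- mk(); c <- mk()
    dab <- 1 - jaccard_index(a, b)
    dbc <- 1 - jaccard_index(b, c)
    dac <- 1 - jaccard_index(a, c)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})
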