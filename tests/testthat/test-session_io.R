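test_that("configuration files validate and fill defaults", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", f)
  cfg <- load_config(f)
  expect_equal(cfg$frequency, 130)
  expect_equal(cfg$pulse_width, 60)
  expect_equal(cfg$amp_step, 0.1)
  expect_equal(cfg$wash_in_s, 30)

  writeLines('{"frequency": 185, "beta0": 2.5}', f)
  cfg <- load_config(f)
  expect_equal(cfg$frequency, 185)
  expect_equal(cfg$beta0, 2.5)

  writeLines('{"amp_step": 0}', f)
  expect_error(load_config(f), "amp_step")
  writeLines('{"ramp_rate": 3}', f)
  expect_error(load_config(f), "unknown configuration key")
  writeLines('{"amp_range": [5, 1]}', f)
  expect_error(load_config(f), "amp_range")

  writeLines('{"predefined_ring": [[0.5,1],[1.5,2],[2.5,1]],
               "predefined_directional": [[0,2],[90,2],[180,2],[270,2]]}', f)
  cfg <- load_config(f)
  expect_equal(cfg$predefined_ring[[2]]$coord1, 1.5)
  expect_equal(cfg$predefined_directional[[4]]$coord1, 270)
})

test_that("session records round-trip losslessly through JSON", {
  pat <- make_patient(21, "clinical")
  rec <- run_hemisphere(patient_responder(pat), patient_spec(pat))
  f <- withr::local_tempfile(fileext = ".json")
  write_session(rec, f)
  back <- read_session(f)
  expect_equal(back$steps, rec$steps)
  expect_equal(back$final$score, rec$final$score)
  expect_equal(back$final$step, rec$final$step)
  expect_equal(length(back$settings), length(rec$settings))
  expect_equal(back$settings[[5]]$fractions, rec$settings[[5]]$fractions)
  expect_equal(back$spec$weight, rec$spec$weight)
  # a second serialization is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_session(back, f2)
  expect_identical(readLines(f), readLines(f2))

  writeLines(sub('"1.0"', '"0.9"', readLines(f)), f2)
  expect_error(read_session(f2), "schema version")
  writeLines(readLines(f)[1:5], f2)
  expect_error(read_session(f2))
})

test_that("synthetic patients replay exactly after serialization", {
  pat <- make_patient(9, "clinical")
  f <- withr::local_tempfile(fileext = ".json")
  write_patient(pat, f)
  back <- read_patient(f)
  s <- ring_point_to_setting(exploration_point("ring", 1.2, 3.0))
  expect_identical(respond(pat, s), respond(back, s))
  r1 <- run_hemisphere(patient_responder(pat), patient_spec(pat))
  r2 <- run_hemisphere(patient_responder(back), patient_spec(back))
  expect_identical(r1$steps, r2$steps)
})

test_that("the published settings table reads with all 40 hemispheres", {
  tbl <- read_settings_table(table1_path())
  expect_equal(nrow(tbl), 40L)
  expect_true(all(vapply(tbl$setting, inherits, logical(1), "stim_setting")))
  expect_true(all(vapply(tbl$setting, function(s)
    sum(s$percents) == 100L, logical(1))))
  soc <- tbl[tbl$condition == "SoC", ]
  agp <- tbl[tbl$condition == "AgP", ]
  cmp <- compare_settings_tables(soc, agp)
  expect_equal(nrow(cmp), 20L)
  expect_true(all(cmp$set_sim >= 0 & cmp$set_sim <= 1))
  i <- cmp$subject == "0309-010" & cmp$hemisphere == "right"
  expect_equal(round(cmp$set_sim[i], 2), 0.85)
})

test_that("the CLI is deterministic end to end", {
  dir <- withr::local_tempdir()
  pfile <- file.path(dir, "patient.json")
  expect_equal(dbs_cli(c("simulate", "--seed", "5", "--preset", "clinical",
                         "--out", pfile)), 0L)
  s1 <- file.path(dir, "s1.json"); s2 <- file.path(dir, "s2.json")
  expect_equal(dbs_cli(c("optimize", "--patient", pfile, "--seed", "5",
                         "--out", s1)), 0L)
  expect_equal(dbs_cli(c("optimize", "--patient", pfile, "--seed", "5",
                         "--out", s2)), 0L)
  expect_identical(readLines(s1), readLines(s2))

  mfile <- file.path(dir, "map.csv")
  expect_equal(dbs_cli(c("export", "--session", s1, "--stage", "ring",
                         "--out", mfile)), 0L)
  expect_gt(nrow(utils::read.csv(mfile)), 0)

  rfile <- file.path(dir, "report.json")
  expect_equal(dbs_cli(c("report", "--session", s1, "--out", rfile)), 0L)
  rep_ <- jsonlite::fromJSON(rfile)
  expect_gt(rep_$steps_to_convergence, 0)

  cfile <- file.path(dir, "cmp.csv")
  tbl <- utils::read.csv(table1_path(), stringsAsFactors = FALSE)
  socf <- file.path(dir, "soc.csv"); agpf <- file.path(dir, "agp.csv")
  utils::write.csv(tbl[tbl$condition == "SoC", ], socf, row.names = FALSE)
  utils::write.csv(tbl[tbl$condition == "AgP", ], agpf, row.names = FALSE)
  expect_equal(dbs_cli(c("compare", socf, agpf, "--out", cfile)), 0L)
  expect_equal(nrow(utils::read.csv(cfile)), 20L)

  expect_equal(suppressMessages(dbs_cli(c("defragment"))), 1L)
  expect_equal(suppressMessages(dbs_cli(character(0))), 1L)
})
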