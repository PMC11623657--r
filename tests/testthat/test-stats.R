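test_that("run_test handles degenerate and textbook inputs", {
  r <- run_test("t", list(c(1, 2, 3), c(1, 2, 3)), paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- run_test("t", list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r2$statistic, 0)
  expect_error(run_test("t", list(1:3)), "two samples")
  expect_error(run_test("t", list(1, 2)), "at least 2")
  expect_error(run_test("t", list(1:3, 1:4), paired = TRUE), "equal-length")
  expect_error(run_test("kruskal", list(1:5)), "two groups")
})

test_that("the t-test detects a three-sigma shift essentially always", {
  set.seed(30)
  p <- replicate(20, {
    run_test("t", list(rnorm(50), rnorm(50, 3)))$p_value
  })
  expect_true(all(p < 0.001))
})

test_that("ANOVA and Kruskal-Wallis run and agree on obvious structure", {
  set.seed(31)
  groups <- list(rnorm(20), rnorm(20, 5), rnorm(20, 10))
  a <- run_test("anova", groups)
  k <- run_test("kruskal", groups)
  expect_lt(a$p_value, 1e-6)
  expect_lt(k$p_value, 1e-6)
  null_g <- list(rnorm(20), rnorm(20))
  expect_gt(run_test("anova", null_g)$p_value, 1e-4)
})

test_that("preset configurations resolve to valid simulation configs", {
  for (p in c("FIG1_NODES", "FIG2_DIVISION", "FIG5_DEC")) {
    cfg <- preset_config(p, seed = 1L)
    expect_s3_class(cfg, "sim_config")
    expect_length(validate_config(cfg), 0)
  }
  for (arm in c("isotype", "anti_cd40l", "anti_cd40l_taci", "taci")) {
    cfg <- preset_config("FIG4_CD40L", arm = arm, seed = 1L)
    kinds <- vapply(cfg$interventions, `[[`, "", "kind")
    expect_true("FTY720" %in% kinds)
    expect_equal("ANTI_CD40L" %in% kinds, grepl("cd40l", arm))
    expect_equal("TACI_IG" %in% kinds, grepl("taci", arm))
  }
})

test_that("report bundles are byte-deterministic given (preset, seed)", {
  b1 <- run_preset("FIG2_DIVISION", n_animals = 2, seed = 5)
  b2 <- run_preset("FIG2_DIVISION", n_animals = 2, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report_bundle(b1, d1)
  write_report_bundle(b2, d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("TOML configuration files round-trip", {
  cfg <- simulation_config(
    seed = 77L, myc_k = 0.5, horizon_steps = 12L,
    interventions = list(intervention("DOXYCYCLINE", 4L),
                         intervention("DEC_OVA", 6L, dose_fraction = 0.25)))
  path <- withr::local_tempfile(fileext = ".toml")
  write_config_toml(cfg, path)
  cfg2 <- read_config_toml(path)
  for (f in c("n_founders", "myc_k", "horizon_steps", "seed",
              "pc_export_prob", "v_gene_pool", "baseline_affinity")) {
    expect_equal(cfg2[[f]], cfg[[f]])
  }
  expect_equal(length(cfg2$interventions), 2)
  expect_equal(cfg2$interventions[[2]]$dose_fraction, 0.25)
  expect_error(read_config_toml(path, banana = 1), "unknown config keys")
  # identical simulation from the round-tripped config
  out1 <- run_simulation(simulation_config(horizon_steps = 6L, seed = 77L,
                                           myc_k = 0.5))
  out2 <- run_simulation(read_config_toml(path, horizon_steps = 6L,
                                          interventions = list()))
  expect_identical(out1$cells, out2$cells)
})

test_that("day/step conversion is consistent and invertible on the grid", {
  cfg <- simulation_config()
  expect_equal(day_to_step(4, cfg), 0L)
  expect_equal(day_to_step(10, cfg), 12L)
  expect_equal(step_to_day(day_to_step(seq(4, 32, 0.5), cfg), cfg),
               seq(4, 32, 0.5))
})
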