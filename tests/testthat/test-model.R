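test_that("antigen capture is saturating, monotone and exact on hand values", {
  expect_equal(antigen_capture(0, cmax = 1, K = 1), 0)
  expect_equal(antigen_capture(1, cmax = 1, K = 1), 0.5)
  expect_equal(antigen_capture(3, cmax = 2, K = 1), 1.5)
  a <- seq(0, 50, by = 0.5)
  cap <- antigen_capture(a, cmax = 4, K = 2)
  expect_true(all(diff(cap) > 0))
  expect_true(all(cap < 4))
  expect_error(antigen_capture(1, cmax = 1, K = 0), "K must be")
  expect_error(antigen_capture(-1, cmax = 1, K = 1), "affinity")
})

test_that("Myc proxy is affine in captured antigen", {
  expect_equal(myc_level(0, m0 = 0.2, k = 1), 0.2)
  expect_equal(myc_level(c(1, 5, 9), m0 = 3, k = 0), rep(3, 3))
  expect_equal(myc_level(2, m0 = 1, k = 1), 3)
  expect_error(myc_level(-1, 0, 1), "captured")
})

test_that("division budgets follow the Myc proxy in both modes", {
  expect_identical(division_budget(3, beta = 1, il21_scale = 1), 3L)
  expect_identical(division_budget(c(0.1, 2, 5), beta = 0), rep(0L, 3))
  expect_identical(division_budget(2, beta = 1.5, il21_scale = 2), 6L)
  set.seed(42)
  draws <- division_budget(rep(2, 1e5), beta = 1, mode = "poisson")
  expect_lt(abs(mean(draws) - 2), 0.05)
  expect_error(division_budget(1, 1, 1, mode = "banana"))
  expect_error(division_budget(-1, 1), "myc")
})

test_that("mutate_chain is the identity at mutation rate zero", {
  cfg <- simulation_config(mutation_rate = 0)
  bcr <- make_bcr()
  set.seed(1)
  res <- mutate_chain(bcr, affinity = 2, cfg)
  expect_identical(res$bcr$heavy$sequence_alignment,
                   bcr$heavy$sequence_alignment)
  expect_identical(res$bcr$light$sequence_alignment,
                   bcr$light$sequence_alignment)
  expect_equal(res$affinity, 2)
  expect_equal(res$fate, "OK")
  expect_equal(nrow(res$events), 0)
})

test_that("a designated-site substitution multiplies affinity by its factor", {
  sites <- default_affinity_sites()[1, ]  # W33L only, factor 8
  cfg <- simulation_config(mutation_rate = 1, site_hotspot_prob = 1,
                           affinity_sites = sites,
                           lethal_fraction = 0, deleterious_fraction = 0)
  set.seed(7)
  res <- mutate_chain(make_bcr(), affinity = 2, cfg)
  expect_equal(res$affinity, 16)
  expect_equal(res$fate, "OK")
  hv <- res$events[res$events$chain == "heavy", ]
  expect_equal(hv$position, 33)
  expect_equal(hv$from_res, "W")
  expect_equal(hv$to_res, "L")
  expect_identical(substr(res$bcr$heavy$sequence_alignment, 33, 33), "L")
  # germline untouched
  expect_identical(res$bcr$heavy$germline_alignment,
                   germline_set()$heavy[["IGHV1-72*01"]])
  # the same substitution on a different V confers nothing
  set.seed(7)
  res2 <- mutate_chain(make_bcr(v_call = "IGHV1-53*01"), affinity = 2, cfg)
  expect_lte(res2$affinity, 2)
})

test_that("per-chain mutation frequency matches the configured rate", {
  cfg <- simulation_config(mutation_rate = 0.3, site_hotspot_prob = 0,
                           lethal_fraction = 0, deleterious_fraction = 0)
  bcr <- make_bcr()
  set.seed(5)
  n <- 1e4
  mut_h <- logical(n)
  for (i in seq_len(n)) {
    res <- mutate_chain(bcr, 1, cfg)
    mut_h[i] <- res$bcr$heavy$sequence_alignment !=
      bcr$heavy$sequence_alignment
  }
  expect_lt(abs(mean(mut_h) - 0.3), 0.02)
})

test_that("mismatched alignment lengths are a data error", {
  bcr <- make_bcr()
  bcr$heavy$sequence_alignment <- substr(bcr$heavy$sequence_alignment, 1, 50)
  cfg <- simulation_config()
  expect_error(mutate_chain(bcr, 1, cfg), "length mismatch")
  expect_error(paired_bcr("x", bcr$heavy, bcr$light), "length mismatch")
})
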