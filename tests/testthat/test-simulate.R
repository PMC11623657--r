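test_that("a zero-step horizon returns the founders unchanged", {
  cfg <- small_config(horizon_steps = 0L)
  out <- run_simulation(cfg)
  expect_equal(nrow(out$cells), 6 * 3)
  expect_true(all(out$cells$compartment == "GC_LZ"))
  expect_true(all(out$cells$affinity ==
                    cfg$baseline_affinity[out$cells$v_call]))
  expect_true(all(out$cells$divisions_since_label == 0))
})

test_that("forced export moves a lone LZ cell to the prePC compartment", {
  cfg <- simulation_config(n_founders = 1L, founder_cells = 1L,
                           pc_export_prob = 1, n_select = 0,
                           gc_death_rate = 0, horizon_steps = 1L, seed = 2L)
  out <- run_simulation(cfg)
  expect_equal(unname(census(out$final_state)[["PREPC"]]), 1)
})

test_that("an exported budget of b yields 2^b plasma cells", {
  # m0 chosen so the PC budget is exactly 3 and the GC budget 0
  cfg <- simulation_config(
    n_founders = 1L, founder_cells = 1L, mutation_rate = 0,
    myc_k = 0, myc_m0 = 1.25, division_beta = 1.2, pc_division_scale = 2,
    pc_divisions_per_step = 1L, pc_export_prob = 1, n_select = 0,
    gc_death_rate = 0, pc_death_rate = 0, horizon_steps = 8L, seed = 3L)
  expect_identical(division_budget(1.25, 1.2, 2), 3L)
  out <- run_simulation(cfg)
  expect_equal(unname(census(out$final_state)[["PC"]]), 8)
  ev <- out$event_log
  expect_equal(ev$n_pc[nrow(ev)], 8)  # stable once the budget is spent
})

test_that("cells are conserved: LIVE + DYING + DEAD equals all ever created", {
  out <- run_simulation(small_config())
  S <- out$final_state
  expect_equal(sum(S$live %in% c("LIVE", "DYING", "DEAD")), S$n)
  expect_equal(length(S$id), S$n)
  expect_equal(length(unique(S$id)), S$n)
})

test_that("fate labels are inherited and never lost", {
  cfg <- small_config(interventions = list(
    intervention("TAMOXIFEN_S1PR2", 0L)))
  out <- run_simulation(cfg)
  S <- out$final_state
  # every cell descends from a labeled founder, so all carry the label
  expect_true(all(S$zsg))
})

test_that("noise-free label fluorescence halves exactly per division", {
  cfg <- small_config(mcherry_sigma = 0, interventions = list(
    intervention("DOXYCYCLINE", 2L)))
  out <- run_simulation(cfg)
  S <- out$final_state
  expect_equal(S$mch, cfg$mcherry_f0 * 2^(-S$divlab))
  # before the label switch fluorescence is constant
  cfg0 <- small_config(mcherry_sigma = 0)
  out0 <- run_simulation(cfg0)
  expect_true(all(out0$final_state$mch == cfg0$mcherry_f0))
  expect_true(all(out0$final_state$divlab == 0))
})

test_that("identical (config, seed) produce byte-identical outputs", {
  cfg <- small_config(snapshot_days = 7, interventions = list(
    intervention("DOXYCYCLINE", 4L)))
  write_out <- function(dir) {
    out <- run_simulation(cfg)
    write_airr_tsv(out$repertoire, file.path(dir, "rep.tsv"))
    utils::write.csv(out$serum, file.path(dir, "serum.csv"),
                     row.names = FALSE)
    utils::write.csv(out$event_log, file.path(dir, "events.csv"),
                     row.names = FALSE)
    dir
  }
  d1 <- write_out(withr::local_tempdir())
  d2 <- write_out(withr::local_tempdir())
  for (f in c("rep.tsv", "serum.csv", "events.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("event-log censuses agree with the final cell snapshot", {
  out <- run_simulation(small_config())
  fin <- out$event_log[nrow(out$event_log), ]
  snap <- out$cells[out$cells$timepoint == max(out$cells$timepoint), ]
  live <- snap[snap$live_state == "LIVE", ]
  expect_equal(fin$n_gc_lz, sum(live$compartment == "GC_LZ"))
  expect_equal(fin$n_gc_dz, sum(live$compartment == "GC_DZ"))
  expect_equal(fin$n_prepc, sum(live$compartment == "PREPC"))
  expect_equal(fin$n_pc, sum(live$compartment == "PC"))
  expect_equal(fin$n_dying, sum(snap$live_state == "DYING"))
  # every repertoire row maps to a snapshot cell
  expect_true(all(out$repertoire$cell_id %in% out$cells$cell_id))
  expect_equal(nrow(out$repertoire), 2 * nrow(out$cells))
})

test_that("help-coupled runs divide plasma cells more than decoupled runs", {
  mean_div <- function(k) {
    cfg <- simulation_config(
      n_founders = 10L, founder_cells = 3L, myc_k = k, n_select = 15,
      horizon_steps = 16L, snapshot_days = 12,
      interventions = list(intervention("DOXYCYCLINE", 8L)), seed = 21L)
    out <- run_simulation(cfg)
    pc <- out$cells[out$cells$celltype == "PC" &
                      out$cells$live_state == "LIVE", ]
    mean(pc$divisions_since_label)
  }
  expect_gt(mean_div(1), mean_div(0))
})

test_that("secretion aggregates identical genotypes and respects affinity", {
  cfg <- simulation_config(seed = 1L)
  S <- new.env()
  S$live <- rep("LIVE", 3)
  S$comp <- c("PC", "PC", "GC_LZ")
  S$affinity <- c(2, 2, 5)
  S$clone <- c("C1", "C1", "C2")
  class(S) <- "sim_state"
  sp <- secrete(S, cfg)
  expect_equal(nrow(sp), 1)  # two identical PCs aggregate; GC cell ignored
  expect_equal(sp$concentration, 2 * cfg$secretion_rate)
  expect_equal(sp$kd, cfg$kd0 / 2)
  S$live <- rep("DEAD", 3)
  expect_equal(nrow(secrete(S, cfg)), 0)
})

test_that("invalid configurations fail with all violations listed", {
  err <- tryCatch(
    simulation_config(mutation_rate = 2, capture_K = -1,
                      division_beta = -0.5),
    error = function(e) conditionMessage(e))
  expect_match(err, "mutation_rate")
  expect_match(err, "capture_K")
  expect_match(err, "division_beta")
})
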