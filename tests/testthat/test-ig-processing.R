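test_that("pairing keeps exactly 1xIgH + 1xIgL cells and explains discards", {
  chains <- rbind(
    chain_row("ok", "IGH"), chain_row("ok", "IGK"),
    chain_row("two_heavy", "IGH"),
    chain_row("two_heavy", "IGH", v_call = "IGHV1-53*01",
              junction = "CARQQQW"),
    chain_row("two_heavy", "IGK"),
    chain_row("no_light", "IGH"),
    chain_row("no_heavy", "IGK"),
    chain_row("two_light", "IGH"), chain_row("two_light", "IGK"),
    chain_row("two_light", "IGL", v_call = "IGKV1-117*01"))
  res <- pair_chains(chains)
  expect_equal(res$paired$cell_id, "ok")
  expect_equal(res$paired$light_locus, "IGK")
  disc <- setNames(res$discarded$reason, res$discarded$cell_id)
  expect_equal(disc[["two_heavy"]], "MULTI_HEAVY")
  expect_equal(disc[["no_light"]], "NO_LIGHT")
  expect_equal(disc[["no_heavy"]], "NO_HEAVY")
  expect_equal(disc[["two_light"]], "MULTI_LIGHT")
})

test_that("exact duplicate chain rows are dropped with a warning", {
  chains <- rbind(chain_row("c", "IGH"), chain_row("c", "IGH"),
                  chain_row("c", "IGK"))
  expect_warning(res <- pair_chains(chains), "duplicate")
  expect_equal(res$paired$cell_id, "c")
})

test_that("mutation calling reports positional diffs and skips gaps", {
  g <- germline_set()$heavy[["IGHV1-72*01"]]
  expect_equal(nrow(call_mutations(g, g)), 0)
  s <- g; substr(s, 33, 33) <- "L"
  m <- call_mutations(s, g, chain = "heavy")
  expect_equal(m$position, 33)
  expect_equal(m$from_res, "W")
  expect_equal(m$to_res, "L")
  # gap and ambiguity characters are never counted
  s2 <- g; substr(s2, 10, 10) <- "-"; substr(s2, 11, 11) <- "X"
  expect_equal(nrow(call_mutations(s2, g)), 0)
  expect_error(call_mutations(substr(g, 1, 10), g, cell_id = "bad"), "bad")
})

test_that("affinity-enhancement scoring is V-restricted and rule-aware", {
  w33l <- data.frame(chain = "heavy", position = 33, from_res = "W",
                     to_res = "L", stringsAsFactors = FALSE)
  res <- is_affinity_enhancing(w33l, "IGHV1-72*01")
  expect_true(res$flag)
  expect_equal(res$hits, "W33L")
  expect_false(is_affinity_enhancing(w33l[0, ], "IGHV1-72*01")$flag)
  expect_false(is_affinity_enhancing(w33l, "IGHV1-53*01")$flag)
  # all-sites rule requires the complete set
  expect_false(is_affinity_enhancing(w33l, "IGHV1-72*01", rule = "all")$flag)
  all3 <- data.frame(chain = "heavy", position = c(33, 59, 99),
                     from_res = c("W", "K", "Y"), to_res = c("L", "R", "G"),
                     stringsAsFactors = FALSE)
  expect_true(is_affinity_enhancing(all3, "IGHV1-72*01", rule = "all")$flag)
  expect_error(is_affinity_enhancing(w33l, "IGHV1-72*01",
                                     site_set = all3[0, ]), "site_set")
  # monotone: adding mutations never turns the flag off
  for (i in 1:3) {
    expect_true(is_affinity_enhancing(all3[seq_len(i), , drop = FALSE],
                                      "IGHV1-72*01")$flag)
  }
})

test_that("clone grouping uses V, J, junction length and single linkage", {
  mk <- function(id, junction, v = "IGHV1-72*01") {
    p <- pair_chains(rbind(chain_row(id, "IGH", v_call = v,
                                     junction = junction),
                           chain_row(id, "IGK")))$paired
    p
  }
  # identical junctions cluster together
  p <- rbind(mk("a", "CARAAAAAAW"), mk("b", "CARAAAAAAW"))
  expect_equal(length(unique(assign_clones(p)$clone_id)), 1)
  # different junction lengths never merge
  p <- rbind(mk("a", "CARAAAAAAW"), mk("b", "CARAAAAAAAW"))
  expect_equal(length(unique(assign_clones(p)$clone_id)), 2)
  # single linkage: identities AB = 0.9, BC = 0.9, AC = 0.8 chain into one
  # clone at threshold 0.85 (brute-force transitive closure oracle)
  ja <- "CARAAAAAAW"
  jb <- "CTRAAAAAAW"   # differs from ja at position 2
  jc <- "CTRAAAAAGW"   # differs from jb at position 9, from ja at 2 and 9
  ident <- function(x, y) mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  expect_equal(ident(ja, jb), 0.9)
  expect_equal(ident(jb, jc), 0.9)
  expect_equal(ident(ja, jc), 0.8)
  p <- rbind(mk("a", ja), mk("b", jb), mk("c", jc))
  expect_equal(length(unique(assign_clones(p, 0.85)$clone_id)), 1)
  expect_equal(length(unique(assign_clones(p, 0.95)$clone_id)), 3)
})

test_that("annotation round-trips through AIRR TSV unchanged", {
  out <- run_simulation(small_config(snapshot_days = 9))
  ann1 <- annotate_repertoire(pair_chains(out$repertoire)$paired)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr_tsv(out$repertoire, path)
  rep2 <- read_airr_tsv(path)
  ann2 <- annotate_repertoire(pair_chains(rep2)$paired)
  for (col in c("cell_id", "clone_id", "mutation_count", "affinity_flag",
                "hits")) {
    expect_identical(ann1[[col]], ann2[[col]])
  }
})

test_that("mutation load sums heavy and light counts", {
  hm <- data.frame(chain = "heavy", position = c(1, 2, 3),
                   from_res = "A", to_res = "C")
  lm <- data.frame(chain = "light", position = c(4, 5),
                   from_res = "A", to_res = "C")
  expect_equal(mutation_load(hm, lm), 5)
  expect_equal(mutation_load(hm[0, ], lm[0, ]), 0)
})

test_that("called mutations equal simulator ground truth cell by cell", {
  out <- run_simulation(small_config(horizon_steps = 14L))
  cells <- out$cells
  g <- germline_set()
  for (i in seq_len(nrow(cells))) {
    expected <- replay_mutations(g$heavy[[cells$v_call[i]]],
                                 cells$mut_log_heavy[i])
    got <- call_mutations(cells$heavy_seq[i], g$heavy[[cells$v_call[i]]])
    expect_equal(got[c("position", "from_res", "to_res")], expected,
                 ignore_attr = TRUE)
  }
})

test_that("clone assignment recovers simulator founders at low mutation", {
  out <- run_simulation(small_config(mutation_rate = 0.05,
                                     horizon_steps = 12L))
  ann <- annotate_repertoire(pair_chains(out$repertoire)$paired)
  cells <- out$cells[match(ann$cell_id, out$cells$cell_id), ]
  # junctions are clone-constant in the simulator, so the inferred clones
  # must exactly refine to the ground-truth founders: no merges, no splits
  tab <- table(ann$clone_id, cells$clone_gt)
  expect_true(all(rowSums(tab > 0) == 1))  # no merges across founders
  expect_true(all(colSums(tab > 0) == 1))  # no splits within founders
})

test_that("germline FASTA round-trips through Biostrings", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_germline_fasta(germline_set(), path)
  g <- read_germlines(path)
  expect_identical(g[["IGHV1-72*01"]],
                   germline_set()$heavy[["IGHV1-72*01"]])
  expect_length(g, 8)
})
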