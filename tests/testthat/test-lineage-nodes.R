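# build a minimal annotated table for node tests
ann_fixture <- function(heavy, light, celltype, flag = FALSE,
                        clone = "CL0001", animal = "A1") {
  n <- length(heavy)
  data.frame(cell_id = sprintf("c%02d", seq_len(n)), clone_id = clone,
             sequence_alignment = heavy, light_sequence_alignment = light,
             c_celltype = celltype,
             affinity_flag = rep_len(flag, n),
             c_animal = rep_len(animal, n), stringsAsFactors = FALSE)
}

test_that("genotype collapsing enumerates unique heavy+light combinations", {
  a <- ann_fixture(c("A", "A", "B", "C", "C"), rep("L", 5), rep("GC", 5))
  nodes <- collapse_genotypes(a)
  expect_equal(nrow(nodes), 3)
  expect_equal(sort(nodes$size), c(1, 2, 2))
  expect_equal(sum(nodes$size), 5)
  # the combination is the key: same heavy, two lights -> two nodes
  b <- ann_fixture(c("A", "A"), c("L1", "L2"), c("GC", "GC"))
  expect_equal(nrow(collapse_genotypes(b)), 2)
  # identical cells collapse to one node
  d <- ann_fixture(rep("A", 3), rep("L", 3), rep("GC", 3))
  expect_equal(collapse_genotypes(d)$size, 3)
  expect_equal(nrow(collapse_genotypes(a[0, ])), 0)
})

test_that("node composition is a partition over GC_ONLY/PC_ONLY/MIXED", {
  a <- ann_fixture(c("A", "A", "B", "C", "C", "C"), rep("L", 6),
                   c("GC", "PC", "GC", "PC", "PC", "prePC"))
  nodes <- collapse_genotypes(a)
  comp <- setNames(nodes$composition, nodes$heavy_seq)
  expect_equal(comp[["A"]], "MIXED")
  expect_equal(comp[["B"]], "GC_ONLY")
  expect_equal(comp[["C"]], "MIXED")  # prePC maps to GC by default
  expect_equal(nrow(nodes), sum(table(nodes$composition)))
  expect_equal(classify_node(2, 0), "GC_ONLY")
  expect_equal(classify_node(0, 3), "PC_ONLY")
  expect_equal(classify_node(1, 1), "MIXED")
  expect_error(classify_node(0, 0), "empty")
  expect_error(collapse_genotypes(
    ann_fixture("A", "L", "monocyte")), "unknown cell type")
})

test_that("collapsing already-collapsed genotypes is a no-op", {
  a <- ann_fixture(c("A", "A", "B"), rep("L", 3), c("GC", "PC", "GC"))
  nodes1 <- collapse_genotypes(a)
  # re-collapse a one-cell-per-genotype table: same nodes, size 1 each
  rep2 <- ann_fixture(nodes1$heavy_seq, nodes1$light_seq, rep("GC", 2))
  nodes2 <- collapse_genotypes(rep2)
  expect_equal(nrow(nodes2), nrow(nodes1))
  expect_true(all(nodes2$size == 1))
})

test_that("node summaries count compositions and flag fractions", {
  heavy <- c(sprintf("H%02d", 1:10))
  a <- ann_fixture(heavy, rep("L", 10), rep("GC", 10),
                   flag = c(rep(TRUE, 4), rep(FALSE, 6)))
  nodes <- collapse_genotypes(a)
  s <- node_summary(nodes, a)
  expect_equal(sum(s$node_counts$n_nodes), 10)
  expect_equal(s$node_flag_fraction$flag_fraction[
    s$node_flag_fraction$composition == "GC_ONLY"], 0.4)
  # unmutated single-type nodes: 0% flagged
  b <- ann_fixture("A", "L", "GC", flag = FALSE)
  sb <- node_summary(collapse_genotypes(b), b)
  expect_equal(sb$node_flag_fraction$flag_fraction, 0)
})

test_that("lineage export builds mutation-distance trees in newick", {
  g <- germline_set()
  gh <- g$heavy[["IGHV1-72*01"]]; gl <- g$light[["IGKV4-1*01"]]
  h1 <- gh; substr(h1, 33, 33) <- "L"              # 1 mutation
  h2 <- h1; substr(h2, 59, 59) <- "R"              # 2 mutations
  a <- ann_fixture(c(h1, h2), c(gl, gl), c("GC", "PC"))
  nodes <- collapse_genotypes(a)
  nwk <- export_lineage(nodes, gh, gl)
  tree <- ape::read.tree(text = nwk)
  expect_s3_class(tree, "phylo")
  # chain topology: germline -> 1-mut node -> 2-mut node; of the three
  # possible parent assignments only the chain nests the 2-mut node inside
  # the 1-mut node with unit branch lengths
  lab1 <- paste0(nodes$node_id[nodes$heavy_seq == h1], "_1")
  lab2 <- paste0(nodes$node_id[nodes$heavy_seq == h2], "_1")
  expect_identical(nwk, paste0("((", lab2, ":1)", lab1, ":1)germline;"))
  # single node: rooted at germline, parseable shape
  single <- export_lineage(nodes[1, ], gh, gl)
  expect_match(single, "germline;$")
})

test_that("mixed nodes are larger and PCs favor them over GC cells", {
  wins_size <- 0; wins_res <- 0; n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    out <- run_simulation(preset_config("FIG1_NODES", seed = 400 + s))
    ann <- annotate_repertoire(pair_chains(out$repertoire)$paired)
    nodes <- collapse_genotypes(ann)
    mixed <- nodes$composition == "MIXED"
    if (mean(nodes$size[mixed]) > mean(nodes$size[!mixed])) {
      wins_size <- wins_size + 1
    }
    srm <- node_summary(nodes, ann)
    res <- setNames(srm$cell_residence$frac_in_mixed,
                    srm$cell_residence$member_class)
    if (res[["PC"]] > res[["GC"]]) wins_res <- wins_res + 1
  }
  expect_gt(wins_size, n_seeds / 2)
  expect_gt(wins_res, n_seeds / 2)
})
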