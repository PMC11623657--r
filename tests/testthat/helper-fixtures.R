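# small deterministic building blocks shared across test files

# a minimal paired BCR on the designated high-affinity V
make_bcr <- function(heavy_muts = NULL, light_muts = NULL,
                     v_call = "IGHV1-72*01", light_v = "IGKV4-1*01") {
  g <- germline_set()
  h <- g$heavy[[v_call]]
  l <- g$light[[light_v]]
  apply_muts <- function(s, muts) {
    for (m in muts) substr(s, m$pos, m$pos) <- m$to
    s
  }
  if (!is.null(heavy_muts)) h <- apply_muts(h, heavy_muts)
  if (!is.null(light_muts)) l <- apply_muts(l, light_muts)
  paired_bcr(
    "cell1",
    heavy = list(locus = "IGH", v_call = v_call, j_call = "IGHJ2*01",
                 sequence_alignment = h,
                 germline_alignment = g$heavy[[v_call]],
                 junction_aa = "CARWDYW"),
    light = list(locus = "IGK", v_call = light_v, j_call = "IGKJ1*01",
                 sequence_alignment = l,
                 germline_alignment = g$light[[light_v]],
                 junction_aa = "CQQYSSF"))
}

# one AIRR-style chain row
chain_row <- function(cell_id, locus, v_call = "IGHV1-72*01",
                      seq = NULL, germ = NULL, junction = "CARWDYW") {
  g <- germline_set()
  if (is.null(germ)) {
    germ <- if (locus == "IGH") g$heavy[[v_call]] else g$light[[1]]
  }
  if (is.null(seq)) seq <- germ
  data.frame(cell_id = cell_id, locus = locus, v_call = v_call,
             j_call = if (locus == "IGH") "IGHJ2*01" else "IGKJ1*01",
             sequence_alignment = seq, germline_alignment = germ,
             junction_aa = junction, stringsAsFactors = FALSE)
}

# a fast, small simulation configuration for structural tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_founders = 6L, founder_cells = 3L, n_select = 10,
         horizon_steps = 10L, seed = 11L),
    list(...))
  do.call(simulation_config, args)
}

# the decoupled (null) configuration: division happens at an
# affinity-independent baseline rate
null_config <- function(seed, animal = "A1") {
  simulation_config(
    n_founders = 10L, founder_cells = 3L, myc_k = 0, myc_m0 = 1.5,
    mutation_rate = 0.05, division_mode = "poisson", n_select = 15,
    horizon_steps = 16L, snapshot_days = 12, snapshot_sample = 150,
    interventions = list(intervention("DOXYCYCLINE", 12L)),
    animal = animal, seed = seed)
}

# replay a simulator ground-truth mutation event log ("33:W>L;12:A>C")
# over the germline to obtain the net expected mutation set
replay_mutations <- function(germline, log) {
  s <- germline
  if (nzchar(log)) {
    for (ev in strsplit(log, ";", fixed = TRUE)[[1]]) {
      m <- regmatches(ev, regexec("^([0-9]+):(.)>(.)$", ev))[[1]]
      pos <- as.integer(m[2])
      stopifnot(substr(s, pos, pos) == m[3])
      substr(s, pos, pos) <- m[4]
    }
  }
  chars_s <- strsplit(s, "")[[1]]
  chars_g <- strsplit(germline, "")[[1]]
  pos <- which(chars_s != chars_g)
  data.frame(position = pos, from_res = chars_g[pos], to_res = chars_s[pos],
             stringsAsFactors = FALSE)
}

# target-V + designated-site flag computed directly from simulator truth
truth_flag <- function(cells, target_v = "IGHV1-72*01") {
  cells$v_call == target_v &
    (substr(cells$heavy_seq, 33, 33) == "L" |
       substr(cells$heavy_seq, 59, 59) == "R" |
       substr(cells$heavy_seq, 99, 99) == "G")
}
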