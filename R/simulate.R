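# Internal cell-state columns (parallel vectors inside a `sim_state`
# environment): id, founder, clone, comp (GC_LZ/GC_DZ/PREPC/PC/EGRESSED),
# live (LIVE/DYING/DEAD), hseq/lseq, vcall/lvcall/jcall/ljcall, junction,
# ljunction, affinity, captured, myc, budget, divlab, zsg, mch, dec, born,
# mut_h/mut_l (ground-truth substitution event logs, "pos:X>Y" joined by
# ";"), decov (pending DEC205 capture override, NA = none).

#' Initialize a simulation state with founder clones
#'
#' Seeds `n_founders` clones of `founder_cells` light-zone cells each.
#' Founder V genes, junctions, light chains and DEC205 targetability are
#' drawn from the configuration; affinities start at the germline baseline
#' for the assigned V.
#'
#' @param config a `sim_config`. The caller is responsible for seeding the
#'   RNG ([run_simulation()] does this from `config$seed`).
#' @return an environment of class `sim_state`.
#' @export
new_sim_state <- function(config) {
  g <- germline_set()
  nf <- config$n_founders
  vcall_f <- sample(names(config$v_gene_pool), nf, replace = TRUE,
                    prob = config$v_gene_pool)
  lvcall_f <- sample(names(g$light), nf, replace = TRUE)
  jlen <- sample(seq(config$junction_length_range[1],
                     config$junction_length_range[2]), nf, replace = TRUE)
  junction_f <- vapply(jlen, function(n) {
    paste(c("C", sample(AA_ALPHABET, n - 2L, TRUE), "W"), collapse = "")
  }, "")
  ljunction_f <- vapply(seq_len(nf), function(i) {
    paste(c("C", sample(AA_ALPHABET, 7L, TRUE), "F"), collapse = "")
  }, "")

  n <- nf * config$founder_cells
  fidx <- rep(seq_len(nf), each = config$founder_cells)
  S <- new.env(parent = emptyenv())
  S$step <- 0L
  S$n <- n
  S$next_id <- n + 1L
  S$id <- seq_len(n)
  S$founder <- fidx
  S$clone <- sprintf("C%03d", fidx)
  S$comp <- rep("GC_LZ", n)
  S$live <- rep("LIVE", n)
  S$vcall <- vcall_f[fidx]
  S$lvcall <- lvcall_f[fidx]
  S$jcall <- rep("IGHJ2*01", n)
  S$ljcall <- rep("IGKJ1*01", n)
  S$junction <- junction_f[fidx]
  S$ljunction <- ljunction_f[fidx]
  S$hseq <- unname(g$heavy[S$vcall])
  S$lseq <- unname(g$light[S$lvcall])
  S$affinity <- unname(config$baseline_affinity[S$vcall])
  S$captured <- rep(0, n)
  S$myc <- rep(myc_level(0, config$myc_m0, config$myc_k), n)
  S$budget <- rep(0L, n)
  S$divlab <- rep(0L, n)
  S$zsg <- rep(FALSE, n)
  S$mch <- config$mcherry_f0 *
    exp(stats::rnorm(n, 0, config$mcherry_sigma))
  # DEC205 targetability is a property of each founder cell's lineage (the
  # transfer-chimera analog mixes targetable and non-targetable B cells)
  S$dec <- stats::runif(n) < config$dec_wt_fraction
  S$born <- rep(0L, n)
  S$mut_h <- rep("", n)
  S$mut_l <- rep("", n)
  S$decov <- rep(NA_real_, n)
  S$sel_step <- rep(NA_integer_, n)
  # time-extended intervention flags
  S$sel_off <- FALSE
  S$gc_div_off <- FALSE
  S$cd40l_kill_step <- NA_integer_
  S$dox_step <- NA_integer_
  S$taci <- FALSE
  S$fty <- FALSE
  # serum and logs
  S$serum <- numeric(0)         # cumulative concentration, named "clone|kd"
  S$serum_steps <- list()
  S$export_log <- list()
  S$event_log <- list()
  class(S) <- "sim_state"
  S
}

dox_active <- function(S) !is.na(S$dox_step) && S$step >= S$dox_step

# antigen on FDCs holds a plateau, then decays with a configurable half-life
.cmax_now <- function(S, cfg) {
  past <- max(0, S$step - cfg$antigen_plateau_steps)
  cfg$capture_cmax * 2^(-past / cfg$antigen_halflife_steps)
}

#' Apply a scheduled intervention to the current state
#'
#' Called by [sim_step()] at the start of every step for every configured
#' intervention whose effect is due; exported so intervention semantics can
#' be exercised directly. One-shot actions (fate labeling, DEC205 antigen
#' loading) fire when `state$step == start_step`; persistent effects set
#' flags that later phases of the step honor.
#'
#' @param state a `sim_state`.
#' @param iv an [intervention()].
#' @param config a `sim_config`.
#' @return the state, invisibly (modified in place).
#' @export
apply_intervention <- function(state, iv, config) {
  S <- state
  if (S$step < iv$start_step) return(invisible(S))
  at_start <- S$step == iv$start_step
  switch(iv$kind,
    ANTI_CD40L = {
      S$sel_off <- TRUE
      S$gc_div_off <- TRUE
      # dead by start + delay: census at the end of that step is zero
      if (S$step + 1L >= iv$start_step + iv$delay_steps) {
        doomed <- S$live == "LIVE" &
          S$comp %in% c("GC_LZ", "GC_DZ", "PREPC")
        S$live[doomed] <- "DEAD"
      }
    },
    TACI_IG = { S$taci <- TRUE },
    DOXYCYCLINE = { if (is.na(S$dox_step)) S$dox_step <- iv$start_step },
    TAMOXIFEN_S1PR2 = {
      if (at_start) {
        S$zsg[S$live == "LIVE" &
                S$comp %in% c("GC_LZ", "GC_DZ", "PREPC")] <- TRUE
      }
    },
    TAMOXIFEN_BLIMP1 = {
      if (at_start) S$zsg[S$live == "LIVE" & S$comp == "PC"] <- TRUE
    },
    FTY720 = { S$fty <- TRUE },
    DEC_OVA = {
      if (at_start) {
        tgt <- S$live == "LIVE" & S$dec &
          S$comp %in% c("GC_LZ", "GC_DZ")
        S$decov[tgt] <- iv$dose_fraction * config$capture_cmax
      }
    },
    stop("unknown intervention kind: ", iv$kind, call. = FALSE)
  )
  invisible(S)
}

# duplicate cell rows at `idx`, returning the indices of the new copies
.grow <- function(S, idx) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  new_idx <- S$n + seq_len(k)
  for (col in c("founder", "clone", "comp", "live", "vcall", "lvcall",
                "jcall", "ljcall", "junction", "ljunction", "hseq", "lseq",
                "affinity", "captured", "myc", "budget", "divlab", "zsg",
                "mch", "dec", "born", "mut_h", "mut_l", "decov", "sel_step")) {
    S[[col]] <- c(S[[col]], S[[col]][idx])
  }
  S$id <- c(S$id, S$next_id - 1L + seq_len(k))
  S$next_id <- S$next_id + k
  S$n <- S$n + k
  new_idx
}

# one-substitution-per-flagged-chain mutation core shared by mutate_chain()
# and the simulator's division phase; uses the global RNG
.mutate_one <- function(hseq, lseq, vcall, affinity, cfg, do_h, do_l) {
  fate <- "OK"
  ev_h <- ""; ev_l <- ""
  for (ch in c("heavy", "light")) {
    if (!(if (ch == "heavy") do_h else do_l)) next
    s <- if (ch == "heavy") hseq else lseq
    pos <- NA_integer_; to <- NA_character_
    if (ch == "heavy" && cfg$site_hotspot_prob > 0) {
      open_sites <- which(cfg$affinity_sites$chain == "heavy" &
                            cfg$affinity_sites$v_call == vcall)
      if (length(open_sites)) {
        open_sites <- open_sites[substr(
          s, cfg$affinity_sites$position[open_sites],
          cfg$affinity_sites$position[open_sites]) !=
            cfg$affinity_sites$to_res[open_sites]]
      }
      if (length(open_sites) && stats::runif(1) < cfg$site_hotspot_prob) {
        k <- if (length(open_sites) > 1L) sample(open_sites, 1L) else
          open_sites
        pos <- cfg$affinity_sites$position[k]
        to <- cfg$affinity_sites$to_res[k]
      }
    }
    cur_at <- function(p) substr(s, p, p)
    if (is.na(pos)) {
      pos <- sample.int(nchar(s), 1L)
      to <- sample(AA_ALPHABET[AA_ALPHABET != cur_at(pos)], 1L)
    }
    cur <- cur_at(pos)
    substr(s, pos, pos) <- to
    ev <- paste0(pos, ":", cur, ">", to)
    if (ch == "heavy") { hseq <- s; ev_h <- ev } else { lseq <- s; ev_l <- ev }
    sites <- cfg$affinity_sites
    hit <- sites$chain == ch & sites$position == pos & sites$to_res == to
    if (ch == "heavy") hit <- hit & sites$v_call == vcall
    if (any(hit)) {
      affinity <- affinity * sites$factor[which(hit)[1L]]
    } else {
      u <- stats::runif(1)
      if (u < cfg$lethal_fraction) {
        fate <- "LETHAL"
      } else if (u < cfg$lethal_fraction + cfg$deleterious_fraction) {
        affinity <- affinity * cfg$deleterious_factor
      }
    }
  }
  list(hseq = hseq, lseq = lseq, affinity = affinity, fate = fate,
       ev_h = ev_h, ev_l = ev_l)
}

# divide cells at `mothers`: each is replaced by two daughters (the mother
# row is reused as daughter 1). Division-label bookkeeping follows the
# doxycycline switch; `mutate = TRUE` applies somatic mutation per daughter.
.divide <- function(S, mothers, cfg, mutate) {
  if (length(mothers) == 0L) return(invisible(S))
  new_idx <- .grow(S, mothers)
  kids <- c(mothers, new_idx)
  S$budget[kids] <- S$budget[kids] - 1L
  S$born[new_idx] <- S$step
  if (dox_active(S)) {
    S$mch[kids] <- S$mch[kids] / 2
    S$divlab[kids] <- S$divlab[kids] + 1L
  }
  if (mutate && cfg$mutation_rate > 0) {
    nk <- length(kids)
    do_h <- stats::runif(nk) < cfg$mutation_rate
    do_l <- stats::runif(nk) < cfg$mutation_rate
    for (j in which(do_h | do_l)) {
      i <- kids[j]
      m <- .mutate_one(S$hseq[i], S$lseq[i], S$vcall[i], S$affinity[i],
                       cfg, do_h[j], do_l[j])
      S$hseq[i] <- m$hseq; S$lseq[i] <- m$lseq
      S$affinity[i] <- m$affinity
      if (nzchar(m$ev_h)) {
        S$mut_h[i] <- if (nzchar(S$mut_h[i]))
          paste0(S$mut_h[i], ";", m$ev_h) else m$ev_h
      }
      if (nzchar(m$ev_l)) {
        S$mut_l[i] <- if (nzchar(S$mut_l[i]))
          paste0(S$mut_l[i], ";", m$ev_l) else m$ev_l
      }
      if (m$fate == "LETHAL") S$live[i] <- "DEAD"
    }
  }
  invisible(S)
}

#' Advance the simulation by one time step
#'
#' Phases, in order: scheduled interventions; light-zone (LZ) positive
#' selection with probability proportional to captured antigen (soft,
#' capped at 1, `n_select` expected winners) and death of unselected LZ
#' cells; dark-zone division with somatic mutation, spent cells returning to
#' the LZ; prePC maturation and affinity-independent LZ export to the prePC
#' compartment (the PC division budget is set here from the historic Myc
#' proxy, scaled by `il21_scale`); PC division without mutation; death
#' (DYING cells die, live PCs are marked DYING at the configured hazard) and
#' optional egress; antibody secretion into serum.
#'
#' @param state a `sim_state` (modified in place).
#' @param config a `sim_config`.
#' @return the state, invisibly.
#' @export
sim_step <- function(state, config) {
  S <- state
  cfg <- config
  for (iv in cfg$interventions) apply_intervention(S, iv, cfg)

  ## 1. LZ selection ------------------------------------------------------
  lz <- which(S$live == "LIVE" & S$comp == "GC_LZ")
  if (length(lz) && !S$sel_off) {
    cap <- ifelse(!is.na(S$decov[lz]), S$decov[lz],
                  antigen_capture(S$affinity[lz], .cmax_now(S, cfg),
                                  cfg$capture_K))
    w <- cap^(1 / cfg$selection_temperature)
    sel <- logical(length(lz))
    if (sum(w) > 0) {
      p <- pmin(1, cfg$n_select * w / sum(w))
      sel <- stats::runif(length(lz)) < p
    }
    si <- lz[sel]
    S$captured[si] <- cap[sel]
    S$myc[si] <- myc_level(cap[sel], cfg$myc_m0, cfg$myc_k)
    S$budget[si] <- division_budget(S$myc[si], cfg$division_beta, 1,
                                    cfg$division_mode)
    S$comp[si] <- "GC_DZ"
    S$sel_step[si] <- S$step
    S$decov[si] <- NA_real_  # delivered antigen is consumed at selection
    ui <- lz[!sel]
    dies <- ui[stats::runif(length(ui)) < cfg$gc_death_rate]
    S$live[dies] <- "DEAD"
  } else if (length(lz) && S$sel_off) {
    dies <- lz[stats::runif(length(lz)) < cfg$gc_death_rate]
    S$live[dies] <- "DEAD"
  }

  ## 2. DZ division and return -------------------------------------------
  if (!S$gc_div_off) {
    mothers <- which(S$live == "LIVE" & S$comp == "GC_DZ" & S$budget > 0L)
    .divide(S, mothers, cfg, mutate = TRUE)
  }
  back <- S$live == "LIVE" & S$comp == "GC_DZ" & S$budget <= 0L
  S$comp[back] <- "GC_LZ"

  ## 3. prePC maturation, then affinity-independent export ----------------
  S$comp[S$live == "LIVE" & S$comp == "PREPC"] <- "PC"
  lz <- which(S$live == "LIVE" & S$comp == "GC_LZ")
  if (length(lz)) {
    ex <- lz[stats::runif(length(lz)) < cfg$pc_export_prob]
    if (length(ex)) {
      S$comp[ex] <- "PREPC"
      # export is the precursor's final help interaction: Myc is refreshed
      # from a fresh (affinity- or DEC-override-proportional) capture
      # reading, then spent Tfh-independently as the PC division budget
      cap_ex <- ifelse(!is.na(S$decov[ex]), S$decov[ex],
                       antigen_capture(S$affinity[ex], .cmax_now(S, cfg),
                                       cfg$capture_K))
      S$captured[ex] <- cap_ex
      S$myc[ex] <- myc_level(cap_ex, cfg$myc_m0, cfg$myc_k)
      S$sel_step[ex] <- S$step
      S$decov[ex] <- NA_real_
      S$budget[ex] <- pmin(cfg$pc_budget_cap, division_budget(
        S$myc[ex], cfg$division_beta,
        cfg$pc_division_scale * cfg$il21_scale, cfg$division_mode))
      S$export_log[[length(S$export_log) + 1L]] <- c(
        step = S$step, n_export = length(ex), sum_aff_export =
          sum(S$affinity[ex]), n_lz = length(lz),
        sum_aff_lz = sum(S$affinity[lz]))
    }
  }

  ## 4. PC division (no further mutation; plasmablasts cycle faster than
  ## the 12 h step, so up to pc_divisions_per_step rounds execute) --------
  for (r in seq_len(cfg$pc_divisions_per_step)) {
    mothers <- which(S$live == "LIVE" & S$comp == "PC" & S$budget > 0L)
    if (!length(mothers)) break
    .divide(S, mothers, cfg, mutate = FALSE)
  }

  ## 5. death and egress ---------------------------------------------------
  S$live[S$live == "DYING"] <- "DEAD"
  pc <- which(S$live == "LIVE" & S$comp == "PC")
  hazard <- if (S$taci) 1 else cfg$pc_death_rate
  if (length(pc) && hazard > 0) {
    dying <- pc[stats::runif(length(pc)) < hazard]
    S$live[dying] <- "DYING"
  }
  egress <- if (S$fty) 0 else cfg$pc_egress_rate
  if (egress > 0) {
    pc <- which(S$live == "LIVE" & S$comp == "PC")
    out <- pc[stats::runif(length(pc)) < egress]
    S$comp[out] <- "EGRESSED"
  }

  ## 6. secretion ----------------------------------------------------------
  if (is.finite(cfg$serum_halflife_steps)) {
    S$serum <- S$serum * 2^(-1 / cfg$serum_halflife_steps)
  }
  sp <- secrete(S, cfg)
  if (nrow(sp)) {
    key <- paste0(sp$clone_id, "|", sprintf("%.12g", sp$kd))
    known <- key %in% names(S$serum)
    S$serum[key[known]] <- S$serum[key[known]] + sp$concentration[known]
    add <- sp$concentration[!known]
    names(add) <- key[!known]
    S$serum <- c(S$serum, add)
  }
  S$step <- S$step + 1L
  S$serum_steps[[S$step]] <- S$serum
  S$event_log[[length(S$event_log) + 1L]] <- c(
    step = S$step,
    n_gc_lz = sum(S$live == "LIVE" & S$comp == "GC_LZ"),
    n_gc_dz = sum(S$live == "LIVE" & S$comp == "GC_DZ"),
    n_prepc = sum(S$live == "LIVE" & S$comp == "PREPC"),
    n_pc = sum(S$live == "LIVE" & S$comp == "PC"),
    n_dying = sum(S$live == "DYING"),
    n_dead = sum(S$live == "DEAD"),
    n_egressed = sum(S$comp == "EGRESSED" & S$live != "DEAD"),
    serum_total = sum(S$serum))
  invisible(S)
}

#' One step of antibody secretion by live plasma cells
#'
#' Each live, node-resident PC contributes `secretion_rate` concentration
#' units of an antibody species with dissociation constant
#' `kd = kd0 / affinity`, aggregated over cells with identical
#' (clone, genotype) — identical genotypes share an affinity and hence a kd.
#'
#' @param state a `sim_state`.
#' @param config a `sim_config`.
#' @return data.frame with columns `clone_id`, `concentration`, `kd`: this
#'   step's contribution (empty when no PC is alive).
#' @export
secrete <- function(state, config) {
  S <- state
  pc <- which(S$live == "LIVE" & S$comp == "PC")
  if (!length(pc)) {
    return(data.frame(clone_id = character(0), concentration = numeric(0),
                      kd = numeric(0), stringsAsFactors = FALSE))
  }
  kd <- config$kd0 / S$affinity[pc]
  key <- paste0(S$clone[pc], "|", sprintf("%.12g", kd))
  agg <- tapply(rep(config$secretion_rate, length(pc)), key, sum)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  data.frame(
    clone_id = vapply(parts, `[`, "", 1L),
    concentration = as.numeric(agg),
    kd = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
}

#' Census of live cells by compartment
#' @param state a `sim_state`.
#' @return named integer vector of LIVE cell counts per compartment plus
#'   `DYING` and `DEAD` tallies.
#' @export
census <- function(state) {
  S <- state
  c(GC_LZ = sum(S$live == "LIVE" & S$comp == "GC_LZ"),
    GC_DZ = sum(S$live == "LIVE" & S$comp == "GC_DZ"),
    PREPC = sum(S$live == "LIVE" & S$comp == "PREPC"),
    PC = sum(S$live == "LIVE" & S$comp == "PC"),
    EGRESSED = sum(S$live == "LIVE" & S$comp == "EGRESSED"),
    DYING = sum(S$live == "DYING"),
    DEAD = sum(S$live == "DEAD"))
}

# snapshot of node-resident, non-dead cells as a data.frame; when
# snapshot_sample is finite, each cell type is uniformly subsampled to at
# most that many cells (sequencing-depth analog)
.snapshot_cells <- function(S, cfg) {
  keep <- which(S$live != "DEAD" & S$comp != "EGRESSED")
  if (is.finite(cfg$snapshot_sample) && length(keep)) {
    ct <- c(GC_LZ = "GC", GC_DZ = "GC", PREPC = "prePC",
            PC = "PC")[S$comp[keep]]
    keep <- sort(unlist(lapply(split(keep, ct), function(ix) {
      if (length(ix) > cfg$snapshot_sample)
        sample(ix, cfg$snapshot_sample) else ix
    }), use.names = FALSE))
  }
  day <- step_to_day(S$step, cfg)
  meas <- S$mch[keep] * exp(stats::rnorm(length(keep), 0, cfg$mcherry_sigma))
  ids <- if (length(keep)) paste0(cfg$animal, "_T", day, "_", S$id[keep])
    else character(0)
  data.frame(
    cell_id = ids,
    animal = rep(cfg$animal, length(keep)),
    timepoint = rep(day, length(keep)),
    clone_gt = S$clone[keep],
    founder = S$founder[keep],
    compartment = S$comp[keep],
    celltype = c(GC_LZ = "GC", GC_DZ = "GC", PREPC = "prePC",
                 PC = "PC")[S$comp[keep]],
    v_call = S$vcall[keep],
    j_call = S$jcall[keep],
    light_v_call = S$lvcall[keep],
    light_j_call = S$ljcall[keep],
    junction = S$junction[keep],
    light_junction = S$ljunction[keep],
    heavy_seq = S$hseq[keep],
    light_seq = S$lseq[keep],
    affinity = S$affinity[keep],
    captured = S$captured[keep],
    myc = S$myc[keep],
    budget = S$budget[keep],
    last_selection_step = S$sel_step[keep],
    divisions_since_label = S$divlab[keep],
    zsg = S$zsg[keep],
    mcherry = meas,
    mcherry_true = S$mch[keep],
    live_state = S$live[keep],
    dec_targetable = S$dec[keep],
    born_step = S$born[keep],
    mut_log_heavy = S$mut_h[keep],
    mut_log_light = S$mut_l[keep],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a full simulation
#'
#' Seeds the RNG from `config$seed`, initializes founders, advances
#' `horizon_steps` steps and assembles the output: per-cell snapshots at the
#' configured days, an AIRR-style paired-chain repertoire table for the
#' snapshot cells, the cumulative serum series, the per-step event log and
#' the export log. Identical `(config, seed)` yield identical output.
#'
#' @param config a `sim_config`.
#' @return an object of class `sim_output`: list with elements `cells`,
#'   `repertoire`, `serum`, `event_log`, `export_log`, `final_state`,
#'   `config`.
#' @export
run_simulation <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid simulation configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  set.seed(config$seed)
  S <- new_sim_state(config)
  snap_steps <- sort(unique(c(
    if (!is.null(config$snapshot_days))
      day_to_step(config$snapshot_days, config),
    config$horizon_steps)))
  snap_steps <- snap_steps[snap_steps >= 0 & snap_steps <= config$horizon_steps]
  snaps <- list()
  if (0L %in% snap_steps) snaps[["0"]] <- .snapshot_cells(S, config)
  if (config$horizon_steps >= 1L) {
    for (t in seq_len(config$horizon_steps)) {
      sim_step(S, config)
      if (t %in% snap_steps) snaps[[as.character(t)]] <-
          .snapshot_cells(S, config)
    }
  }
  cells <- do.call(rbind, snaps)
  rownames(cells) <- NULL
  serum <- serum_series(S, config)
  ev <- as.data.frame(do.call(rbind, S$event_log))
  if (nrow(ev)) ev$day <- step_to_day(ev$step, config)
  ex <- as.data.frame(do.call(rbind, S$export_log))
  out <- list(cells = cells, repertoire = repertoire_from_cells(cells),
              serum = serum, event_log = ev, export_log = ex,
              final_state = S, config = config)
  class(out) <- "sim_output"
  out
}

# cumulative serum series as a long data.frame
serum_series <- function(S, cfg) {
  rows <- lapply(seq_along(S$serum_steps), function(t) {
    v <- S$serum_steps[[t]]
    if (!length(v)) return(NULL)
    parts <- strsplit(names(v), "|", fixed = TRUE)
    data.frame(timepoint = step_to_day(t, cfg),
               clone_id = vapply(parts, `[`, "", 1L),
               concentration = as.numeric(v),
               kd = as.numeric(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(timepoint = numeric(0), clone_id = character(0),
                      concentration = numeric(0), kd = numeric(0))
  }
  out
}

#' Build the AIRR-style repertoire table from a cell snapshot table
#'
#' Two rows per cell (IGH + IGK) with AIRR Rearrangement core columns plus
#' the custom per-cell columns used downstream (`c_celltype`, `c_zsg`,
#' `c_mcherry`, `c_live_state`, `c_timepoint`, `c_animal`).
#'
#' @param cells cell snapshot data.frame (see [run_simulation()]).
#' @return AIRR-style data.frame.
#' @export
repertoire_from_cells <- function(cells) {
  g <- germline_set()
  mk <- function(locus) {
    heavy <- locus == "IGH"
    data.frame(
      cell_id = cells$cell_id,
      locus = locus,
      v_call = if (heavy) cells$v_call else cells$light_v_call,
      j_call = if (heavy) cells$j_call else cells$light_j_call,
      sequence_alignment = if (heavy) cells$heavy_seq else cells$light_seq,
      germline_alignment = if (heavy) unname(g$heavy[cells$v_call]) else
        unname(g$light[cells$light_v_call]),
      junction_aa = if (heavy) cells$junction else cells$light_junction,
      c_celltype = cells$celltype,
      c_zsg = cells$zsg,
      c_mcherry = cells$mcherry,
      c_live_state = cells$live_state,
      c_timepoint = cells$timepoint,
      c_animal = cells$animal,
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk("IGH"), mk("IGK"))
  out <- out[order(out$cell_id, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output> animal ", x$config$animal, ", ",
      x$config$horizon_steps, " steps, ",
      length(unique(x$cells$timepoint)), " snapshot(s)\n", sep = "")
  fin <- x$event_log[nrow(x$event_log), ]
  cat("  final census: GC ", fin$n_gc_lz + fin$n_gc_dz, " (LZ ", fin$n_gc_lz,
      "/DZ ", fin$n_gc_dz, "), prePC ", fin$n_prepc, ", PC ", fin$n_pc,
      ", dead ", fin$n_dead, "\n", sep = "")
  invisible(x)
}

#' Pooled export-vs-LZ affinity comparison
#'
#' Summarizes the export log of one or more runs: the concentration-weighted
#' mean affinity of cells at the moment of prePC export and of the
#' contemporaneous LZ pool, pooled over all export events. Under
#' affinity-independent export the two should agree.
#'
#' @param ... one or more `sim_output` objects (or a list of them).
#' @return list with `mean_export`, `mean_lz` and `relative_difference`.
#' @export
export_affinity_summary <- function(...) {
  outs <- list(...)
  if (length(outs) == 1L && !inherits(outs[[1]], "sim_output")) {
    outs <- outs[[1]]
  }
  logs <- do.call(rbind, lapply(outs, function(o) as.matrix(o$export_log)))
  me <- sum(logs[, "sum_aff_export"]) / sum(logs[, "n_export"])
  ml <- sum(logs[, "sum_aff_lz"]) / sum(logs[, "n_lz"])
  list(mean_export = me, mean_lz = ml,
       relative_difference = (me - ml) / ml)
}
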