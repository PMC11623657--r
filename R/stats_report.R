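#' Run a standard statistical test and return a tidy result
#'
#' Wraps the tests used across the analyses: two-sided Student's t
#' (paired or unpaired), one-way ANOVA and Kruskal-Wallis. Small samples
#' are rejected explicitly rather than returning silent NaN; Kruskal-Wallis
#' uses the chi-squared approximation with the standard tie correction (as
#' implemented by [stats::kruskal.test()]).
#'
#' @param name `"t"`, `"anova"` or `"kruskal"`.
#' @param samples list of numeric vectors, one per group (exactly two for
#'   `"t"`).
#' @param paired paired t-test across equal-length samples (t only).
#' @param stratum optional label stored in the result.
#' @return one-row data.frame: `test`, `statistic`, `p_value`, `n`,
#'   `direction` (sign of the first-minus-second group mean for t,
#'   `"none"` otherwise), `stratum`.
#' @export
run_test <- function(name = c("t", "anova", "kruskal"), samples,
                     paired = FALSE, stratum = NA_character_) {
  name <- match.arg(name)
  stopifnot(is.list(samples))
  n_per <- lengths(samples)
  n <- sum(n_per)
  direction <- "none"
  if (name == "t") {
    if (length(samples) != 2L) stop("t-test needs exactly two samples",
                                    call. = FALSE)
    if (paired && n_per[1] != n_per[2]) {
      stop("paired t-test needs equal-length samples", call. = FALSE)
    }
    if (any(n_per < 2L)) stop("need at least 2 observations per group",
                              call. = FALSE)
    delta <- mean(samples[[1]]) - mean(samples[[2]])
    sd_ok <- if (paired) stats::sd(samples[[1]] - samples[[2]]) > 0 else
      stats::sd(unlist(samples)) > 0
    if (!sd_ok) {
      res <- list(statistic = 0, p.value = 1)
    } else {
      res <- stats::t.test(samples[[1]], samples[[2]], paired = paired,
                           var.equal = !paired)
    }
    direction <- if (delta > 0) "greater" else if (delta < 0) "less" else
      "none"
  } else {
    if (length(samples) < 2L) stop("need at least two groups", call. = FALSE)
    if (any(n_per < 2L)) stop("need at least 2 observations per group",
                              call. = FALSE)
    y <- unlist(samples)
    g <- factor(rep(seq_along(samples), n_per))
    if (name == "anova") {
      fit <- stats::aov(y ~ g)
      tab <- summary(fit)[[1]]
      res <- list(statistic = tab[["F value"]][1],
                  p.value = tab[["Pr(>F)"]][1])
    } else {
      kt <- stats::kruskal.test(y, g)
      res <- list(statistic = unname(kt$statistic), p.value = kt$p.value)
    }
  }
  data.frame(test = name, statistic = unname(res$statistic),
             p_value = unname(res$p.value), n = n, direction = direction,
             stratum = stratum, stringsAsFactors = FALSE)
}

PRESET_NAMES <- c("FIG1_NODES", "FIG2_DIVISION", "FIG4_CD40L", "FIG5_DEC")

# derive a per-animal child seed from a master seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Resolve an experiment preset to simulation configurations
#'
#' Presets mirror the package's four reference experimental designs:
#' \describe{
#'   \item{FIG1_NODES}{fate-label GC cells on day 5, sample GC + PC on
#'     day 14; genotype-node and affinity-mutation analysis.}
#'   \item{FIG2_DIVISION}{doxycycline label shut-off on day 10, sort PCs by
#'     label dilution on day 12; diversity and target-V comparisons between
#'     divided (LO) and undivided (HI) gates.}
#'   \item{FIG4_CD40L}{fate-label day 8, four arms (isotype, anti-CD40L,
#'     anti-CD40L + TACI-Ig, TACI-Ig) from day 10 with FTY720 retention;
#'     snapshots day 10/16/32 and the serum avidity-ratio series.}
#'   \item{FIG5_DEC}{graded BCR-independent antigen delivery (DEC205) on
#'     day 6 at dose fractions 0, 1/16, 1/4, 1; Myc and division readouts
#'     on day 8.}
#' }
#'
#' @param preset one of `r paste(PRESET_NAMES, collapse = ", ")`.
#' @param animal label for the run.
#' @param seed integer seed for the run.
#' @param arm arm name (FIG4_CD40L) or dose fraction (FIG5_DEC).
#' @param ... overrides forwarded to [simulation_config()].
#' @return a `sim_config`.
#' @export
preset_config <- function(preset = PRESET_NAMES, animal = "A1", seed = 1L,
                          arm = NULL, ...) {
  preset <- match.arg(preset)
  base <- list(animal = animal, seed = seed)
  cfg_args <- switch(preset,
    FIG1_NODES = {
      base$horizon_steps <- 20L   # day 14
      base$snapshot_days <- 14
      base$snapshot_sample <- 300
      base$interventions <- list(intervention("TAMOXIFEN_S1PR2", 2L))
      base
    },
    FIG2_DIVISION = {
      base$horizon_steps <- 16L   # day 12
      base$snapshot_days <- 12
      base$snapshot_sample <- 300
      base$interventions <- list(intervention("DOXYCYCLINE", 12L))
      base
    },
    FIG4_CD40L = {
      arm <- if (is.null(arm)) "isotype" else arm
      arm <- match.arg(arm, c("isotype", "anti_cd40l", "anti_cd40l_taci",
                              "taci"))
      ivs <- list(intervention("TAMOXIFEN_S1PR2", 8L),   # day 8
                  intervention("FTY720", 12L))           # day 10
      if (arm %in% c("anti_cd40l", "anti_cd40l_taci")) {
        ivs <- c(ivs, list(intervention("ANTI_CD40L", 12L)))
      }
      if (arm %in% c("taci", "anti_cd40l_taci")) {
        ivs <- c(ivs, list(intervention("TACI_IG", 12L)))
      }
      base$horizon_steps <- 56L   # day 32
      base$snapshot_days <- c(10, 16, 32)
      base$snapshot_sample <- 300
      base$interventions <- ivs
      base
    },
    FIG5_DEC = {
      dose <- if (is.null(arm)) 1 else as.numeric(arm)
      base$n_founders <- 60L
      base$dec_wt_fraction <- 0.25
      base$division_mode <- "poisson"  # keeps the dose-division expectation
                                       # proportional, free of rounding steps
      base$horizon_steps <- 10L   # day 9
      base$snapshot_days <- 9
      base$interventions <- list(
        intervention("DEC_OVA", 4L, dose_fraction = dose),   # day 6
        intervention("DOXYCYCLINE", 4L))
      base
    })
  extra <- list(...)
  cfg_args[names(extra)] <- extra
  do.call(simulation_config, cfg_args)
}

# run + annotate one virtual animal; returns annotated PC-relevant tables
.sim_annotated <- function(cfg) {
  out <- run_simulation(cfg)
  pr <- pair_chains(out$repertoire)
  ann <- annotate_repertoire(pr$paired, target_v = cfg$target_v,
                             site_set = cfg$affinity_sites)
  list(out = out, annotated = ann)
}

#' Run an experiment preset across virtual animals
#'
#' Simulates `n_animals` replicate animals (child seeds derived from
#' `seed`), runs the preset's analysis recipe and returns all figure-analog
#' tables plus directional checks. Output is deterministic given
#' `(preset, n_animals, seed)`.
#'
#' @param preset preset name (see [preset_config()]).
#' @param n_animals virtual animals per arm.
#' @param seed master seed.
#' @param ... configuration overrides forwarded to [preset_config()].
#' @return a list report bundle; contents depend on the preset. All bundles
#'   carry `preset`, `seed` and `n_animals`.
#' @export
run_preset <- function(preset = PRESET_NAMES, n_animals = 5L, seed = 1L,
                       ...) {
  preset <- match.arg(preset)
  bundle <- list(preset = preset, seed = seed, n_animals = n_animals)
  animals <- sprintf("A%d", seq_len(n_animals))
  if (preset == "FIG1_NODES") {
    ann_all <- list(); nodes_all <- list()
    for (i in seq_len(n_animals)) {
      r <- .sim_annotated(preset_config(preset, animals[i],
                                        child_seed(seed, i), ...))
      ann <- r$annotated
      ann <- ann[ann$c_celltype %in% c("GC", "PC", "prePC"), ]
      ann_all[[i]] <- ann
      nodes_all[[i]] <- collapse_genotypes(ann)
    }
    ann <- do.call(rbind, ann_all)
    nodes <- do.call(rbind, nodes_all)
    bundle$summary <- node_summary(nodes, ann)
    bundle$nodes <- nodes
    cf <- bundle$summary$cell_flag_freq
    pooled <- cf[cf$animal == "pooled", ]
    bundle$checks <- data.frame(
      check = "pc_flag_freq_gt_gc",
      pass = pooled$flag_freq[pooled$celltype == "PC"] >
        pooled$flag_freq[pooled$celltype == "GC"])
  } else if (preset == "FIG2_DIVISION") {
    per <- list()
    for (i in seq_len(n_animals)) {
      r <- .sim_annotated(preset_config(preset, animals[i],
                                        child_seed(seed, i), ...))
      pc <- r$annotated[r$annotated$c_celltype == "PC" &
                          r$annotated$c_live_state == "LIVE", ]
      g <- gate_by_label(pc$c_mcherry)
      pc$gate <- as.character(g$gate)
      per[[i]] <- pc
    }
    pc <- do.call(rbind, per)
    bundle$cells <- pc
    tv <- pc$v_call == "IGHV1-72*01"
    bundle$target_v <- compare_by_division(pc$c_animal, pc$gate, tv)
    bundle$affinity_flag <- compare_by_division(pc$c_animal, pc$gate,
                                                pc$affinity_flag)
    lohi <- pc[pc$gate %in% c("LO", "HI"), ]
    bundle$diversity <- diversity_summary(
      lohi, paste(lohi$c_animal, lohi$gate, sep = ":"))
    div <- bundle$diversity
    div$animal <- sub(":.*", "", div$stratum)
    div$gate <- sub(".*:", "", div$stratum)
    ch <- stats::reshape(div[c("animal", "gate", "chao1")],
                         idvar = "animal", timevar = "gate",
                         direction = "wide")
    bundle$checks <- data.frame(
      check = c("targetv_lo_gt_hi", "chao1_lo_lt_hi"),
      pass = c(bundle$target_v$direction == "LO>HI",
               mean(ch$chao1.LO, na.rm = TRUE) <
                 mean(ch$chao1.HI, na.rm = TRUE)))
  } else if (preset == "FIG4_CD40L") {
    arms <- c("isotype", "anti_cd40l", "anti_cd40l_taci", "taci")
    arm_res <- list()
    for (arm in arms) {
      rows <- list(); serum <- list(); gc_census <- list(); ml <- list()
      for (i in seq_len(n_animals)) {
        cfg <- preset_config(preset, paste0(arm, "_", animals[i]),
                             child_seed(seed, match(arm, arms) * 1000 + i),
                             arm = arm, ...)
        r <- .sim_annotated(cfg)
        ann <- r$annotated
        pcs <- ann[ann$c_celltype == "PC" & ann$c_zsg &
                     ann$c_live_state == "LIVE", ]
        frac <- tapply(pcs$v_call == cfg$target_v, pcs$c_timepoint, mean)
        rows[[i]] <- data.frame(
          animal = animals[i], timepoint = as.numeric(names(frac)),
          n_pc = as.integer(table(pcs$c_timepoint)[names(frac)]),
          targetv_frac = as.numeric(frac),
          chao1 = vapply(split(pcs, pcs$c_timepoint), function(d) {
            if (nrow(d) == 0) NA_real_ else
              chao1(table(d$clone_id))
          }, 0)[names(frac)],
          stringsAsFactors = FALSE)
        ml[[i]] <- data.frame(animal = animals[i],
                              timepoint = pcs$c_timepoint,
                              mutation_count = pcs$mutation_count)
        s <- r$out$serum
        s$animal <- animals[i]
        serum[[i]] <- s
        ev <- r$out$event_log
        gc_census[[i]] <- data.frame(animal = animals[i], day = ev$day,
                                     n_gc = ev$n_gc_lz + ev$n_gc_dz)
      }
      serum <- do.call(rbind, serum)
      ratio_by_day <- do.call(rbind, lapply(
        split(serum, list(serum$animal, serum$timepoint), drop = TRUE),
        function(s) data.frame(animal = s$animal[1],
                               timepoint = s$timepoint[1],
                               np_ratio = np_ratio(s))))
      fold <- tapply(seq_len(nrow(serum)), serum$animal, function(ii) {
        affinity_fold_change(serum[ii, ], 11, 32)
      })
      arm_res[[arm]] <- list(
        pc_table = do.call(rbind, rows),
        mutation_load = do.call(rbind, ml),
        gc_census = do.call(rbind, gc_census),
        np_ratio = ratio_by_day[order(ratio_by_day$animal,
                                      ratio_by_day$timepoint), ],
        fold_change = data.frame(animal = names(fold),
                                 fold = as.numeric(fold)))
    }
    bundle$arms <- arm_res
    iso <- arm_res$isotype$pc_table
    cd40 <- arm_res$anti_cd40l$pc_table
    mean_frac <- function(tab, tp) mean(tab$targetv_frac[tab$timepoint == tp],
                                        na.rm = TRUE)
    gc_after <- arm_res$anti_cd40l$gc_census
    bundle$checks <- data.frame(
      check = c("cd40l_gc_ablated_d12_on",
                "cd40l_targetv_rises_d10_d16",
                "cd40l_lower_mutation_load_d16",
                "isotype_fold_gt_1", "taci_fold_near_1"),
      pass = c(
        all(gc_after$n_gc[gc_after$day >= 12] == 0),
        mean_frac(cd40, 16) > mean_frac(cd40, 10),
        mean(arm_res$anti_cd40l$mutation_load$mutation_count[
          arm_res$anti_cd40l$mutation_load$timepoint == 16]) <
          mean(arm_res$isotype$mutation_load$mutation_count[
            arm_res$isotype$mutation_load$timepoint == 16]),
        mean(arm_res$isotype$fold_change$fold) > 1,
        abs(mean(arm_res$taci$fold_change$fold) - 1) <
          abs(mean(arm_res$isotype$fold_change$fold) - 1)))
  } else { # FIG5_DEC
    doses <- c(0, 1 / 16, 1 / 4, 1)
    rows <- list()
    for (di in seq_along(doses)) {
      for (i in seq_len(n_animals)) {
        cfg <- preset_config(preset, animals[i],
                             child_seed(seed, di * 1000 + i),
                             arm = doses[di], ...)
        out <- run_simulation(cfg)
        snap <- out$cells[out$cells$timepoint == 9 &
                            out$cells$live_state == "LIVE", ]
        tgt <- snap[snap$dec_targetable &
                      snap$celltype %in% c("GC", "prePC", "PC"), ]
        # dose-attributable readouts: cells whose last selection happened
        # at or after antigen delivery (day 6 = step 4); others sit at the
        # help-independent baseline
        post <- !is.na(tgt$last_selection_step) &
          tgt$last_selection_step >= 4
        myc_win <- ifelse(post, tgt$myc, cfg$myc_m0)
        div_win <- ifelse(post, tgt$divisions_since_label, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          dose = doses[di], animal = animals[i],
          n_targeted = nrow(tgt),
          mean_myc = mean(myc_win),
          mean_divisions = mean(div_win),
          frac_selected_post_delivery = mean(post),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    bundle$dose_response <- tab
    agg <- tapply(tab$mean_myc, tab$dose, mean)
    agg_div <- tapply(tab$mean_divisions, tab$dose, mean)
    bundle$checks <- data.frame(
      check = c("myc_nondecreasing_in_dose",
                "division_nondecreasing_in_dose"),
      pass = c(!is.unsorted(as.numeric(agg)),
               !is.unsorted(as.numeric(agg_div))))
  }
  bundle
}

#' Write a report bundle to disk
#'
#' Writes every data.frame in the bundle as CSV and the directional checks
#' plus scalar metadata as JSON, with deterministic file content for a
#' deterministic bundle.
#'
#' @param bundle a [run_preset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_node <- function(x, name) {
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    } else if (is.list(x)) {
      for (nm in names(x)) write_node(x[[nm]], paste0(name, "_", nm))
    }
  }
  for (nm in setdiff(names(bundle), c("preset", "seed", "n_animals"))) {
    write_node(bundle[[nm]], nm)
  }
  meta <- list(preset = bundle$preset, seed = bundle$seed,
               n_animals = bundle$n_animals)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
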