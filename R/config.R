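#' Construct a simulation configuration
#'
#' All knobs of the lymph-node model in one validated object. The defaults
#' are the study conditions used throughout the package's tests and presets:
#' a 12-hour time step, founders seeded on day 4 after immunization, a
#' germinal center (GC) limited by a fixed number of T-cell-help selection
#' slots per step, affinity-independent export of light-zone (LZ) cells into
#' the plasma-cell (PC) pathway, and PC division budgets set once at export
#' from the historic Myc proxy of the last LZ selection.
#'
#' @param n_founders number of founder clones seeded into the GC.
#' @param founder_cells cells per founder clone at step 0.
#' @param v_gene_pool named numeric vector of heavy V-gene assignment
#'   probabilities (must match names in [germline_set()]`$heavy`).
#' @param target_v the designated high-affinity V analog.
#' @param baseline_affinity named numeric vector, per-V germline-encoded
#'   relative affinity (dimensionless, > 0).
#' @param mutation_rate substitutions per chain per division (probability).
#' @param affinity_sites data.frame with columns `chain`, `v_call`,
#'   `position`, `to_res`, `factor`: designated substitutions that multiply
#'   affinity by `factor`. Defaults to the W33L (x8), K59R (x2), Y99G (x2)
#'   analogs on the target V.
#' @param site_hotspot_prob probability that a heavy-chain substitution on a
#'   V carrying designated sites is drawn from the site table instead of
#'   uniformly — the somatic-hypermutation hotspot targeting that makes the
#'   canonical affinity-enhancing replacements recurrent in real repertoires.
#' @param lethal_fraction,deleterious_fraction,deleterious_factor fate mix of
#'   non-designated substitutions; the remainder is neutral.
#' @param capture_cmax,capture_K antigen-capture saturation parameters
#'   (see [antigen_capture()]).
#' @param antigen_plateau_steps steps during which the antigen depot on
#'   follicular dendritic cells is at full strength.
#' @param antigen_halflife_steps half-life, in steps, of the antigen depot
#'   after the plateau: the effective `capture_cmax` decays exponentially,
#'   so the response wanes (`Inf` = no decay).
#' @param myc_m0,myc_k intercept and slope of the Myc proxy in captured
#'   antigen (see [myc_level()]); `myc_k = 0` decouples division from help and
#'   is the null model used for calibration.
#' @param division_beta divisions per unit Myc.
#' @param division_mode `"deterministic"` (rounded mean) or `"poisson"`.
#' @param pc_division_scale multiplier on the PC (post-export) division
#'   budget relative to the dark-zone burst of an equally helped cell: the
#'   post-export expansion of plasma-cell precursors in GC-adjacent foci
#'   exceeds the corresponding DZ burst.
#' @param pc_divisions_per_step maximum PC divisions executed per 12 h step
#'   (default 2: plasmablast cycle times are shorter than the DZ's).
#' @param pc_budget_cap upper bound on the division budget granted at
#'   export (finite plasmablast proliferative capacity).
#' @param il21_scale multiplicative IL-21 scale applied to PC division
#'   budgets only (1 = intact IL-21 signaling).
#' @param n_select T-cell-help selection slots per step (expected number of
#'   LZ cells positively selected each step).
#' @param selection_temperature softness of selection; capture weights are
#'   raised to `1/selection_temperature` before normalization.
#' @param gc_death_rate per-step death hazard of unselected LZ cells.
#' @param pc_export_prob per-LZ-cell per-step probability of export to the
#'   prePC compartment (affinity-independent).
#' @param pc_death_rate per-step PC death hazard (affinity-independent).
#' @param pc_egress_rate per-step probability that a PC leaves the node
#'   (default 0; FTY720 forces it to 0).
#' @param secretion_rate antibody concentration units secreted per live PC
#'   per step.
#' @param kd0 dissociation constant of a unit-affinity antibody; a PC of
#'   affinity `a` secretes antibody with `kd = kd0 / a`.
#' @param serum_halflife_steps optional first-order serum decay half-life in
#'   steps (`Inf` = no decay).
#' @param mcherry_f0 initial division-label fluorescence (arbitrary units).
#' @param mcherry_sigma lognormal sigma applied to each founder's initial
#'   label and to measured fluorescence at snapshot time (0 = noise-free).
#' @param dec_wt_fraction fraction of founder clones whose cells are
#'   targetable by antigen delivery to DEC205 (the DEC205-wt analog).
#' @param junction_length_range integer range of heavy CDR3 lengths sampled
#'   per founder.
#' @param step_hours hours per step.
#' @param start_day day after immunization at which founders are seeded.
#' @param horizon_steps number of steps to simulate.
#' @param snapshot_days days at which cell snapshots and repertoire rows are
#'   recorded (the final step is always recorded).
#' @param snapshot_sample maximum cells recorded per cell type per snapshot
#'   (uniform subsample, mimicking single-cell sequencing depth; `Inf`
#'   records every cell).
#' @param interventions list of [intervention()] objects.
#' @param animal label stored with output rows.
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(
    n_founders = 30L,
    founder_cells = 4L,
    v_gene_pool = c("IGHV1-72*01" = 0.25, "IGHV1-53*01" = 0.25,
                    "IGHV1-82*01" = 0.20, "IGHV5-17*01" = 0.15,
                    "IGHV9-3*01" = 0.15),
    target_v = "IGHV1-72*01",
    baseline_affinity = c("IGHV1-72*01" = 2.0, "IGHV1-53*01" = 1.0,
                          "IGHV1-82*01" = 0.8, "IGHV5-17*01" = 1.2,
                          "IGHV9-3*01" = 0.6),
    mutation_rate = 0.15,
    affinity_sites = default_affinity_sites(target_v),
    site_hotspot_prob = 0.2,
    lethal_fraction = 0.3,
    deleterious_fraction = 0.4,
    deleterious_factor = 0.7,
    capture_cmax = 4,
    capture_K = 2,
    antigen_plateau_steps = 20,
    antigen_halflife_steps = 8,
    myc_m0 = 0.2,
    myc_k = 1.0,
    division_beta = 1.2,
    division_mode = "deterministic",
    pc_division_scale = 2.0,
    pc_divisions_per_step = 2L,
    pc_budget_cap = 10L,
    il21_scale = 1.0,
    n_select = 40,
    selection_temperature = 3,
    gc_death_rate = 0.22,
    pc_export_prob = 0.05,
    pc_death_rate = 0.12,
    pc_egress_rate = 0,
    secretion_rate = 1,
    kd0 = 7,
    serum_halflife_steps = Inf,
    mcherry_f0 = 1000,
    mcherry_sigma = 0.15,
    dec_wt_fraction = 0.1,
    junction_length_range = c(10L, 14L),
    step_hours = 12,
    start_day = 4,
    horizon_steps = 56L,
    snapshot_days = NULL,
    snapshot_sample = Inf,
    interventions = list(),
    animal = "A1",
    seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders), founder_cells = as.integer(founder_cells),
    v_gene_pool = v_gene_pool, target_v = target_v,
    baseline_affinity = baseline_affinity,
    mutation_rate = mutation_rate, affinity_sites = affinity_sites,
    site_hotspot_prob = site_hotspot_prob,
    lethal_fraction = lethal_fraction,
    deleterious_fraction = deleterious_fraction,
    deleterious_factor = deleterious_factor,
    capture_cmax = capture_cmax, capture_K = capture_K,
    antigen_plateau_steps = antigen_plateau_steps,
    antigen_halflife_steps = antigen_halflife_steps,
    myc_m0 = myc_m0, myc_k = myc_k,
    division_beta = division_beta, division_mode = division_mode,
    pc_division_scale = pc_division_scale,
    pc_divisions_per_step = as.integer(pc_divisions_per_step),
    pc_budget_cap = as.integer(pc_budget_cap),
    il21_scale = il21_scale,
    n_select = n_select, selection_temperature = selection_temperature,
    gc_death_rate = gc_death_rate,
    pc_export_prob = pc_export_prob, pc_death_rate = pc_death_rate,
    pc_egress_rate = pc_egress_rate,
    secretion_rate = secretion_rate, kd0 = kd0,
    serum_halflife_steps = serum_halflife_steps,
    mcherry_f0 = mcherry_f0, mcherry_sigma = mcherry_sigma,
    dec_wt_fraction = dec_wt_fraction,
    junction_length_range = as.integer(junction_length_range),
    step_hours = step_hours, start_day = start_day,
    horizon_steps = as.integer(horizon_steps),
    snapshot_days = snapshot_days,
    snapshot_sample = snapshot_sample,
    interventions = interventions,
    animal = animal, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop("invalid simulation configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Default affinity-enhancing substitution table
#'
#' Three designated heavy-chain substitutions on the high-affinity V analog,
#' modeled on the canonical W33L / K59R / Y99G replacements: W33L multiplies
#' affinity by 8, K59R and Y99G by 2. Effect sizes are configuration, not
#' constants.
#'
#' @param target_v V identifier the sites are restricted to.
#' @param factors numeric length-3 multiplicative factors for W33L, K59R,
#'   Y99G in that order.
#' @return data.frame with columns `chain`, `v_call`, `position`, `from_res`,
#'   `to_res`, `factor`.
#' @export
default_affinity_sites <- function(target_v = "IGHV1-72*01",
                                   factors = c(8, 2, 2)) {
  data.frame(
    chain = "heavy", v_call = target_v,
    position = c(33L, 59L, 99L),
    from_res = c("W", "K", "Y"),
    to_res = c("L", "R", "G"),
    factor = factors,
    stringsAsFactors = FALSE)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` (or plain list with the same fields).
#' @return character vector of violations (length 0 when valid).
#' @export
validate_config <- function(cfg) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  prob_fields <- c("mutation_rate", "site_hotspot_prob", "lethal_fraction",
                   "deleterious_fraction", "pc_export_prob", "pc_death_rate",
                   "pc_egress_rate", "gc_death_rate")
  for (f in prob_fields) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste0(f, " must be a probability in [0, 1]"))
  }
  chk(cfg$lethal_fraction + cfg$deleterious_fraction <= 1,
      "lethal_fraction + deleterious_fraction must be <= 1")
  chk(cfg$capture_K > 0, "capture_K must be > 0")
  chk(cfg$antigen_halflife_steps > 0, "antigen_halflife_steps must be > 0")
  chk(cfg$antigen_plateau_steps >= 0, "antigen_plateau_steps must be >= 0")
  chk(cfg$capture_cmax > 0, "capture_cmax must be > 0")
  chk(cfg$division_beta >= 0, "division_beta must be >= 0")
  chk(cfg$pc_division_scale >= 0, "pc_division_scale must be >= 0")
  chk(cfg$pc_divisions_per_step >= 1, "pc_divisions_per_step must be >= 1")
  chk(cfg$pc_budget_cap >= 0, "pc_budget_cap must be >= 0")
  chk(cfg$il21_scale >= 0, "il21_scale must be >= 0")
  chk(cfg$horizon_steps >= 0, "horizon_steps must be >= 0")
  chk(cfg$n_founders >= 1, "n_founders must be >= 1")
  chk(cfg$division_mode %in% c("deterministic", "poisson"),
      "division_mode must be 'deterministic' or 'poisson'")
  chk(all(cfg$affinity_sites$factor > 0), "affinity factors must be > 0")
  chk(abs(sum(cfg$v_gene_pool) - 1) < 1e-8, "v_gene_pool must sum to 1")
  chk(all(names(cfg$v_gene_pool) %in% names(germline_set()$heavy)),
      "v_gene_pool names must be in the built-in germline set")
  chk(all(names(cfg$v_gene_pool) %in% names(cfg$baseline_affinity)),
      "baseline_affinity must cover every V in v_gene_pool")
  chk(all(cfg$baseline_affinity > 0), "baseline_affinity must be > 0")
  chk(cfg$mcherry_f0 > 0, "mcherry_f0 must be > 0")
  chk(cfg$mcherry_sigma >= 0, "mcherry_sigma must be >= 0")
  chk(cfg$kd0 > 0, "kd0 must be > 0")
  for (iv in cfg$interventions) {
    if (!inherits(iv, "sim_intervention")) {
      p <- c(p, "interventions must be built with intervention()")
      next
    }
    chk(iv$start_step <= cfg$horizon_steps,
        paste0(iv$kind, " start_step must be within the horizon"))
  }
  p
}

INTERVENTION_KINDS <- c("TAMOXIFEN_S1PR2", "TAMOXIFEN_BLIMP1", "DOXYCYCLINE",
                        "ANTI_CD40L", "TACI_IG", "FTY720", "DEC_OVA")

#' Construct a scheduled intervention
#'
#' @param kind one of `TAMOXIFEN_S1PR2` (fate-label GC/prePC cells),
#'   `TAMOXIFEN_BLIMP1` (fate-label PCs), `DOXYCYCLINE` (start division-label
#'   dilution), `ANTI_CD40L` (terminate T-cell help; the GC collapses within
#'   `delay_steps`), `TACI_IG` (PC depletion, death hazard 1), `FTY720`
#'   (block PC egress from the node), `DEC_OVA` (BCR-independent antigen
#'   delivery to DEC205-targetable GC cells).
#' @param start_step step at which the intervention starts (see
#'   [day_to_step()] to convert from days after immunization).
#' @param dose_fraction antigen dose as a fraction of `capture_cmax`
#'   (required for, and only for, `DEC_OVA`).
#' @param delay_steps latency before full effect (used by `ANTI_CD40L`;
#'   default 4 steps = 2 days at 12 h per step).
#' @return an object of class `sim_intervention`.
#' @export
intervention <- function(kind, start_step, dose_fraction = NULL,
                         delay_steps = 4L) {
  kind <- match.arg(kind, INTERVENTION_KINDS)
  if (kind == "DEC_OVA") {
    if (is.null(dose_fraction) || !is.numeric(dose_fraction) ||
        dose_fraction < 0 || dose_fraction > 1) {
      stop("DEC_OVA requires dose_fraction in [0, 1]", call. = FALSE)
    }
  } else if (!is.null(dose_fraction)) {
    stop("dose_fraction is only meaningful for DEC_OVA", call. = FALSE)
  }
  structure(list(kind = kind, start_step = as.integer(start_step),
                 dose_fraction = dose_fraction,
                 delay_steps = as.integer(delay_steps)),
            class = "sim_intervention")
}

#' Convert days after immunization to simulation steps
#'
#' @param day numeric day(s) after immunization.
#' @param cfg a `sim_config` (uses `start_day` and `step_hours`).
#' @return integer step(s); step 0 is `start_day`.
#' @export
day_to_step <- function(day, cfg) {
  as.integer(round((day - cfg$start_day) * 24 / cfg$step_hours))
}

#' Convert simulation steps to days after immunization
#' @param step integer step(s).
#' @param cfg a `sim_config`.
#' @return numeric day(s).
#' @export
step_to_day <- function(step, cfg) {
  cfg$start_day + step * cfg$step_hours / 24
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_founders, " founder clones, ",
      x$horizon_steps, " steps of ", x$step_hours, "h (day ",
      x$start_day, " to day ", step_to_day(x$horizon_steps, x), "), seed ",
      x$seed, "\n", sep = "")
  cat("  myc: m0=", x$myc_m0, " k=", x$myc_k, "; beta=", x$division_beta,
      "; il21=", x$il21_scale, "; export p=", x$pc_export_prob,
      "; PC death=", x$pc_death_rate, "\n", sep = "")
  if (length(x$interventions)) {
    for (iv in x$interventions) {
      cat("  intervention ", iv$kind, " @ step ", iv$start_step,
          if (!is.null(iv$dose_fraction)) paste0(" dose=", iv$dose_fraction),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Read a simulation configuration from a TOML file
#'
#' Supports the flat subset of TOML the package itself writes: top-level
#' `key = value` pairs (numbers, booleans, strings, inline arrays), an
#' inline-table array `interventions` and a `v_gene_pool` / `baseline_affinity`
#' table of `"name" = number` pairs. Unknown keys are an error.
#'
#' @param path TOML file path.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `sim_config`.
#' @export
read_config_toml <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  top <- list(); tables <- list()
  for (ln in lines) {
    if (grepl("^\\[\\[interventions\\]\\]$", ln)) {
      section <- "interventions"
      tables$interventions <- c(tables$interventions, list(list()))
      next
    }
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      tables[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^(\"[^\"]+\"|[A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse TOML line: ", ln, call. = FALSE)
    key <- gsub("^\"|\"$", "", m[2])
    val <- parse_toml_value(m[3])
    if (section == "") {
      top[[key]] <- val
    } else if (section == "interventions") {
      i <- length(tables$interventions)
      tables$interventions[[i]][[key]] <- val
    } else {
      tables[[section]][[key]] <- val
    }
  }
  args <- top
  for (nm in setdiff(names(tables), "interventions")) {
    args[[nm]] <- unlist(tables[[nm]])
  }
  if (!is.null(tables$interventions)) {
    args$interventions <- lapply(tables$interventions, function(iv) {
      do.call(intervention, iv)
    })
  }
  dots <- list(...)
  args[names(dots)] <- dots
  known <- names(formals(simulation_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(simulation_config, args)
}

parse_toml_value <- function(txt) {
  txt <- trimws(txt)
  if (grepl("^\\[", txt)) {
    inner <- gsub("^\\[|\\]$", "", txt)
    if (!nzchar(trimws(inner))) return(numeric(0))
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl("^\"", txt)) return(gsub("^\"|\"$", "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  if (txt == "inf") return(Inf)
  suppressWarnings(num <- as.numeric(txt))
  if (is.na(num)) stop("cannot parse TOML value: ", txt, call. = FALSE)
  num
}

#' Write a simulation configuration to TOML
#'
#' Writes the flat-TOML subset understood by [read_config_toml()]; the
#' affinity-site table and germline set are package defaults and are not
#' serialized.
#'
#' @param cfg a `sim_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config_toml <- function(cfg, path) {
  fmt <- function(v) {
    if (is.character(v)) paste0("\"", v, "\"")
    else if (is.logical(v)) tolower(as.character(v))
    else if (is.infinite(v)) "inf"
    else format(v, scientific = FALSE)
  }
  scalar_keys <- c("n_founders", "founder_cells", "target_v", "mutation_rate",
                   "site_hotspot_prob",
                   "lethal_fraction", "deleterious_fraction",
                   "deleterious_factor", "capture_cmax", "capture_K",
                   "antigen_plateau_steps", "antigen_halflife_steps",
                   "myc_m0", "myc_k", "division_beta", "division_mode",
                   "pc_division_scale", "pc_divisions_per_step",
                   "pc_budget_cap",
                   "il21_scale", "n_select", "selection_temperature",
                   "gc_death_rate", "pc_export_prob", "pc_death_rate",
                   "pc_egress_rate", "secretion_rate", "kd0",
                   "serum_halflife_steps", "mcherry_f0", "mcherry_sigma",
                   "dec_wt_fraction", "step_hours", "start_day",
                   "horizon_steps", "animal", "seed")
  out <- character(0)
  for (k in scalar_keys) out <- c(out, paste0(k, " = ", fmt(cfg[[k]])))
  out <- c(out, paste0("junction_length_range = [",
                       paste(cfg$junction_length_range, collapse = ", "), "]"))
  if (!is.null(cfg$snapshot_days)) {
    out <- c(out, paste0("snapshot_days = [",
                         paste(cfg$snapshot_days, collapse = ", "), "]"))
  }
  for (tab in c("v_gene_pool", "baseline_affinity")) {
    out <- c(out, "", paste0("[", tab, "]"))
    v <- cfg[[tab]]
    out <- c(out, paste0("\"", names(v), "\" = ", vapply(v, fmt, "")))
  }
  for (iv in cfg$interventions) {
    out <- c(out, "", "[[interventions]]",
             paste0("kind = \"", iv$kind, "\""),
             paste0("start_step = ", iv$start_step),
             paste0("delay_steps = ", iv$delay_steps))
    if (!is.null(iv$dose_fraction)) {
      out <- c(out, paste0("dose_fraction = ", fmt(iv$dose_fraction)))
    }
  }
  writeLines(out, path)
  invisible(path)
}
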