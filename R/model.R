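#' Antigen capture as a saturating function of BCR affinity
#'
#' Light-zone B cells capture antigen displayed on follicular dendritic cells
#' in proportion to receptor affinity, saturating at high affinity:
#' `captured = cmax * affinity / (affinity + K)`. The amount of T-cell help a
#' cell can obtain is proportional to the antigen it captures and presents.
#'
#' @param affinity dimensionless relative affinity, >= 0 (vectorized).
#' @param cmax maximal capture (saturation level), > 0.
#' @param K affinity at half-saturation, > 0.
#' @return captured antigen, same length as `affinity`; strictly increasing
#'   in affinity and bounded above by `cmax`.
#' @export
#' @examples
#' antigen_capture(1, cmax = 1, K = 1)  # 0.5 at half-saturation
antigen_capture <- function(affinity, cmax, K) {
  if (!is.numeric(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.numeric(cmax) || cmax <= 0) stop("cmax must be > 0", call. = FALSE)
  if (any(affinity < 0)) stop("affinity must be >= 0", call. = FALSE)
  cmax * affinity / (affinity + K)
}

#' Myc proxy as an affine function of captured antigen
#'
#' Positively selected cells up-regulate Myc in direct proportion to the
#' amount of antigen they captured and presented: `myc = m0 + k * captured`.
#' Setting `k = 0` decouples division from help (the null model).
#'
#' @param captured captured antigen, >= 0 (vectorized).
#' @param m0 intercept (help-independent baseline).
#' @param k slope (units of Myc per unit captured antigen).
#' @return Myc proxy values.
#' @export
myc_level <- function(captured, m0, k) {
  if (any(captured < 0)) stop("captured must be >= 0", call. = FALSE)
  m0 + k * captured
}

#' Division budget from the Myc proxy
#'
#' The number of "inertial" divisions a selected cell will execute without
#' further T-cell input is proportional to the Myc proxy set at selection:
#' mean `beta * il21_scale * myc`, either rounded (deterministic mode) or
#' drawn from a Poisson with that mean.
#'
#' @param myc Myc proxy, >= 0 (vectorized).
#' @param beta divisions per unit Myc, >= 0.
#' @param il21_scale multiplicative IL-21 scale (1 = intact; applied to PC
#'   budgets in the simulator), >= 0.
#' @param mode `"deterministic"` or `"poisson"`.
#' @return integer division budget(s).
#' @export
#' @examples
#' division_budget(3, beta = 1, il21_scale = 1)  # 3
division_budget <- function(myc, beta, il21_scale = 1,
                            mode = c("deterministic", "poisson")) {
  mode <- match.arg(mode)
  if (any(myc < 0)) stop("myc must be >= 0", call. = FALSE)
  if (beta < 0 || il21_scale < 0) {
    stop("beta and il21_scale must be >= 0", call. = FALSE)
  }
  mu <- beta * il21_scale * myc
  if (mode == "deterministic") as.integer(round(mu)) else
    as.integer(stats::rpois(length(mu), mu))
}

#' Apply one division's somatic mutation to a paired BCR
#'
#' With probability `mutation_rate` per chain, introduces one random amino
#' acid substitution at a uniformly chosen position (the new residue is drawn
#' uniformly from the 19 alternatives to the current one). A substitution
#' matching a designated affinity-site entry (same chain, heavy V call,
#' position and target residue) multiplies affinity by that site's factor;
#' any other substitution is lethal with `lethal_fraction`, multiplies
#' affinity by `deleterious_factor` with `deleterious_fraction`, and is
#' neutral otherwise. On a heavy chain whose V carries designated sites,
#' the substitution is drawn from the site table with probability
#' `site_hotspot_prob` (hypermutation hotspot targeting). The germline
#' alignment is never modified; this is the same mutation core the
#' simulator applies at each dark-zone division. Uses R's global RNG
#' stream.
#'
#' @param bcr a [paired_bcr()] with coordinate-aligned sequences.
#' @param affinity current dimensionless affinity, > 0.
#' @param config a `sim_config` (uses the mutation and fate parameters).
#' @return list with elements `bcr` (possibly mutated), `affinity` (updated),
#'   `fate` (`"OK"` or `"LETHAL"`) and `events` (data.frame of substitutions
#'   applied this call: `chain`, `position`, `from_res`, `to_res`).
#' @export
mutate_chain <- function(bcr, affinity, config) {
  stopifnot(inherits(bcr, "paired_bcr"))
  for (ch in c("heavy", "light")) {
    if (nchar(bcr[[ch]]$sequence_alignment) !=
        nchar(bcr[[ch]]$germline_alignment)) {
      stop("sequence/germline length mismatch on ", ch, " chain of cell ",
           bcr$cell_id, call. = FALSE)
    }
  }
  do_h <- stats::runif(1) < config$mutation_rate
  do_l <- stats::runif(1) < config$mutation_rate
  m <- .mutate_one(bcr$heavy$sequence_alignment,
                   bcr$light$sequence_alignment,
                   bcr$heavy$v_call, affinity, config, do_h, do_l)
  bcr$heavy$sequence_alignment <- m$hseq
  bcr$light$sequence_alignment <- m$lseq
  parse_ev <- function(ev, chain) {
    if (!nzchar(ev)) return(NULL)
    g <- regmatches(ev, regexec("^([0-9]+):(.)>(.)$", ev))[[1]]
    data.frame(chain = chain, position = as.integer(g[2]), from_res = g[3],
               to_res = g[4], stringsAsFactors = FALSE)
  }
  ev <- rbind(parse_ev(m$ev_h, "heavy"), parse_ev(m$ev_l, "light"))
  if (is.null(ev)) {
    ev <- data.frame(chain = character(0), position = integer(0),
                     from_res = character(0), to_res = character(0),
                     stringsAsFactors = FALSE)
  }
  list(bcr = bcr, affinity = m$affinity, fate = m$fate, events = ev)
}

#' Construct a paired BCR
#'
#' One heavy plus one light chain, each aligned to its germline in germline
#' coordinates (equal-length amino-acid strings; 1-based positions).
#'
#' @param cell_id cell identifier.
#' @param heavy,light lists with fields `locus`, `v_call`, `j_call`,
#'   `sequence_alignment`, `germline_alignment`, `junction_aa`.
#' @return an object of class `paired_bcr`.
#' @export
paired_bcr <- function(cell_id, heavy, light) {
  stopifnot(heavy$locus == "IGH", light$locus %in% c("IGK", "IGL"))
  for (ch in list(heavy, light)) {
    if (nchar(ch$sequence_alignment) != nchar(ch$germline_alignment)) {
      stop("sequence/germline length mismatch for cell ", cell_id,
           call. = FALSE)
    }
  }
  structure(list(cell_id = cell_id, heavy = heavy, light = light),
            class = "paired_bcr")
}
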