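#' ELISA signal of a serum mixture against a hapten carrier of valency n
#'
#' A carrier bearing `n` hapten copies binds each antibody species with an
#' avidity-adjusted dissociation constant `kd / n` and offers `n` times the
#' epitopes, giving the occupancy-type signal
#' `sum_i n * c_i / (c_i + kd_i / n)`. With `normalize = TRUE` (the
#' default) concentrations are first divided by their total, so the signal
#' reads the composition of the serum rather than its amount; this makes
#' the valency ratio of [np_ratio()] exactly invariant to uniform scaling
#' of all concentrations (the serum-dilution invariance expected of an
#' avidity index). The signal is additive over species and monotone in each
#' concentration share and each affinity (1/kd).
#'
#' @param serum data.frame with columns `concentration` (>= 0) and `kd`
#'   (> 0), one row per antibody species.
#' @param n hapten valency (positive number; 7 and 28 are the conventional
#'   low/high-valency carriers).
#' @param normalize divide concentrations by their total first (default
#'   TRUE).
#' @return signal in arbitrary units (0 for empty serum).
#' @export
#' @examples
#' elisa_signal(data.frame(concentration = 1, kd = 7), 7)   # 3.5
#' elisa_signal(data.frame(concentration = 1, kd = 7), 28)  # 22.4
elisa_signal <- function(serum, n, normalize = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("valency n must be a positive number", call. = FALSE)
  }
  if (nrow(serum) == 0L) return(0)
  if (any(serum$concentration < 0)) stop("concentrations must be >= 0",
                                         call. = FALSE)
  if (any(serum$kd <= 0)) stop("kd must be > 0", call. = FALSE)
  conc <- serum$concentration
  total <- sum(conc)
  if (normalize && total > 0) conc <- conc / total
  sum(n * conc / (conc + serum$kd / n))
}

#' Low/high-valency binding ratio of a serum sample
#'
#' `np_ratio = signal(valency 7) / signal(valency 28)`, the serum-avidity
#' surrogate. For a single species the ratio increases strictly with
#' affinity between the analytic limits `49/784 = 0.0625` (kd to infinity,
#' linear regime) and `7/28 = 0.25` (kd to 0, full occupancy); any mixture
#' lies strictly between those bounds, and with the default normalized
#' signal the ratio is invariant to uniform scaling of all concentrations.
#'
#' @param serum data.frame with `concentration` and `kd` columns.
#' @param valency_low,valency_high hapten copy numbers (defaults 7 and 28).
#' @param normalize passed to [elisa_signal()].
#' @return the ratio; `NA` with a warning when the high-valency signal is 0.
#' @export
#' @examples
#' np_ratio(data.frame(concentration = 1, kd = 7))  # 0.15625
np_ratio <- function(serum, valency_low = 7, valency_high = 28,
                     normalize = TRUE) {
  stopifnot(valency_low < valency_high)
  hi <- elisa_signal(serum, valency_high, normalize)
  if (hi <= 0) {
    warning("zero high-valency signal; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  elisa_signal(serum, valency_low, normalize) / hi
}

#' Fold change in the serum avidity ratio between two timepoints
#'
#' @param serum_series long data.frame with columns `timepoint`,
#'   `concentration`, `kd` (e.g. the `serum` element of a
#'   [run_simulation()] output).
#' @param t_early,t_late timepoints (matched exactly against the
#'   `timepoint` column).
#' @param ... passed to [np_ratio()].
#' @return `np_ratio(t_late) / np_ratio(t_early)`.
#' @export
affinity_fold_change <- function(serum_series, t_early, t_late, ...) {
  pick <- function(t) {
    s <- serum_series[serum_series$timepoint == t, , drop = FALSE]
    if (nrow(s) == 0L) stop("timepoint ", t, " not present in series",
                            call. = FALSE)
    s
  }
  np_ratio(pick(t_late), ...) / np_ratio(pick(t_early), ...)
}
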