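#' Gate cells by division-label fluorescence
#'
#' Partitions cells into LO / MID / HI by their label (H2B-mCherry analog)
#' fluorescence. The default quantile method takes the outer quartiles of
#' the supplied population: LO below the `lo_q` quantile (most divided,
#' most diluted label), HI above the `hi_q` quantile (least divided). Ties
#' are broken deterministically by rank order of (fluorescence, cell index),
#' so an all-equal input still yields a partition (flagged degenerate).
#'
#' @param mcherry numeric fluorescence values, >= 0.
#' @param method `"quantile"` or `"threshold"`.
#' @param lo_q,hi_q quantile cut points (defaults 0.25 / 0.75); must satisfy
#'   `0 < lo_q < hi_q < 1`.
#' @param lo_thresh,hi_thresh absolute thresholds for the threshold method
#'   (LO strictly below `lo_thresh`, HI at or above `hi_thresh`).
#' @return list with `gate` (factor LO/MID/HI), `degenerate` (logical: the
#'   quantile cuts coincide, e.g. constant fluorescence) and the cut values.
#' @export
gate_by_label <- function(mcherry, method = c("quantile", "threshold"),
                          lo_q = 0.25, hi_q = 0.75,
                          lo_thresh = NULL, hi_thresh = NULL) {
  method <- match.arg(method)
  if (any(mcherry < 0)) stop("mcherry must be >= 0", call. = FALSE)
  n <- length(mcherry)
  if (n < 10L) warning("fewer than 10 cells; gates computed anyway",
                       call. = FALSE)
  if (method == "quantile") {
    if (!(lo_q > 0 && lo_q < hi_q && hi_q < 1)) {
      stop("need 0 < lo_q < hi_q < 1", call. = FALSE)
    }
    r <- rank(mcherry, ties.method = "first")
    lo_cut <- stats::quantile(mcherry, lo_q, names = FALSE)
    hi_cut <- stats::quantile(mcherry, hi_q, names = FALSE)
    gate <- rep("MID", n)
    gate[r <= lo_q * n] <- "LO"
    gate[r > hi_q * n] <- "HI"
    degenerate <- isTRUE(all.equal(lo_cut, hi_cut))
    cuts <- c(lo = lo_cut, hi = hi_cut)
  } else {
    if (is.null(lo_thresh) || is.null(hi_thresh) ||
        lo_thresh <= 0 || hi_thresh <= 0 || lo_thresh > hi_thresh) {
      stop("threshold method needs 0 < lo_thresh <= hi_thresh", call. = FALSE)
    }
    gate <- ifelse(mcherry < lo_thresh, "LO",
                   ifelse(mcherry >= hi_thresh, "HI", "MID"))
    degenerate <- FALSE
    cuts <- c(lo = lo_thresh, hi = hi_thresh)
  }
  list(gate = factor(gate, levels = c("LO", "MID", "HI")),
       degenerate = degenerate, cuts = cuts)
}

#' Compare a per-cell flag between divided and undivided gates
#'
#' For each animal, computes the frequency of `flag` among LO-gated (more
#' divided) and HI-gated (less divided) cells, then runs a paired two-sided
#' t-test across animals on the LO vs HI frequencies. MID cells are
#' excluded. Animals with an empty gate are dropped with a warning.
#'
#' @param animal per-cell animal labels.
#' @param gate per-cell gate factor from [gate_by_label()] (levels
#'   LO/MID/HI); gate per animal before calling if gates should be
#'   animal-wise.
#' @param flag per-cell logical (e.g. affinity flag or target-V expression).
#' @return list with `per_animal` (data.frame `animal`, `freq_lo`,
#'   `freq_hi`), `test` (a [run_test()] result, NA-filled when fewer than
#'   two complete pairs) and `direction` (`"LO>HI"`, `"HI>LO"` or `"none"`).
#' @export
compare_by_division <- function(animal, gate, flag) {
  stopifnot(length(animal) == length(gate), length(gate) == length(flag))
  keep <- gate %in% c("LO", "HI")
  d <- data.frame(animal = animal[keep], gate = as.character(gate[keep]),
                  flag = flag[keep], stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(split(d, d$animal), function(x) {
    data.frame(animal = x$animal[1],
               freq_lo = mean(x$flag[x$gate == "LO"]),
               freq_hi = mean(x$flag[x$gate == "HI"]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  incomplete <- is.na(per$freq_lo) | is.na(per$freq_hi)
  if (any(incomplete)) {
    warning("animal(s) with an empty gate excluded: ",
            paste(per$animal[incomplete], collapse = ", "), call. = FALSE)
  }
  cmp <- per[!incomplete, , drop = FALSE]
  test <- if (nrow(cmp) >= 2L) {
    run_test("t", list(cmp$freq_lo, cmp$freq_hi), paired = TRUE)
  } else {
    data.frame(test = "t", statistic = NA_real_, p_value = NA_real_,
               n = nrow(cmp), direction = "none", stringsAsFactors = FALSE)
  }
  delta <- mean(cmp$freq_lo) - mean(cmp$freq_hi)
  direction <- if (isTRUE(delta > 0)) "LO>HI" else
    if (isTRUE(delta < 0)) "HI>LO" else "none"
  list(per_animal = per, test = test, direction = direction)
}

#' Estimate the division-affinity coupling slope
#'
#' Least-squares slope of division count on log-affinity with a percentile
#' bootstrap confidence interval. When `cluster` is supplied (e.g. clone
#' identifiers) whole clusters are resampled instead of cells — cells of a
#' clone share both affinity and division history, so a cell-level
#' bootstrap would understate the variance on clonally structured data. A
#' constant affinity vector leaves the slope undefined and is flagged.
#'
#' @param divisions per-cell division counts.
#' @param affinity per-cell affinities (> 0); the regressor is
#'   `log(affinity)`.
#' @param cluster optional per-cell cluster labels for a cluster bootstrap.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @return list with `slope`, `ci` (length-2), `n`, and `defined` (FALSE
#'   when affinity is constant).
#' @export
estimate_coupling <- function(divisions, affinity, cluster = NULL,
                              n_boot = 1000L, conf = 0.95) {
  stopifnot(length(divisions) == length(affinity))
  if (any(affinity <= 0)) stop("affinity must be > 0", call. = FALSE)
  x <- log(affinity)
  y <- as.numeric(divisions)
  n <- length(x)
  if (stats::var(x) == 0) {
    return(list(slope = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                defined = FALSE))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  if (is.null(cluster)) {
    # vectorized percentile bootstrap over cells
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    mx <- colMeans(xb); my <- colMeans(yb)
    sxy <- colMeans(xb * yb) - mx * my
    sxx <- colMeans(xb * xb) - mx * mx
    slopes <- sxy / sxx
  } else {
    stopifnot(length(cluster) == n)
    cl <- split(seq_len(n), cluster)
    cs <- vapply(cl, function(ix) {
      c(length(ix), sum(x[ix]), sum(y[ix]), sum(x[ix] * y[ix]),
        sum(x[ix] * x[ix]))
    }, numeric(5))
    k <- ncol(cs)
    pick <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = k)
    tot <- function(r) matrix(cs[r, ][pick], nrow = k)
    nb <- colSums(tot(1)); sx <- colSums(tot(2)); sy <- colSums(tot(3))
    sxy_ <- colSums(tot(4)); sxx_ <- colSums(tot(5))
    slopes <- (sxy_ - sx * sy / nb) / (sxx_ - sx * sx / nb)
  }
  slopes <- slopes[is.finite(slopes)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(slopes, c(alpha, 1 - alpha), names = FALSE)
  list(slope = slope, ci = ci, n = n, defined = TRUE)
}

#' Generate a synthetic division-tracking cohort with known coupling
#'
#' Draws per-cell log-affinities from a normal distribution and division
#' counts from a Poisson whose mean is affine in log-affinity with the
#' requested slope (negative means are truncated at 0). Used for
#' calibration and parameter-recovery studies of [estimate_coupling()].
#'
#' @param n cells.
#' @param slope generative divisions-per-log-affinity slope.
#' @param intercept mean divisions at log-affinity 0 (default 4, high
#'   enough that truncation at 0 is negligible for slopes up to ~3).
#' @param sd_log_affinity spread of log-affinity (default 0.8).
#' @return data.frame with `affinity` and `divisions`.
#' @export
simulate_division_cohort <- function(n, slope, intercept = 4,
                                     sd_log_affinity = 0.8) {
  la <- stats::rnorm(n, 0, sd_log_affinity)
  mu <- pmax(0, intercept + slope * la)
  data.frame(affinity = exp(la),
             divisions = stats::rpois(n, mu))
}
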