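#' Bias-corrected Chao1 species richness
#'
#' `S_chao1 = S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` where `f1` and `f2`
#' are the numbers of singleton and doubleton species. The bias-corrected
#' form is defined even when no doubletons are observed; when `f1 <= 1` the
#' estimate reduces to the observed richness.
#'
#' @param abundances vector of per-species (clone or node) counts, all >= 1.
#' @return the richness estimate (>= observed species count).
#' @export
#' @examples
#' chao1(c(1, 1, 2, 3))  # 4.5
chao1 <- function(abundances) {
  if (length(abundances) == 0L) {
    stop("abundance vector must be non-empty", call. = FALSE)
  }
  if (any(abundances < 1) || any(abundances != round(abundances))) {
    stop("abundances must be positive integers", call. = FALSE)
  }
  s_obs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  if (f1 <= 1) return(as.numeric(s_obs))
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Clone sizes per stratum
#'
#' @param annotated annotated cell table with `clone_id`.
#' @param stratum optional vector (same length as rows) defining strata;
#'   `NULL` pools everything into one stratum.
#' @return data.frame with `stratum`, `clone_id`, `size`, ordered by
#'   stratum, decreasing size, then clone id (deterministic).
#' @export
clone_sizes <- function(annotated, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", nrow(annotated))
  tab <- as.data.frame(table(stratum = stratum, clone_id = annotated$clone_id),
                       responseName = "size", stringsAsFactors = FALSE)
  tab <- tab[tab$size > 0, , drop = FALSE]
  tab <- tab[order(tab$stratum, -tab$size, tab$clone_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Percentage of cells in expanded clones
#'
#' The percentage of cells belonging to clones of size >= 2.
#'
#' @param sizes vector of clone sizes.
#' @return percentage in [0, 100].
#' @export
#' @examples
#' expanded_fraction(c(3, 1, 1))  # 60
expanded_fraction <- function(sizes) {
  if (length(sizes) == 0L) stop("sizes must be non-empty", call. = FALSE)
  100 * sum(sizes[sizes >= 2]) / sum(sizes)
}

#' Per-stratum diversity summary
#'
#' Cell count, clone count, Chao1 richness (on clone abundances) and the
#' expanded-clone percentage, per stratum.
#'
#' @param annotated annotated cell table with `clone_id`.
#' @param stratum vector defining strata (e.g. `interaction(animal, gate)`),
#'   or `NULL` to pool.
#' @return data.frame with `stratum`, `n_cells`, `n_clones`, `chao1`,
#'   `expanded_pct`.
#' @export
diversity_summary <- function(annotated, stratum = NULL) {
  sizes <- clone_sizes(annotated, stratum)
  out <- do.call(rbind, lapply(split(sizes, sizes$stratum), function(d) {
    data.frame(stratum = d$stratum[1], n_cells = sum(d$size),
               n_clones = nrow(d), chao1 = chao1(d$size),
               expanded_pct = expanded_fraction(d$size),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
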