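#' Pair heavy and light chains per cell
#'
#' A cell is kept iff it has exactly one IGH chain and exactly one light
#' chain (IGK or IGL); all other cells are discarded with a reason. Exact
#' duplicate rows (same cell, same chain record) are deduplicated with a
#' warning.
#'
#' @param chains data.frame of chain rows with at least `cell_id`, `locus`,
#'   `v_call`, `j_call`, `sequence_alignment`, `germline_alignment`,
#'   `junction_aa`; extra columns (the simulator's `c_*` annotations) are
#'   carried through from the heavy row.
#' @return list with `paired` (one row per kept cell: heavy columns, then
#'   light columns prefixed `light_`) and `discarded` (data.frame of
#'   `cell_id`, `reason` in NO_HEAVY/NO_LIGHT/MULTI_HEAVY/MULTI_LIGHT).
#' @export
pair_chains <- function(chains) {
  stopifnot(all(c("cell_id", "locus") %in% names(chains)))
  key_cols <- intersect(c("cell_id", "locus", "v_call", "j_call",
                          "sequence_alignment", "junction_aa"),
                        names(chains))
  dup <- duplicated(chains[key_cols])
  if (any(dup)) {
    warning(sum(dup), " duplicate chain row(s) removed", call. = FALSE)
    chains <- chains[!dup, , drop = FALSE]
  }
  is_h <- chains$locus == "IGH"
  is_l <- chains$locus %in% c("IGK", "IGL")
  nh <- table(factor(chains$cell_id[is_h], levels = unique(chains$cell_id)))
  nl <- table(factor(chains$cell_id[is_l], levels = unique(chains$cell_id)))
  ids <- unique(chains$cell_id)
  reason <- rep(NA_character_, length(ids))
  reason[nh[ids] == 0] <- "NO_HEAVY"
  reason[nh[ids] > 1] <- "MULTI_HEAVY"
  reason[is.na(reason) & nl[ids] == 0] <- "NO_LIGHT"
  reason[is.na(reason) & nl[ids] > 1] <- "MULTI_LIGHT"
  keep <- ids[is.na(reason)]
  discarded <- data.frame(cell_id = ids[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  h <- chains[is_h & chains$cell_id %in% keep, , drop = FALSE]
  l <- chains[is_l & chains$cell_id %in% keep, , drop = FALSE]
  h <- h[match(keep, h$cell_id), , drop = FALSE]
  l <- l[match(keep, l$cell_id), , drop = FALSE]
  light_cols <- c("locus", "v_call", "j_call", "sequence_alignment",
                  "germline_alignment", "junction_aa")
  light <- l[light_cols]
  names(light) <- paste0("light_", light_cols)
  paired <- cbind(h, light)
  rownames(paired) <- NULL
  list(paired = paired, discarded = discarded)
}

#' Call somatic mutations against the germline alignment
#'
#' Compares equal-length coordinate-aligned sequences position by position
#' and reports one mutation per mismatching position, in 1-based germline
#' coordinates. Positions where either string carries a gap or ambiguity
#' character (`.`, `-`, `X`) are skipped.
#'
#' @param sequence_alignment observed amino-acid string.
#' @param germline_alignment germline string of equal length.
#' @param chain label stored in the output (`"heavy"` or `"light"`).
#' @param cell_id used in error messages.
#' @return data.frame with columns `chain`, `position`, `from_res`, `to_res`.
#' @export
call_mutations <- function(sequence_alignment, germline_alignment,
                           chain = "heavy", cell_id = NULL) {
  if (nchar(sequence_alignment) != nchar(germline_alignment)) {
    stop("sequence/germline length mismatch",
         if (!is.null(cell_id)) paste0(" for cell ", cell_id), call. = FALSE)
  }
  obs <- strsplit(sequence_alignment, "")[[1]]
  germ <- strsplit(germline_alignment, "")[[1]]
  skip <- obs %in% c(".", "-", "X") | germ %in% c(".", "-", "X")
  pos <- which(obs != germ & !skip)
  data.frame(chain = rep(chain, length(pos)), position = pos,
             from_res = germ[pos], to_res = obs[pos],
             stringsAsFactors = FALSE)
}

# vectorized mismatch count over equal-length string pairs (gap-aware)
.mismatch_count <- function(seqs, germs) {
  mapply(function(s, g) nrow(call_mutations(s, g)), seqs, germs,
         USE.NAMES = FALSE)
}

#' Score affinity-enhancing mutations on a paired record
#'
#' A cell is flagged iff its heavy V call equals `target_v` and its heavy
#' mutations match the designated site set: at least one site under
#' `rule = "any"` (the default; presence-based scoring), every site under
#' `rule = "all"`.
#'
#' @param mutations data.frame from [call_mutations()] for the heavy chain.
#' @param v_call heavy V call of the cell.
#' @param target_v designated high-affinity V identifier.
#' @param site_set data.frame with columns `position`, `from_res`, `to_res`
#'   (default: the W33L/K59R/Y99G analog set of [default_affinity_sites()]).
#' @param rule `"any"` or `"all"`.
#' @return list with `flag` (logical) and `hits` (character vector of
#'   matched sites in `W33L` notation).
#' @export
is_affinity_enhancing <- function(mutations, v_call,
                                  target_v = "IGHV1-72*01",
                                  site_set = default_affinity_sites(target_v),
                                  rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (is.null(site_set) || nrow(site_set) == 0L) {
    stop("site_set must contain at least one site", call. = FALSE)
  }
  site_lab <- paste0(site_set$from_res, site_set$position, site_set$to_res)
  if (!identical(v_call, target_v) || nrow(mutations) == 0L) {
    return(list(flag = FALSE, hits = character(0)))
  }
  mut_lab <- paste0(mutations$from_res, mutations$position, mutations$to_res)
  hits <- site_lab[site_lab %in% mut_lab]
  flag <- if (rule == "any") length(hits) >= 1L else
    length(hits) == length(site_lab)
  list(flag = flag, hits = hits)
}

#' Total heavy + light mutation load of a paired record
#'
#' @param heavy_mutations,light_mutations data.frames from
#'   [call_mutations()].
#' @return integer count of VH + VL substitutions.
#' @export
mutation_load <- function(heavy_mutations, light_mutations) {
  nrow(heavy_mutations) + nrow(light_mutations)
}

#' Group paired records into clones
#'
#' Cells belong to the same clone iff they share heavy `v_call` and
#' `j_call`, have heavy junctions of identical length, and are connected by
#' single linkage at junction amino-acid identity >= `cdr3_identity_min`.
#' Clone identifiers are deterministic: groups are processed in canonical
#' (V, J, junction-length) order and members sorted lexicographically, so
#' the labeling does not depend on input row order.
#'
#' @param paired data.frame from [pair_chains()].
#' @param cdr3_identity_min minimum junction identity fraction (default
#'   0.85).
#' @return `paired` with a `clone_id` column added.
#' @export
assign_clones <- function(paired, cdr3_identity_min = 0.85) {
  key <- paste(paired$v_call, paired$j_call, nchar(paired$junction_aa),
               sep = "|")
  clone_id <- rep(NA_character_, nrow(paired))
  counter <- 0L
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    jx <- paired$junction_aa[idx]
    uj <- sort(unique(jx))
    comp <- .single_linkage(uj, cdr3_identity_min)
    # components ordered by first occurrence over the sorted junction list
    relab <- as.integer(factor(comp, levels = unique(comp)))
    for (cmp in sort(unique(relab))) {
      counter <- counter + 1L
      members <- uj[relab == cmp]
      clone_id[idx[jx %in% members]] <- sprintf("CL%04d", counter)
    }
  }
  paired$clone_id <- clone_id
  paired
}

# single-linkage components over unique junctions at an identity threshold
.single_linkage <- function(junctions, id_min) {
  n <- length(junctions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    chars <- strsplit(junctions, "")
    len <- nchar(junctions[1])
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ident <- sum(chars[[i]] == chars[[j]]) / len
        if (ident >= id_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Annotate a paired repertoire table
#'
#' Runs the full per-cell annotation used across the analysis modules:
#' mutation calling on both chains, mutation load, affinity-enhancing-site
#' scoring and clone assignment.
#'
#' @param paired data.frame from [pair_chains()].
#' @param target_v designated high-affinity V identifier.
#' @param site_set affinity-site table (see [is_affinity_enhancing()]).
#' @param rule `"any"` or `"all"` site-matching rule.
#' @param cdr3_identity_min clone-grouping junction identity threshold.
#' @return `paired` with columns `mutation_count_heavy`,
#'   `mutation_count_light`, `mutation_count`, `affinity_flag`, `hits`
#'   (semicolon-separated site labels) and `clone_id` added.
#' @export
annotate_repertoire <- function(paired, target_v = "IGHV1-72*01",
                                site_set = default_affinity_sites(target_v),
                                rule = "any", cdr3_identity_min = 0.85) {
  n <- nrow(paired)
  mh <- integer(n); ml <- integer(n)
  flag <- logical(n); hits <- character(n)
  for (i in seq_len(n)) {
    hm <- call_mutations(paired$sequence_alignment[i],
                         paired$germline_alignment[i], "heavy",
                         paired$cell_id[i])
    lm <- call_mutations(paired$light_sequence_alignment[i],
                         paired$light_germline_alignment[i], "light",
                         paired$cell_id[i])
    mh[i] <- nrow(hm); ml[i] <- nrow(lm)
    sc <- is_affinity_enhancing(hm, paired$v_call[i], target_v, site_set,
                                rule)
    flag[i] <- sc$flag
    hits[i] <- paste(sc$hits, collapse = ";")
  }
  paired$mutation_count_heavy <- mh
  paired$mutation_count_light <- ml
  paired$mutation_count <- mh + ml
  paired$affinity_flag <- flag
  paired$hits <- hits
  assign_clones(paired, cdr3_identity_min)
}

#' Read / write AIRR-style rearrangement TSV
#'
#' Plain tab-separated files with a header row; logical columns are written
#' as `TRUE`/`FALSE` and restored on read.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_airr_tsv`: data.frame. `write_airr_tsv`: `path`, invisibly.
#' @export
write_airr_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_airr_tsv
#' @export
read_airr_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
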