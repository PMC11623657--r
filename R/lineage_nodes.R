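#' Collapse a clone into genotype nodes
#'
#' A genotype node is the set of cells within a clone sharing an identical
#' heavy + light sequence combination. Node identifiers are deterministic:
#' nodes are numbered in canonical (heavy, light) sequence sort order within
#' each clone.
#'
#' @param annotated annotated paired table (see [annotate_repertoire()]);
#'   may contain several clones. prePC cells are mapped to the GC class for
#'   composition purposes by default (`prepc_as` = `"GC"`); set `prepc_as`
#'   to `"prePC"` to keep them as a third class.
#' @param prepc_as how to classify prePC members: `"GC"` (default) or
#'   `"prePC"`.
#' @return data.frame of nodes: `clone_id`, `node_id`, `heavy_seq`,
#'   `light_seq`, `size`, `n_gc`, `n_pc`, `composition`, `affinity_flag`,
#'   `member_cells` (semicolon-separated cell ids).
#' @export
collapse_genotypes <- function(annotated, prepc_as = c("GC", "prePC")) {
  prepc_as <- match.arg(prepc_as)
  if (nrow(annotated) == 0L) {
    return(data.frame(clone_id = character(0), node_id = character(0),
                      heavy_seq = character(0), light_seq = character(0),
                      size = integer(0), n_gc = integer(0),
                      n_pc = integer(0), composition = character(0),
                      affinity_flag = logical(0),
                      member_cells = character(0), stringsAsFactors = FALSE))
  }
  celltype <- annotated$c_celltype
  if (is.null(celltype)) celltype <- annotated$celltype
  bad <- !celltype %in% c("GC", "PC", "prePC")
  if (any(bad)) {
    stop("unknown cell type(s): ", paste(unique(celltype[bad]), collapse = ", "),
         call. = FALSE)
  }
  type <- ifelse(celltype == "prePC",
                 if (prepc_as == "GC") "GC" else "prePC", celltype)
  key <- paste(annotated$clone_id, annotated$sequence_alignment,
               annotated$light_sequence_alignment, sep = "\r")
  ord <- order(annotated$clone_id, annotated$sequence_alignment,
               annotated$light_sequence_alignment)
  ukey <- unique(key[ord])
  grp <- match(key, ukey)
  n_nodes <- length(ukey)
  size <- tabulate(grp, n_nodes)
  n_gc <- tabulate(grp[type == "GC"], n_nodes)
  n_pc <- tabulate(grp[type == "PC"], n_nodes)
  n_prepc <- tabulate(grp[type == "prePC"], n_nodes)
  first <- match(ukey, key)
  clone <- annotated$clone_id[first]
  # per-clone node numbering in canonical order
  node_num <- stats::ave(seq_len(n_nodes), clone, FUN = seq_along)
  flag <- as.logical(tapply(annotated$affinity_flag, grp, any))
  members <- vapply(split(annotated$cell_id, grp),
                    paste, "", collapse = ";")
  comp <- ifelse(size == n_gc, "GC_ONLY",
                 ifelse(size == n_pc, "PC_ONLY", "MIXED"))
  if (prepc_as == "prePC") {
    comp[size == n_prepc] <- "PREPC_ONLY"
  }
  out <- data.frame(
    clone_id = clone,
    node_id = paste0(clone, "_N", sprintf("%03d", node_num)),
    heavy_seq = annotated$sequence_alignment[first],
    light_seq = annotated$light_sequence_alignment[first],
    size = size, n_gc = n_gc, n_pc = n_pc,
    composition = comp,
    affinity_flag = flag,
    member_cells = members,
    stringsAsFactors = FALSE)
  out <- out[order(out$clone_id, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a node's composition
#'
#' @param n_gc,n_pc member counts by cell class.
#' @return `"GC_ONLY"`, `"PC_ONLY"` or `"MIXED"` (vectorized).
#' @export
classify_node <- function(n_gc, n_pc) {
  size <- n_gc + n_pc
  if (any(size == 0)) stop("empty node", call. = FALSE)
  ifelse(n_pc == 0, "GC_ONLY", ifelse(n_gc == 0, "PC_ONLY", "MIXED"))
}

#' Node and cell-level composition summary
#'
#' Emits the node statistics used to characterize the GC/PC relationship:
#' node counts by composition, node-size distributions separately for GC and
#' PC members, the fraction of nodes carrying affinity-enhancing mutations
#' per composition class, where each cell class resides, and the cell-level
#' affinity-mutation frequency among GC cells vs PCs — per animal and
#' pooled.
#'
#' @param nodes data.frame from [collapse_genotypes()].
#' @param annotated the annotated cell table the nodes were built from
#'   (needs `c_animal`/`animal`, `c_celltype`/`celltype`, `affinity_flag`).
#' @return list with elements `node_counts`, `node_flag_fraction`,
#'   `node_sizes`, `cell_residence` and `cell_flag_freq`.
#' @export
node_summary <- function(nodes, annotated) {
  animal <- annotated$c_animal
  if (is.null(animal)) animal <- annotated$animal
  celltype <- annotated$c_celltype
  if (is.null(celltype)) celltype <- annotated$celltype
  celltype <- ifelse(celltype == "prePC", "GC", celltype)
  comp_levels <- intersect(c("GC_ONLY", "MIXED", "PC_ONLY", "PREPC_ONLY"),
                           unique(nodes$composition))
  comp <- factor(nodes$composition, levels = comp_levels)
  node_counts <- as.data.frame(table(composition = comp),
                               responseName = "n_nodes")
  flag_frac <- tapply(nodes$affinity_flag, comp, mean)
  node_flag_fraction <- data.frame(composition = names(flag_frac),
                                   flag_fraction = as.numeric(flag_frac),
                                   stringsAsFactors = FALSE)
  node_sizes <- data.frame(
    node_id = rep(nodes$node_id, 2L),
    composition = rep(as.character(comp), 2L),
    member_class = rep(c("GC", "PC"), each = nrow(nodes)),
    n_members = c(nodes$n_gc, nodes$n_pc),
    stringsAsFactors = FALSE)
  node_sizes <- node_sizes[node_sizes$n_members > 0, , drop = FALSE]
  rownames(node_sizes) <- NULL
  # where do GC cells / PCs live (mixed vs single-type nodes)?
  residence <- data.frame(
    member_class = c("GC", "PC"),
    frac_in_mixed = c(
      sum(nodes$n_gc[nodes$composition == "MIXED"]) / max(1, sum(nodes$n_gc)),
      sum(nodes$n_pc[nodes$composition == "MIXED"]) / max(1, sum(nodes$n_pc))))
  freq_tab <- function(flags, types, label) {
    data.frame(
      animal = label,
      celltype = c("GC", "PC"),
      n_cells = c(sum(types == "GC"), sum(types == "PC")),
      flag_freq = c(mean(flags[types == "GC"]), mean(flags[types == "PC"])),
      stringsAsFactors = FALSE)
  }
  per_animal <- do.call(rbind, lapply(sort(unique(animal)), function(a) {
    sel <- animal == a
    freq_tab(annotated$affinity_flag[sel], celltype[sel], a)
  }))
  pooled <- freq_tab(annotated$affinity_flag, celltype, "pooled")
  list(node_counts = node_counts,
       node_flag_fraction = node_flag_fraction,
       node_sizes = node_sizes,
       cell_residence = residence,
       cell_flag_freq = rbind(per_animal, pooled))
}

#' Export a clone's genotype nodes as a newick lineage
#'
#' A simple mutation-distance lineage: each node is attached to the
#' candidate ancestor (another node or the germline root) at minimum Hamming
#' distance over the concatenated heavy+light sequences, restricted to
#' candidates with strictly fewer mutations from germline; ties go to the
#' candidate with fewer germline mutations, then lexicographically smaller
#' node id. Node labels carry sizes (`id_size`), branch lengths are Hamming
#' distances.
#'
#' @param nodes data.frame of one clone's nodes (from
#'   [collapse_genotypes()]).
#' @param germline_heavy,germline_light germline sequences for the clone's
#'   V calls.
#' @return a newick string rooted at `germline`.
#' @export
export_lineage <- function(nodes, germline_heavy, germline_light) {
  stopifnot(length(unique(nodes$clone_id)) == 1L)
  full <- paste0(nodes$heavy_seq, nodes$light_seq)
  root <- paste0(germline_heavy, germline_light)
  hd <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  n <- nrow(nodes)
  dist_root <- vapply(full, hd, 0, b = root, USE.NAMES = FALSE)
  parent <- integer(n)  # 0 = germline root
  ord <- order(dist_root, nodes$node_id)
  for (i in ord) {
    cand <- which(dist_root < dist_root[i])
    best <- 0L; best_d <- dist_root[i]
    if (length(cand)) {
      dd <- vapply(cand, function(j) hd(full[i], full[j]), 0)
      o <- order(dd, dist_root[cand], nodes$node_id[cand])
      if (dd[o[1]] < best_d ||
          (dd[o[1]] == best_d && dist_root[cand[o[1]]] < dist_root[i])) {
        best <- cand[o[1]]; best_d <- dd[o[1]]
      }
    }
    parent[i] <- best
  }
  label <- paste0(gsub("[ ();,:]", "_", nodes$node_id), "_", nodes$size)
  children <- split(seq_len(n), parent[seq_len(n)])
  as_nwk <- function(i) {
    kids <- children[[as.character(i)]]
    kid_str <- if (!is.null(kids)) {
      paste0("(", paste(vapply(kids, as_nwk, ""), collapse = ","), ")")
    } else ""
    d <- if (i == 0L) 0 else if (parent[i] == 0L) dist_root[i] else
      hd(full[i], full[parent[i]])
    if (i == 0L) paste0(kid_str, "germline") else
      paste0(kid_str, label[i], ":", d)
  }
  paste0(as_nwk(0L), ";")
}
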