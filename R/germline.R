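#' Built-in germline V-segment set
#'
#' The simulator works on fixed-length amino-acid sequences pre-aligned to
#' germline coordinates, so the germline set is a named vector of equal-length
#' strings per locus. The heavy pool contains one designated high-affinity
#' analog, `IGHV1-72*01`, which carries the canonical residues whose
#' replacement enhances hapten binding (W at position 33, K at 59, Y at 99 —
#' the W33L/K59R/Y99G sites). The sequences themselves are synthetic: they are
#' fixed random amino-acid strings, not IMGT alleles, and only the designated
#' positions carry meaning.
#'
#' @return A list with elements `heavy` and `light`, each a named character
#'   vector of germline V-region amino-acid sequences.
#' @export
#' @examples
#' g <- germline_set()
#' substr(g$heavy[["IGHV1-72*01"]], 33, 33)  # "W"
germline_set <- function() {
  heavy <- c(
    "IGHV1-72*01" = "TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEWPFECVDTVGGCYDCGLIFATHEPLKKYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLYA",
    "IGHV1-53*01" = "WTQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQSTMVC",
    "IGHV1-82*01" = "LEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQYWNWG",
    "IGHV5-17*01" = "NLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTGWLPGAMPLPRTRIEGLYSNSWDHDLLHWPLQMPDLWCHYMMAGLK",
    "IGHV9-3*01"  = "NPVRAMIPQCGPDPSWSPPIPGGIFKLMAREHMLIDPYSIDKSMPHVHFYVHTDSIWVLRNDYSLCIAPHMMPFCRFQFTVTVHPCNDYIYQAQVCFLND"
  )
  light <- c(
    "IGKV4-1*01"   = "VVVRAIWIYWCYWMRVILCETNYWHKWMMNTCYHTEPWATECIDPCEKMLQAAQYMKWFCKDNCSVTYIIWRGDAREKAMGYQKGNTMKVMWAMT",
    "IGKV1-117*01" = "TIMVAGCQFAVERHQLDHFGFVKDDKPHLTCYTNGWLSALHCEYIRQTFTTSYGDQKNKQDEDHAFEINNNRKDDKHNPTRRYDPWCFKVAEVFD",
    "IGKV10-96*01" = "LHQLLKHGYIFWYMTHLNEYDASFWTMAAVDFHGSPAWVLQLCSKTCRIDCTDMFADQGSLIKDCGCSKFTNYEGCDVTVMIHYAWSIYVLLWPN"
  )
  list(heavy = heavy, light = light)
}

# one-letter amino-acid alphabet used throughout
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Write a germline set to FASTA
#'
#' @param germlines named character vector (or the list from [germline_set()],
#'   in which case heavy and light pools are concatenated).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(germlines, path) {
  if (is.list(germlines)) germlines <- c(germlines$heavy, germlines$light)
  stopifnot(is.character(germlines), !is.null(names(germlines)))
  writeLines(paste0(">", names(germlines), "\n", unname(germlines)), path)
  invisible(path)
}

#' Read a germline FASTA keyed by V call
#'
#' @param path FASTA file of amino-acid V segments, record ids used as
#'   `v_call` keys.
#' @return named character vector of sequences.
#' @export
read_germlines <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
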