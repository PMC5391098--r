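# Degenerate (IUPAC) motif scanning.
#
# The B box motif GTTCRANNC and the A box motifs TNNNNNANNNG (permissive) /
# TRRYNNARYNG (stringent) are written in IUPAC nucleotide code; scanning is
# the first step of building an A/B-box target catalog.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", W = "AT", S = "CG", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

check_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  toupper(pattern)
}

#' Translate an IUPAC motif to a regular expression
#'
#' Each degenerate code becomes a character class (`R` -> `[AG]`, `N` ->
#' `[ACGT]`). The resulting pattern never matches `N` in the subject: an
#' ambiguous reference base is treated conservatively as matching nothing.
#'
#' @param pattern IUPAC motif string.
#' @return A single regular-expression string.
#' @export
iupac_to_regex <- function(pattern) {
  chars <- strsplit(check_iupac(pattern), "")[[1]]
  paste(vapply(IUPAC_CODES[chars], function(s) {
    if (nchar(s) == 1L) s else paste0("[", s, "]")
  }, character(1)), collapse = "")
}

#' Scan references for a degenerate motif
#'
#' Finds every (possibly overlapping) match of an IUPAC motif in a set of
#' reference sequences. Reverse-strand matches are reported on plus-strand
#' coordinates (1-based, both ends inclusive) with `strand == "-"`. `N` bases
#' in the reference never satisfy a non-N motif position.
#'
#' @param refs Tibble with columns `ref_id`, `kind`, `seq` (see [make_genome()]).
#' @param pattern IUPAC motif, e.g. `"GTTCRANNC"`.
#' @param both_strands Scan the reverse strand as well? Default `TRUE`.
#' @return Tibble with columns `ref_id`, `start`, `end`, `strand`, sorted by
#'   reference then position.
#' @export
#' @examples
#' refs <- tibble::tibble(ref_id = "r", kind = "chromosome", seq = "AAGTTCAAACCTT")
#' scan_motif(refs, "GTTCRANNC", both_strands = FALSE)
scan_motif <- function(refs, pattern, both_strands = TRUE) {
  check_refs(refs)
  pattern <- check_iupac(pattern)
  w <- nchar(pattern)
  one_strand <- function(seq, pat) {
    if (nchar(seq) < w) return(integer(0))
    # fixed = "subject": degenerate codes are expanded in the pattern only, so
    # an N in the reference fails every non-N motif position (conservative)
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq), fixed = "subject")
    BiocGenerics::start(m)
  }
  hits <- purrr::pmap(refs, function(ref_id, kind, seq, ...) {
    fwd <- one_strand(seq, pattern)
    out <- tibble::tibble(ref_id = ref_id, start = fwd, strand = "+")
    if (both_strands) {
      # match the reverse-complemented motif on the plus strand: a match of
      # rc(pattern) at [s, s+w-1] is a minus-strand motif occurrence there
      rev <- one_strand(seq, revcomp(pattern))
      out <- dplyr::bind_rows(out, tibble::tibble(ref_id = ref_id, start = rev, strand = "-"))
    }
    out
  })
  dplyr::bind_rows(hits) |>
    dplyr::mutate(end = .data$start + w - 1L, .after = "start") |>
    dplyr::arrange(.data$ref_id, .data$start, .data$strand)
}
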