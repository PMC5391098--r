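# The tagged retrotransposon construct used for profiling.
#
# The element model is a synthetic stand-in for a marker-tagged, tRNA
# gene-targeting non-LTR retrotransposon: a retained 5'-UTR (the promoter
# fragment carried along on retrotransposition), an ORF1-like body carrying
# the LAM primer site and a nested primer site, and the plasmid context
# (Pol II promoter analog) present upstream of the transformed copy only.

#' Synthetic retrotransposon element model
#'
#' Builds a deterministic element construct. Position 1 is the first base of
#' the retained 5'-UTR; truncations are measured from there. The LAM (ORF1)
#' primer site marks the fixed element end of every amplicon; the nested
#' primer site is the sequence required in adapter-library pseudoreads.
#'
#' @param element_len Total element length in bp (default 400; a compact
#'   analog of the tagged construct, long enough to carry both primer sites).
#' @param retained_utr_len 5'-UTR bp carried along on retrotransposition
#'   (default 42).
#' @param nested_primer_site,orf1_primer_site Integer intervals (element
#'   coordinates) of the nested and LAM primer sites.
#' @param plasmid_context_len Length of the plasmid (promoter) context
#'   upstream of the transformed element copy (default 300).
#' @param construct_seed Integer seed fixing the construct sequence; the
#'   default yields one canonical reference construct.
#' @return A list of class `element_model` with fields `full_sequence`,
#'   `retained_utr_len`, `orf1_primer_site`, `nested_primer_site`,
#'   `plasmid_context`.
#' @export
element_model <- function(element_len = 400L, retained_utr_len = 42L,
                          nested_primer_site = c(55L, 74L),
                          orf1_primer_site = c(231L, 250L),
                          plasmid_context_len = 300L,
                          construct_seed = 4713L) {
  stopifnot(retained_utr_len < element_len,
            nested_primer_site[1] >= 1, nested_primer_site[2] <= element_len,
            orf1_primer_site[1] >= 1, orf1_primer_site[2] <= element_len,
            nested_primer_site[2] < orf1_primer_site[1])
  with_seed(construct_seed, {
    full <- random_dna(element_len, gc = 0.35)
    ctx <- random_dna(plasmid_context_len, gc = 0.30)
  })
  structure(list(
    full_sequence = full,
    retained_utr_len = as.integer(retained_utr_len),
    orf1_primer_site = as.integer(orf1_primer_site),
    nested_primer_site = as.integer(nested_primer_site),
    plasmid_context = ctx
  ), class = "element_model")
}

# Element-coordinate end of every amplicon (the LAM primer 3' end).
element_amplicon_end <- function(element) element$orf1_primer_site[2]

# Sequence required in adapter-library pseudoreads.
nested_primer_seq <- function(element) {
  substr(element$full_sequence, element$nested_primer_site[1], element$nested_primer_site[2])
}

#' @export
print.element_model <- function(x, ...) {
  cat("<element_model>\n")
  cat("  length:", nchar(x$full_sequence), "bp; retained 5'-UTR:", x$retained_utr_len, "bp\n")
  cat("  nested primer:", x$nested_primer_site[1], "-", x$nested_primer_site[2],
      "; LAM primer:", x$orf1_primer_site[1], "-", x$orf1_primer_site[2], "\n")
  cat("  plasmid context:", nchar(x$plasmid_context), "bp\n")
  invisible(x)
}
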