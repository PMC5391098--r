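# Internal helpers shared across modules.

#' Reverse-complement a DNA string
#'
#' Vectorised reverse complement over character vectors. IUPAC ambiguity
#' codes are complemented correctly (R<->Y, K<->M, B<->V, D<->H, N<->N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GTTCRANNC"))
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x) & !is.na(x)
  out[!nz] <- x[!nz]
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

# Evaluate expr with a private RNG state seeded at `seed`; the caller's RNG
# stream is untouched. All stochastic operations in the package go through
# this so a single user-supplied seed makes runs reproducible.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation; keeps results independent across stages
# while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483562) + 1L
}

# Random DNA of length n at the given GC fraction (i.i.d. bases).
random_dna <- function(n, gc = 0.25) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Assemble a refs tibble row set; `kind` one of chromosome/palindrome_arm/plasmid.
new_refs <- function(ref_id, kind, seq) {
  tibble::tibble(ref_id = ref_id, kind = kind, seq = toupper(seq))
}

check_refs <- function(refs) {
  stopifnot(is.data.frame(refs), all(c("ref_id", "kind", "seq") %in% names(refs)))
  bad <- stringr::str_detect(refs$seq, "[^ACGTN]")
  if (any(bad)) {
    stop("reference sequences may contain only A/C/G/T/N: ", paste(refs$ref_id[bad], collapse = ", "))
  }
  invisible(refs)
}

ref_seq <- function(refs, id) {
  i <- match(id, refs$ref_id)
  if (is.na(i)) stop("unknown reference id: ", id)
  refs$seq[i]
}
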