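# Pseudoread assembly and junction-fragment extraction.
#
# Read pairs are merged across their overlap into single "pseudoreads"; the
# element-derived part and the primer/adapter part are located and trimmed
# away, leaving the genomic junction fragment that is mapped downstream.
# Fragments are kept in a canonical orientation: the base adjacent to the
# element 5' terminus (the junction) comes first, i.e. the fragment reads in
# the targeted gene's 5'->3' sense.

#' Read-preparation parameters
#'
#' @param min_pseudoread_len Discard merged pseudoreads shorter than this
#'   (default 100 nt).
#' @param min_overlap Minimum pair overlap for merging (default 10 nt).
#' @param max_overlap_mismatch_rate Maximum mismatch fraction inside the
#'   overlap (default 0.1).
#' @param primer_max_mismatches Substitutions tolerated when matching primer
#'   or adapter sequences (default 1; set 0 for exact matching).
#' @param min_trimmed_len Discard fragments whose genomic part is shorter
#'   than this after trimming (default 40 nt, guarding against imprecise
#'   mapping of very short A+T-rich fragments).
#' @param element_min_match_len Minimum element match length to call a read
#'   element-derived (default 20 nt).
#' @param element_max_divergence Maximum divergence of the element match
#'   (default 0.1).
#' @return A list of class `prep_params`.
#' @export
prep_params <- function(min_pseudoread_len = 100L, min_overlap = 10L,
                        max_overlap_mismatch_rate = 0.1,
                        primer_max_mismatches = 1L,
                        min_trimmed_len = 40L,
                        element_min_match_len = 20L,
                        element_max_divergence = 0.1) {
  stopifnot(min_pseudoread_len >= 0, min_overlap >= 1,
            max_overlap_mismatch_rate >= 0, max_overlap_mismatch_rate <= 1,
            primer_max_mismatches >= 0, min_trimmed_len >= 0,
            element_max_divergence >= 0, element_max_divergence <= 1)
  structure(list(
    min_pseudoread_len = as.integer(min_pseudoread_len),
    min_overlap = as.integer(min_overlap),
    max_overlap_mismatch_rate = max_overlap_mismatch_rate,
    primer_max_mismatches = as.integer(primer_max_mismatches),
    min_trimmed_len = as.integer(min_trimmed_len),
    element_min_match_len = as.integer(element_min_match_len),
    element_max_divergence = element_max_divergence
  ), class = "prep_params")
}

# Merge one pair; returns list(seq, qual, status). Qualities are handled as
# integer code points so comparisons are locale-independent.
merge_one_pair <- function(s1, q1, s2, q2, params) {
  s2r <- revcomp(s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2r, "")[[1]]
  p1 <- utf8ToInt(q1); p2 <- rev(utf8ToInt(q2))
  n1 <- length(c1); n2 <- length(c2)
  if (min(n1, n2) >= params$min_overlap) {
    for (o in seq.int(min(n1, n2), params$min_overlap)) {
      left <- c1[(n1 - o + 1L):n1]; right <- c2[1:o]
      mm <- left != right
      if (sum(mm) / o <= params$max_overlap_mismatch_rate) {
        ql <- p1[(n1 - o + 1L):n1]; qr <- p2[1:o]
        cons <- left; qcons <- pmax(ql, qr)
        if (any(mm)) {
          take2 <- mm & (qr > ql)
          cons[take2] <- right[take2]
          cons[mm & (qr == ql)] <- "N"   # unresolvable conflict at equal quality
          qcons[mm] <- pmin(ql, qr)[mm]
        }
        seq <- paste(c(c1[seq_len(n1 - o)], cons, c2[seq.int(o + 1L, length.out = n2 - o)]), collapse = "")
        qual <- intToUtf8(c(p1[seq_len(n1 - o)], qcons, p2[seq.int(o + 1L, length.out = n2 - o)]))
        status <- if (nchar(seq) < params$min_pseudoread_len) "short_pseudoread" else "merged"
        return(list(seq = seq, qual = qual, status = status))
      }
    }
  }
  list(seq = NA_character_, qual = NA_character_, status = "no_overlap")
}

#' Merge read pairs into pseudoreads
#'
#' Finds the best overlap (longest acceptable, scanning down to
#' `min_overlap`) between read 1 and the reverse complement of read 2; the
#' consensus takes the higher-quality base at conflicts and `N` at
#' equal-quality conflicts. Pairs without an acceptable overlap, or whose
#' merged length is below `min_pseudoread_len`, are rejected with a reason.
#'
#' @param pairs Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (see [read_fastq_pairs()]), or a `tre_reads` object.
#' @param params A [prep_params()] object.
#' @return Tibble `read_id`, `seq`, `qual`, `status` with status one of
#'   `merged`, `short_pseudoread`, `no_overlap`.
#' @export
merge_pairs <- function(pairs, params = prep_params()) {
  if (inherits(pairs, "tre_reads")) pairs <- pairs$pairs
  out <- purrr::pmap(pairs[, c("seq1", "qual1", "seq2", "qual2")],
                     function(seq1, qual1, seq2, qual2) {
                       merge_one_pair(seq1, qual1, seq2, qual2, params)
                     })
  tibble::tibble(
    read_id = pairs$read_id,
    seq = purrr::map_chr(out, "seq"),
    qual = purrr::map_chr(out, "qual"),
    status = purrr::map_chr(out, "status")
  )
}

# Does `primer` (or its revcomp) occur in seq with <= k substitutions?
contains_primer <- function(seqs, primer, k) {
  x <- Biostrings::DNAStringSet(ifelse(is.na(seqs), "", seqs))
  fwd <- Biostrings::vcountPattern(primer, x, max.mismatch = k) > 0
  rev <- Biostrings::vcountPattern(revcomp(primer), x, max.mismatch = k) > 0
  fwd | rev
}

#' Require a nested-primer sequence in pseudoreads
#'
#' Adapter-library pseudoreads that lack the nested element primer (in either
#' orientation, up to `primer_max_mismatches` substitutions) are artifacts
#' and are dropped before mapping.
#'
#' @param pseudo Pseudoread tibble from [merge_pairs()].
#' @param primer Nested primer sequence.
#' @param params A [prep_params()] object.
#' @return The tibble with failing rows marked `status = "no_primer"`.
#' @export
require_primer <- function(pseudo, primer, params = prep_params()) {
  live <- pseudo$status == "merged"
  keep <- contains_primer(pseudo$seq[live], primer, params$primer_max_mismatches)
  pseudo$status[live][!keep] <- "no_primer"
  pseudo
}

#' Locate and trim the element part of pseudoreads
#'
#' Aligns each pseudoread (both orientations) against the element and keeps
#' the orientation in which the element 5' terminus faces the downstream
#' genomic part. Records the 5' truncation (how far the element match falls
#' short of element position 1, the first base of the retained 5'-UTR) and
#' the tail (extras + genomic + primer part). Reads whose best element match
#' is shorter than `element_min_match_len` or more divergent than
#' `element_max_divergence` are rejected (`no_element`); reads with an
#' equal-quality merge conflict (`N`) within 2 bases of the element end or
#' the first 6 tail bases are rejected as `ambiguous_junction`, because the
#' junction fields could not be read reliably.
#'
#' @param pseudo Pseudoread tibble (rows with `status == "merged"` are
#'   processed).
#' @param element An [element_model()].
#' @param params A [prep_params()] object.
#' @return Tibble `read_id`, `seq` (canonical orientation), `element_len`,
#'   `truncation`, `tail`, `status`.
#' @export
locate_and_trim_element <- function(pseudo, element, params = prep_params()) {
  if (is.null(element$orf1_primer_site)) stop("element model is missing primer coordinates")
  elem <- element$full_sequence
  L <- nchar(elem)
  pe <- element_amplicon_end(element)
  rc_elem <- Biostrings::DNAString(revcomp(elem))
  rc_ep_raw <- charToRaw(revcomp(substr(elem, 1L, pe)))  # read-start region of the amplicon
  live <- which(pseudo$status == "merged")
  out <- tibble::tibble(
    read_id = pseudo$read_id, seq = pseudo$seq,
    element_len = NA_integer_, truncation = NA_integer_,
    tail = NA_character_, status = pseudo$status
  )
  if (!length(live)) return(out)

  finish <- function(idx, read, r2, trunc) {
    tail <- substr(read, r2 + 1L, nchar(read))
    zone <- paste0(substr(read, max(1L, r2 - 1L), r2), substr(tail, 1L, 6L))
    if (grepl("N", zone, fixed = TRUE)) {
      out$status[idx] <<- "ambiguous_junction"
    } else {
      out$seq[idx] <<- read
      out$element_len[idx] <<- r2
      out$truncation[idx] <<- trunc
      out$tail[idx] <<- tail
    }
  }

  # Fast path: the amplicon begins at the LAM primer end, so an intact read
  # equals revcomp(element[1..pe]) up to the junction. The longest common
  # prefix then locates the element end exactly; a short look-ahead guards
  # against a substitution bridge that full alignment would cross.
  lcp_with_ep <- function(read) {
    a <- charToRaw(read)
    n <- min(length(a), length(rc_ep_raw))
    mm <- which(a[seq_len(n)] != rc_ep_raw[seq_len(n)])
    if (length(mm)) mm[1] - 1L else n
  }
  slow <- integer(0)
  for (i in live) {
    read <- pseudo$seq[i]
    l1 <- lcp_with_ep(read)
    if (l1 < params$element_min_match_len) {
      rc_read <- revcomp(read)
      l2 <- lcp_with_ep(rc_read)
      if (l2 >= params$element_min_match_len) { read <- rc_read; l1 <- l2 }
    }
    if (l1 >= params$element_min_match_len) {
      if (l1 == pe) { finish(i, read, l1, 0L); next }
      ridx <- l1 + 2L:9L
      ridx <- ridx[ridx <= min(nchar(read), pe)]
      rc_ep <- rawToChar(rc_ep_raw)
      bridged <- length(ridx) > 0L &&
        sum(substring(read, ridx, ridx) == substring(rc_ep, ridx, ridx)) > 2L
      if (!bridged) { finish(i, read, l1, pe - l1); next }
    }
    slow <- c(slow, i)
  }

  if (length(slow)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
    seqs <- pseudo$seq[slow]
    pats_f <- Biostrings::DNAStringSet(seqs)
    pats_r <- Biostrings::reverseComplement(pats_f)
    pa_f <- Biostrings::pairwiseAlignment(pats_f, rc_elem, type = "local",
                                          substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    pa_r <- Biostrings::pairwiseAlignment(pats_r, rc_elem, type = "local",
                                          substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    use_r <- BiocGenerics::score(pa_r) > BiocGenerics::score(pa_f)
    for (j in seq_along(slow)) {
      pa <- if (use_r[j]) pa_r[j] else pa_f[j]
      read <- if (use_r[j]) as.character(pats_r[[j]]) else seqs[j]
      prange <- IRanges::ranges(Biostrings::pattern(pa))
      srange <- IRanges::ranges(Biostrings::subject(pa))
      mlen <- BiocGenerics::width(prange)
      nmatch <- Biostrings::nmatch(pa)
      if (mlen < params$element_min_match_len ||
          (1 - nmatch / mlen) > params$element_max_divergence) {
        out$status[slow[j]] <- "no_element"
        next
      }
      finish(slow[j], read, BiocGenerics::end(prange), L - BiocGenerics::end(srange))
    }
  }
  out
}

# Hamming distance of equal-length strings.
hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

#' Trim the target-end primer or adapter from fragments
#'
#' Removes the tDNA-primer-matching suffix (tDNA library) or the
#' reverse-complemented adapter plus its 6-nt random hexamer (adapter
#' library) from the fragment tail. Fragments without a recognizable suffix
#' are left unchanged and flagged.
#'
#' @param frags Fragment tibble from [locate_and_trim_element()].
#' @param library_type `"tdna"` or `"adapter"`.
#' @param primers For the tDNA library, a tibble with columns `target_id`,
#'   `primer` (gene-sense primer sequences), or a character vector.
#' @param adapter Adapter sequence (adapter library).
#' @param params A [prep_params()] object.
#' @return The tibble with `genomic_part`, `trimmed_primer` (primer/adapter
#'   id or `NA`), and `primer_found` columns added.
#' @export
trim_target_end <- function(frags, library_type = c("tdna", "adapter"),
                            primers = NULL, adapter = ADAPTER_SEQ,
                            params = prep_params()) {
  library_type <- match.arg(library_type)
  k <- params$primer_max_mismatches
  frags$genomic_part <- frags$tail
  frags$trimmed_primer <- NA_character_
  frags$primer_found <- FALSE
  live <- which(frags$status == "merged" & !is.na(frags$tail) & nzchar(frags$tail))
  if (library_type == "tdna") {
    stopifnot(!is.null(primers))
    if (is.character(primers)) {
      primers <- tibble::tibble(target_id = paste0("primer", seq_along(primers)), primer = primers)
    }
    for (i in live) {
      tail <- frags$tail[i]; n <- nchar(tail)
      for (j in seq_len(nrow(primers))) {
        p <- primers$primer[j]; w <- nchar(p)
        if (n >= w && hamming(substr(tail, n - w + 1L, n), p) <= k) {
          frags$genomic_part[i] <- substr(tail, 1L, n - w)
          frags$trimmed_primer[i] <- primers$target_id[j]
          frags$primer_found[i] <- TRUE
          break
        }
      }
    }
  } else {
    suf <- revcomp(adapter); w <- nchar(suf)
    for (i in live) {
      tail <- frags$tail[i]; n <- nchar(tail)
      if (n >= w + 6L && hamming(substr(tail, n - w + 1L, n), suf) <= k) {
        frags$genomic_part[i] <- substr(tail, 1L, n - w - 6L)  # drop hexamer too
        frags$trimmed_primer[i] <- "adapter"
        frags$primer_found[i] <- TRUE
      }
    }
  }
  frags
}

#' Length-filter trimmed fragments
#'
#' @param frags Fragment tibble with `genomic_part`.
#' @param params A [prep_params()] object; fragments shorter than
#'   `min_trimmed_len` get `status = "short_fragment"`.
#' @return The filtered tibble (statuses updated).
#' @export
length_filter <- function(frags, params = prep_params()) {
  live <- frags$status == "merged"
  glen <- ifelse(is.na(frags$genomic_part), 0L, nchar(frags$genomic_part))
  frags$status[live & glen < params$min_trimmed_len] <- "short_fragment"
  frags
}

#' Run the full read-preparation stage
#'
#' Chains [merge_pairs()], [require_primer()] (adapter library only),
#' [locate_and_trim_element()], [trim_target_end()] and [length_filter()].
#'
#' @param pairs Pairs tibble or `tre_reads` object.
#' @param element An [element_model()].
#' @param library_type `"tdna"` or `"adapter"`.
#' @param primers tDNA trimming primers (tibble `target_id`, `primer`).
#' @param adapter Adapter sequence.
#' @param params A [prep_params()] object.
#' @return A list of class `tre_prep`: `fragments` (retained junction
#'   fragments), `all` (every pseudoread with its terminal status), `counts`
#'   (per-stage accounting tibble).
#' @export
prep_reads <- function(pairs, element, library_type = c("tdna", "adapter"),
                       primers = NULL, adapter = ADAPTER_SEQ,
                       params = prep_params()) {
  library_type <- match.arg(library_type)
  if (inherits(pairs, "tre_reads")) pairs <- pairs$pairs
  n_pairs <- nrow(pairs)
  ps <- merge_pairs(pairs, params)
  if (library_type == "adapter") {
    ps <- require_primer(ps, nested_primer_seq(element), params)
  }
  frags <- locate_and_trim_element(ps, element, params)
  frags <- trim_target_end(frags, library_type, primers = primers,
                           adapter = adapter, params = params)
  frags <- length_filter(frags, params)
  kept <- frags[frags$status == "merged", , drop = FALSE]
  counts <- tibble::tibble(
    stage = c("read_pairs", "assembled_pseudoreads", "no_overlap",
              "short_pseudoread", "no_primer", "no_element",
              "ambiguous_junction", "short_fragment", "fragments_out"),
    count = c(n_pairs, sum(!frags$status %in% c("no_overlap", "short_pseudoread")),
              sum(frags$status == "no_overlap"),
              sum(frags$status == "short_pseudoread"),
              sum(frags$status == "no_primer"),
              sum(frags$status == "no_element"),
              sum(frags$status == "ambiguous_junction"),
              sum(frags$status == "short_fragment"),
              nrow(kept))
  )
  structure(list(fragments = kept, all = frags, counts = counts,
                 library_type = library_type), class = "tre_prep")
}
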