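# Independent oracles and small fixture builders used across the suite.

# Brute-force IUPAC motif scan via regular expressions with a lookahead so
# overlapping matches are reported; minus strand scanned on the
# reverse-complemented sequence with coordinates mapped back. Independent of
# scan_motif()'s Biostrings path.
regex_scan_oracle <- function(seq, pattern, both_strands = TRUE) {
  w <- nchar(pattern)
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  starts_on <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  plus <- starts_on(seq)
  out <- tibble::tibble(start = plus, strand = rep("+", length(plus)))
  if (both_strands) {
    L <- nchar(seq)
    rcpos <- starts_on(revcomp(seq))
    minus <- L - (rcpos + w - 1L) + 1L
    out <- dplyr::bind_rows(out, tibble::tibble(start = minus, strand = rep("-", length(minus))))
  }
  dplyr::arrange(out, start, strand)
}

# Full dynamic-programming local alignment (Gotoh affine gaps) returning the
# best score. A gap of length g costs open + g * ext. Vectorised over the
# subject dimension per pattern row; independent of the seeded aligner.
dp_local_best_score <- function(pattern, subject, match = 1, mismatch = -1,
                                open = 2, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(s)
  Hprev <- numeric(n + 1L)
  Fprev <- rep(-Inf, n + 1L)
  best <- 0
  idx <- seq_len(n)
  for (i in seq_along(p)) {
    sc <- ifelse(s == p[i], match, mismatch)
    Fi <- pmax(Hprev - open - ext, Fprev - ext)
    H0 <- pmax(0, Hprev[idx] + sc, Fi[idx + 1L])
    # gaps in the subject direction: exact via running max of H0[k] + k*ext
    M <- cummax(H0 + idx * ext)
    E <- c(-Inf, M[-n] - open)[seq_len(n)] - idx * ext
    Hi <- pmax(H0, E)
    best <- max(best, max(Hi))
    Hprev <- c(0, Hi)
    Fprev <- c(-Inf, Fi[idx + 1L])
  }
  best
}

# Small, fast simulation configuration shared by end-to-end tests.
tiny_config <- function(seed = 7, n_events = 15, error_rate = 0, library_type = "tdna",
                        background_fraction = 0.15, ...) {
  run_config(
    seed = seed, library_type = library_type,
    sim = sim_params(genome_len = 24000, n_trna_genes = 6, n_events = n_events,
                     error_rate = error_rate, background_fraction = background_fraction,
                     palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L,
                     library_type = library_type, seed = seed, ...)
  )
}

random_refs <- function(n, len, gc = 0.25, seed = 1) {
  with_seed_test(seed, {
    tibble::tibble(ref_id = sprintf("r%03d", seq_len(n)), kind = "chromosome",
                   seq = vapply(seq_len(n), function(i)
                     paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                           collapse = ""), character(1)))
  })
}

# Test-local DNA helpers (kept independent of package internals where they
# serve as oracles; plain aliases where they are plumbing).
random_dna <- function(n, gc = 0.25) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
splice_in <- function(seq, at, insert) {
  paste0(substr(seq, 1, at - 1), insert, substr(seq, at + nchar(insert), nchar(seq)))
}
sample_motif_instance <- function(motif) treprofiler:::sample_motif_instance(motif)
ref_seq <- function(refs, id) refs$seq[match(id, refs$ref_id)]

# Seed an expression locally without disturbing the session RNG.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
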