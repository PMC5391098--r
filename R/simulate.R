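# Synthetic profiling data with a planted truth set.
#
# The generator emulates the study design end to end: an A+T-rich genome with
# planted tRNA genes (+1 G, A box at +8, B box at 32-57 bp spacing), a
# mirror-symmetric rDNA-palindrome analog carrying A/B-box loci and a 5S-like
# gene, a plasmid reference holding the transformed element copy, planted
# orientation-specific integrations (distance ~47 bp upstream, 5'
# truncations, non-templated extra nucleotides, target site duplications),
# and LAM-PCR-shaped read pairs for the tDNA-primer and adapter-primer
# library designs, including plasmid/promoter background.

DNA_BASES <- c("A", "C", "G", "T")

# Fixed adapter used by the adapter-primer library simulation.
ADAPTER_SEQ <- "CTAGAGACCGGCAGTCAATCGT"

# ---- insertion-distance distributions ---------------------------------------

#' Insertion-distance distributions
#'
#' Discrete distributions over the integration distance (bases strictly
#' between the element 5' terminus and the target +1). `dist_gaussian()` is
#' an integer-discretised truncated Gaussian (default mean 47, sd 2,
#' support 23-181); `dist_fixed()` is degenerate; `dist_uniform()` is uniform
#' over an integer range; `dist_table()` takes explicit probabilities.
#'
#' @param mean,sd Gaussian location and scale (bp).
#' @param min,max Integer support bounds (bp).
#' @param d Fixed distance for `dist_fixed()`.
#' @param values,probs Support and probabilities for `dist_table()`.
#' @return A list describing the distribution, for use in [sim_params()].
#' @export
dist_gaussian <- function(mean = 47, sd = 2, min = 23L, max = 181L) {
  list(kind = "gaussian", mean = mean, sd = sd, min = as.integer(min), max = as.integer(max))
}

#' @rdname dist_gaussian
#' @export
dist_fixed <- function(d) list(kind = "fixed", d = as.integer(d))

#' @rdname dist_gaussian
#' @export
dist_uniform <- function(min, max) list(kind = "uniform", min = as.integer(min), max = as.integer(max))

#' @rdname dist_gaussian
#' @export
dist_table <- function(values, probs) {
  stopifnot(length(values) == length(probs), all(probs >= 0), sum(probs) > 0, all(values >= 1))
  list(kind = "table", values = as.integer(values), probs = probs / sum(probs))
}

#' Probability mass function of a distance distribution
#'
#' @param dist A distribution from [dist_gaussian()] and friends.
#' @return Tibble with columns `distance`, `prob`.
#' @export
distance_pmf <- function(dist) {
  switch(dist$kind,
    fixed = tibble::tibble(distance = dist$d, prob = 1),
    uniform = {
      v <- seq.int(dist$min, dist$max)
      tibble::tibble(distance = v, prob = rep(1 / length(v), length(v)))
    },
    table = tibble::tibble(distance = dist$values, prob = dist$probs),
    gaussian = {
      v <- seq.int(dist$min, dist$max)
      p <- stats::pnorm(v + 0.5, dist$mean, dist$sd) - stats::pnorm(v - 0.5, dist$mean, dist$sd)
      tibble::tibble(distance = v, prob = p / sum(p))
    },
    stop("unknown distance distribution kind: ", dist$kind)
  )
}

sample_distances <- function(dist, n) {
  pmf <- distance_pmf(dist)
  if (nrow(pmf) == 1L) rep(pmf$distance, n) else
    sample(pmf$distance, n, replace = TRUE, prob = pmf$prob)
}

# ---- simulation parameters ---------------------------------------------------

#' Simulation parameters
#'
#' Defaults describe the study conditions the generator emulates: an A+T-rich
#' genome (GC 0.25), A/B-box spacings of 32-57 bp, integration distances from
#' an integer Gaussian centred at 47 bp (sd 2) truncated to 23-181 bp, short
#' 5' truncations, 1-3 non-templated extra nucleotides at half of the
#' junctions, target site duplications of 0-15 bp, 300-bp paired-end reads
#' with constant Q30 qualities, and a plasmid/promoter read background.
#'
#' @param genome_len Chromosome length in bp.
#' @param gc_content GC fraction of background DNA.
#' @param n_trna_genes Number of planted tRNA genes.
#' @param n_families Number of tRNA gene families the genes are labelled with.
#' @param ab_spacing_range A/B-box spacing range sampled per gene (bp).
#' @param distance_dist Insertion-distance distribution ([dist_gaussian()]).
#' @param tsd_len_range Target-site-duplication length range (bp).
#' @param p_truncation Probability that an insertion is 5'-truncated.
#' @param truncation_geom_p Geometric parameter of the truncation length
#'   (support 1, 2, ...; capped at `max_truncation`).
#' @param max_truncation Maximum truncation in bp.
#' @param p_extra_nt Probability of non-templated extra nucleotides.
#' @param extra_len_range Length range of the extras (bp).
#' @param read_len Read length (bp).
#' @param frag_len_range Genomic extent of adapter-library fragments and of
#'   plasmid background fragments (bp, measured from the junction).
#' @param error_rate Per-base substitution error probability.
#' @param library_type `"tdna"` or `"adapter"`.
#' @param n_reads_per_event Integer range of read pairs emitted per event.
#' @param n_events Number of integration events to plant.
#' @param background_fraction Fraction of all read pairs that are background
#'   (half plasmid/promoter, half unrelated genome).
#' @param share_family_sequence Give all genes of a family one sequence
#'   (default `FALSE`: every gene is distinguishable, i.e. unique flanks).
#' @param palindrome_arm_len Length of one palindrome arm (bp).
#' @param n_palindrome_ab_loci A/B-box loci planted per arm.
#' @param seed Default seed for the generator stages.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_len = 100000L, gc_content = 0.25,
                       n_trna_genes = 40L, n_families = 8L,
                       ab_spacing_range = c(32L, 57L),
                       distance_dist = dist_gaussian(),
                       tsd_len_range = c(0L, 15L),
                       p_truncation = 0.25, truncation_geom_p = 0.35,
                       max_truncation = 40L,
                       p_extra_nt = 0.5, extra_len_range = c(1L, 3L),
                       read_len = 300L,
                       frag_len_range = c(45L, 150L),
                       error_rate = 0.001,
                       library_type = c("tdna", "adapter"),
                       n_reads_per_event = c(1L, 5L),
                       n_events = 250L,
                       background_fraction = 0.1,
                       share_family_sequence = FALSE,
                       palindrome_arm_len = 8000L,
                       n_palindrome_ab_loci = 3L,
                       seed = 1L) {
  library_type <- match.arg(library_type)
  stopifnot(gc_content >= 0, gc_content <= 1,
            p_truncation >= 0, p_truncation <= 1,
            p_extra_nt >= 0, p_extra_nt <= 1,
            error_rate >= 0, error_rate < 1,
            background_fraction >= 0, background_fraction < 1,
            ab_spacing_range[1] <= ab_spacing_range[2],
            n_reads_per_event[1] >= 1)
  structure(list(
    genome_len = as.integer(genome_len), gc_content = gc_content,
    n_trna_genes = as.integer(n_trna_genes), n_families = as.integer(n_families),
    ab_spacing_range = as.integer(ab_spacing_range),
    distance_dist = distance_dist,
    tsd_len_range = as.integer(tsd_len_range),
    p_truncation = p_truncation, truncation_geom_p = truncation_geom_p,
    max_truncation = as.integer(max_truncation),
    p_extra_nt = p_extra_nt, extra_len_range = as.integer(extra_len_range),
    read_len = as.integer(read_len),
    frag_len_range = as.integer(frag_len_range),
    error_rate = error_rate, library_type = library_type,
    n_reads_per_event = as.integer(n_reads_per_event),
    n_events = as.integer(n_events),
    background_fraction = background_fraction,
    share_family_sequence = isTRUE(share_family_sequence),
    palindrome_arm_len = as.integer(palindrome_arm_len),
    n_palindrome_ab_loci = as.integer(n_palindrome_ab_loci),
    seed = as.integer(seed)
  ), class = "sim_params")
}

# Sample a concrete instance of an IUPAC motif, one base per position.
sample_motif_instance <- function(motif) {
  chars <- strsplit(check_iupac(motif), "")[[1]]
  paste(vapply(IUPAC_CODES[chars], function(s) {
    opts <- strsplit(s, "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# Build one Pol III gene in local coordinates (position 1 = the +1 G).
# Returns seq plus local box and primer coordinates.
make_pol3_gene <- function(spacing, cp, with_tail = TRUE) {
  a_box <- sample_motif_instance(cp$a_box_stringent)
  b_box <- sample_motif_instance(cp$b_box_motif)
  head <- paste0("G", random_dna(6, gc = 0.4))
  spacer <- random_dna(spacing, gc = 0.3)
  tail <- if (with_tail) paste0(random_dna(8, gc = 0.3), "TTTTT") else ""
  seq <- paste0(head, a_box, spacer, b_box, tail)
  glen <- nchar(seq)
  list(
    seq = seq,
    a_start = 8L, a_end = 8L + nchar(a_box) - 1L,
    b_start = 8L + nchar(a_box) + spacing,
    b_end = 8L + nchar(a_box) + spacing + nchar(b_box) - 1L,
    primer_start = if (with_tail) glen - 24L else NA_integer_,
    primer_end = if (with_tail) glen - 5L else NA_integer_
  )
}

# Splice `insert` over positions [at, at + nchar(insert) - 1] of `seq`.
splice_in <- function(seq, at, insert) {
  paste0(substr(seq, 1L, at - 1L), insert, substr(seq, at + nchar(insert), nchar(seq)))
}

# Complement of single bases (character vector).
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Generate a synthetic genome and its target catalog
#'
#' Plants `n_trna_genes` tRNA genes (strands at random) on one chromosome,
#' builds a mirror-symmetric palindrome with A/B-box loci and a 5S-like gene
#' on both arms, and adds a plasmid reference holding the transformed element
#' copy (element preceded by its promoter context). Deterministic given
#' `seed`.
#'
#' @param params A [sim_params()] object.
#' @param element An [element_model()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @param catalog_parameters A [catalog_params()] object used for motif
#'   instances and duplicate grouping.
#' @return A list of class `tre_genome`: `refs` (tibble `ref_id`, `kind`,
#'   `seq`), `catalog` (see [build_ab_box_catalog()] for columns), `primers`
#'   (per-target tDNA trimming primers), `element`, `params`.
#' @export
make_genome <- function(params = sim_params(), element = element_model(),
                        seed = params$seed,
                        catalog_parameters = catalog_params()) {
  cp <- catalog_parameters
  with_seed(derive_seed(seed, 1L), {
    glen_max <- 40L + params$ab_spacing_range[2]
    slot <- params$genome_len %/% params$n_trna_genes
    if (slot < 2L * 300L + glen_max + 50L) {
      stop("infeasible packing: ", params$n_trna_genes, " tRNA genes do not fit in ",
           params$genome_len, " bp with required clearance")
    }
    chr <- random_dna(params$genome_len, params$gc_content)

    fams <- sprintf("fam%02d", rep_len(seq_len(params$n_families), params$n_trna_genes))
    fam_gene <- list()  # cached per-family gene when sequences are shared
    cat_rows <- list(); primer_rows <- list()
    for (i in seq_len(params$n_trna_genes)) {
      spacing <- sample(seq.int(params$ab_spacing_range[1], params$ab_spacing_range[2]), 1L)
      if (params$share_family_sequence && !is.null(fam_gene[[fams[i]]])) {
        g <- fam_gene[[fams[i]]]
      } else {
        g <- make_pol3_gene(spacing, cp, with_tail = TRUE)
        if (params$share_family_sequence) fam_gene[[fams[i]]] <- g
      }
      glen <- nchar(g$seq)
      strand <- sample(c("+", "-"), 1L)
      lo <- (i - 1L) * slot + 300L
      hi <- i * slot - 300L - glen
      p1 <- sample(seq.int(lo, hi), 1L)
      if (strand == "+") {
        chr <- splice_in(chr, p1, g$seq)
        a <- c(p1 + g$a_start - 1L, p1 + g$a_end - 1L)
        b <- c(p1 + g$b_start - 1L, p1 + g$b_end - 1L)
      } else {
        p1 <- p1 + glen - 1L   # +1 sits at the high end of the spliced block
        chr <- splice_in(chr, p1 - glen + 1L, revcomp(g$seq))
        a <- c(p1 - g$a_end + 1L, p1 - g$a_start + 1L)
        b <- c(p1 - g$b_end + 1L, p1 - g$b_start + 1L)
      }
      tid <- sprintf("trna%03d", i)
      cat_rows[[i]] <- tibble::tibble(
        target_id = tid, ref_id = "chr1", plus_one = p1, strand = strand,
        target_class = "trna", a_start = a[1], a_end = a[2],
        b_start = b[1], b_end = b[2], a_box_class = "stringent",
        family = fams[i], duplicate_group = tid
      )
      primer_rows[[i]] <- tibble::tibble(
        target_id = tid, family = fams[i],
        primer = substr(g$seq, g$primer_start, g$primer_end),
        p_start = g$primer_start, p_end = g$primer_end
      )
    }

    # palindrome: left arm carries the loci; full element is arm + revcomp(arm)
    arm <- random_dna(params$palindrome_arm_len, params$gc_content)
    n_loc <- params$n_palindrome_ab_loci + 1L  # + one 5S-like gene
    pslot <- params$palindrome_arm_len %/% n_loc
    stopifnot(pslot > 700L)
    pal_rows <- list()
    for (j in seq_len(n_loc)) {
      is_5s <- j == n_loc
      g <- make_pol3_gene(sample(seq.int(params$ab_spacing_range[1], params$ab_spacing_range[2]), 1L),
                          cp, with_tail = is_5s)
      p1 <- (j - 1L) * pslot + 300L + sample.int(50L, 1L)
      arm <- splice_in(arm, p1, g$seq)
      pal_rows[[j]] <- tibble::tibble(
        target_id = if (is_5s) "pal5S_L" else sprintf("palab%02d_L", j),
        ref_id = "palindrome", plus_one = p1, strand = "+",
        target_class = if (is_5s) "five_s" else "ab_box",
        a_start = p1 + g$a_start - 1L, a_end = p1 + g$a_end - 1L,
        b_start = p1 + g$b_start - 1L, b_end = p1 + g$b_end - 1L,
        a_box_class = "stringent", family = if (is_5s) "5S" else "ab_box",
        duplicate_group = NA_character_
      )
    }
    pal_left <- dplyr::bind_rows(pal_rows)
    La <- params$palindrome_arm_len
    pal_right <- pal_left |>
      dplyr::mutate(
        target_id = sub("_L$", "_R", .data$target_id),
        plus_one = 2L * La - .data$plus_one + 1L,
        strand = "-",
        a_start0 = 2L * La - .data$a_end + 1L, a_end = 2L * La - .data$a_start + 1L,
        b_start0 = 2L * La - .data$b_end + 1L, b_end = 2L * La - .data$b_start + 1L
      ) |>
      dplyr::mutate(a_start = .data$a_start0, b_start = .data$b_start0) |>
      dplyr::select(-"a_start0", -"b_start0")
    palindrome <- paste0(arm, revcomp(arm))

    plasmid <- paste0(revcomp(element$full_sequence), element$plasmid_context)

    refs <- dplyr::bind_rows(
      new_refs("chr1", "chromosome", chr),
      new_refs("palindrome", "palindrome_arm", palindrome),
      new_refs("plasmid", "plasmid", plasmid)
    )
    catalog <- dplyr::bind_rows(c(cat_rows, list(pal_left, pal_right))) |>
      dplyr::mutate(duplicate_group = dplyr::coalesce(.data$duplicate_group, .data$target_id))
    catalog <- group_duplicate_loci(catalog, refs, cp)
    validate_catalog(catalog, cp)
    structure(list(
      refs = refs, catalog = catalog,
      primers = dplyr::bind_rows(primer_rows),
      element = element, params = params, seed = as.integer(seed)
    ), class = "tre_genome")
  })
}

# ---- planting integrations ---------------------------------------------------

# Gene-sense base `i` positions upstream of the junction (beyond the gap):
# the base that a leftward alignment extension would pair with.
upstream_base <- function(refseq, plus_one, strand, d, i) {
  if (strand == "+") substr(refseq, plus_one - d - i, plus_one - d - i)
  else comp_base(substr(refseq, plus_one + d + i, plus_one + d + i))
}

# Gene-sense gap base g_i (g_1 adjacent to the element 5' terminus).
gap_base <- function(refseq, plus_one, strand, d, i) {
  if (strand == "+") substr(refseq, plus_one - d + (i - 1L), plus_one - d + (i - 1L))
  else comp_base(substr(refseq, plus_one + d - (i - 1L), plus_one + d - (i - 1L)))
}

#' Plant integration events and build the truth table
#'
#' Each event samples a target (tRNA genes for the tDNA library; any catalog
#' target for the adapter library), an insertion distance, a 5' truncation,
#' non-templated extra nucleotides, and a target-site-duplication length,
#' then builds a mutated allele (haplotype) window around the junction with
#' the orientation-specific geometry: element 5' end facing the target +1,
#' extras at the 5' junction, duplicated target bases flanking the insert.
#' Extras are planted so that no alignment-tie ambiguity exists between
#' element, extras and genome at the junction (an extra base identical to the
#' adjacent genomic or element base is undetectable in principle and is never
#' planted; see the methods vignette). Deterministic given `seed`.
#'
#' @param genome A `tre_genome` from [make_genome()].
#' @param n_events Number of events (default `params$n_events`).
#' @param seed Integer seed.
#' @return A list of class `tre_sim`: `genome`, `refs` (originals plus one
#'   haplotype sequence per event), `truth` tibble (`event_id`, `target_id`,
#'   `duplicate_group`, `ref_id`, `strand`, `plus_one`, `distance`,
#'   `truncation`, `extras`, `tsd_len`, `hap_id`), and `n_resampled`.
#' @export
plant_integrations <- function(genome, n_events = genome$params$n_events,
                               seed = genome$params$seed) {
  params <- genome$params
  element <- genome$element
  elem <- element$full_sequence
  L <- nchar(elem)
  eligible <- if (params$library_type == "tdna") {
    dplyr::filter(genome$catalog, .data$target_class == "trna")
  } else genome$catalog
  if (!nrow(eligible)) stop("catalog has no eligible targets")
  n_resampled <- 0L
  with_seed(derive_seed(seed, 2L), {
    rows <- vector("list", n_events)
    haps <- vector("list", n_events)
    for (e in seq_len(n_events)) {
      tgt <- eligible[sample.int(nrow(eligible), 1L), ]
      refseq <- ref_seq(genome$refs, tgt$ref_id)
      rl <- nchar(refseq)
      P <- tgt$plus_one; strand <- tgt$strand

      repeat {
        d <- sample_distances(params$distance_dist, 1L)
        jlo <- if (strand == "+") P - d else P + 1L
        jhi <- if (strand == "+") P - 1L else P + d
        in_gap <- genome$catalog$ref_id == tgt$ref_id &
          genome$catalog$plus_one >= jlo - 20L & genome$catalog$plus_one <= jhi &
          genome$catalog$target_id != tgt$target_id
        fits <- if (strand == "+") P - d - params$tsd_len_range[2] - 45L >= 1L
                else P + d + params$tsd_len_range[2] + 45L <= rl
        if (fits && !any(in_gap)) break
        n_resampled <- n_resampled + 1L
      }

      # truncation, resampled until the element-side junction is free of
      # score-improving alignment extensions (see vignette)
      trunc <- 0L
      if (stats::runif(1) < params$p_truncation) {
        trunc <- min(stats::rgeom(1, params$truncation_geom_p) + 1L, params$max_truncation)
      }
      # extras: each base anti-matched to the genomic base it would pair with
      # in a leftward extension; first base also anti-matched to the next
      # truncated element base
      xlen <- 0L
      if (stats::runif(1) < params$p_extra_nt) {
        xlen <- sample(seq.int(params$extra_len_range[1], params$extra_len_range[2]), 1L)
      }
      xs <- character(xlen)
      if (xlen > 0L) {
        for (k in seq_len(xlen)) {
          forbid <- upstream_base(refseq, P, strand, d, xlen - k + 1L)
          if (k == 1L && trunc > 0L) forbid <- c(forbid, comp_base(substr(elem, trunc, trunc)))
          xs[k] <- sample(setdiff(DNA_BASES, forbid), 1L)
        }
      }
      extras <- paste(xs, collapse = "")
      if (trunc > 0L) {
        # every prefix of a rightward element-extension walk must score <= -1,
        # so not even a single masked (N) junction base can make an extension
        # profitable for the aligner
        for (try in 1:25) {
          post <- vapply(seq_len(trunc), function(i) {
            if (i <= xlen) xs[i] else gap_base(refseq, P, strand, d, i - xlen)
          }, character(1))
          esides <- comp_base(vapply(seq_along(post), function(i) {
            substr(elem, trunc + 1L - i, trunc + 1L - i)
          }, character(1)))
          sums <- cumsum(ifelse(post == esides, 1L, -1L))
          if (all(sums <= -1L)) break
          trunc <- if (try < 25) min(stats::rgeom(1, params$truncation_geom_p) + 1L,
                                     params$max_truncation) else 0L
          if (trunc == 0L) break
        }
      }

      tsd <- sample(seq.int(params$tsd_len_range[1], params$tsd_len_range[2]), 1L)
      tsd <- min(tsd, max(0L, d - 1L))

      elem_ins <- substr(elem, 1L + trunc, L)
      hap_id <- sprintf("%s|ev%04d", tgt$ref_id, e)
      if (strand == "+") {
        up <- substr(refseq, max(1L, P - d - tsd - 40L), P - d - 1L)
        tsd_seq <- if (tsd > 0L) substr(refseq, P - d, P - d + tsd - 1L) else ""
        down <- substr(refseq, P - d, min(rl, P + 250L))
        hap <- paste0(up, tsd_seq, revcomp(elem_ins), extras, down)
      } else {
        up <- substr(refseq, max(1L, P - 250L), P + d)
        tsd_seq <- if (tsd > 0L) substr(refseq, P + d - tsd + 1L, P + d) else ""
        down <- substr(refseq, P + d + 1L, min(rl, P + d + tsd + 40L))
        hap <- paste0(up, revcomp(extras), elem_ins, tsd_seq, down)
      }
      haps[[e]] <- new_refs(hap_id, "haplotype", hap)
      rows[[e]] <- tibble::tibble(
        event_id = sprintf("ev%04d", e), target_id = tgt$target_id,
        duplicate_group = tgt$duplicate_group, ref_id = tgt$ref_id,
        strand = strand, plus_one = P, distance = d, truncation = trunc,
        extras = extras, tsd_len = tsd, hap_id = hap_id
      )
    }
    structure(list(
      genome = genome,
      refs = dplyr::bind_rows(c(list(genome$refs), haps)),
      truth = dplyr::bind_rows(rows),
      n_resampled = n_resampled
    ), class = "tre_sim")
  })
}

# ---- read simulation ----------------------------------------------------------

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Gene-sense genomic sequence starting at the junction base g1, length len.
gene_sense_from_junction <- function(refseq, plus_one, strand, d, len) {
  if (strand == "+") substr(refseq, plus_one - d, plus_one - d + len - 1L)
  else revcomp(substr(refseq, plus_one + d - len + 1L, plus_one + d))
}

#' Simulate LAM-PCR amplicon read pairs
#'
#' Emits paired 300-bp reads per planted event. Every amplicon runs from the
#' LAM (ORF1) primer across the element 5' end and the junction into the
#' genomic flank; tDNA-library amplicons end at the target's tDNA primer
#' site, adapter-library amplicons end at a random genomic position followed
#' by the reverse-complemented hexamer+adapter. Background pairs come from
#' the transformed plasmid copy (promoter context visible) and from unrelated
#' genome. Substitution errors at `error_rate`; constant Q30 qualities.
#' Deterministic given `seed`.
#'
#' @param sim A `tre_sim` from [plant_integrations()].
#' @param seed Integer seed.
#' @return A list of class `tre_reads`: `pairs` (tibble `read_id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`, `origin`), `read_map` (`read_id`, `event_id`,
#'   `origin`), `truth` (truth table with `n_reads_emitted` filled).
#' @export
simulate_amplicons <- function(sim, seed = sim$genome$params$seed) {
  params <- sim$genome$params
  element <- sim$genome$element
  elem <- element$full_sequence
  pe <- element_amplicon_end(element)
  rl <- params$read_len
  primers <- sim$genome$primers
  refs <- sim$genome$refs
  truth <- sim$truth
  with_seed(derive_seed(seed, 3L), {
    amps <- character(0); map <- list()
    n_reads <- integer(nrow(truth))
    for (e in seq_len(nrow(truth))) {
      tr <- truth[e, ]
      refseq <- ref_seq(refs, tr$ref_id)
      n <- sample(seq.int(params$n_reads_per_event[1], params$n_reads_per_event[2]), 1L)
      n_reads[e] <- n
      elem_part <- revcomp(substr(elem, 1L + tr$truncation, pe))
      for (r in seq_len(n)) {
        if (params$library_type == "tdna") {
          pr <- primers[primers$target_id == tr$target_id, ]
          tail_len <- tr$distance + pr$p_end
          genomic <- gene_sense_from_junction(refseq, tr$plus_one, tr$strand, tr$distance, tail_len)
          amp <- paste0(elem_part, tr$extras, genomic)
        } else {
          k <- sample(seq.int(params$frag_len_range[1], params$frag_len_range[2]), 1L)
          genomic <- gene_sense_from_junction(refseq, tr$plus_one, tr$strand, tr$distance, k)
          amp <- paste0(elem_part, tr$extras, genomic,
                        revcomp(random_dna(6, 0.5)), revcomp(ADAPTER_SEQ))
        }
        amps <- c(amps, amp)
        map[[length(map) + 1L]] <- tibble::tibble(event_id = tr$event_id, origin = "junction")
      }
    }
    n_junction <- length(amps)
    f <- params$background_fraction
    n_bg <- if (f > 0) round(n_junction * f / (1 - f)) else 0L
    n_plasmid <- n_bg %/% 2L; n_rand <- n_bg - n_plasmid
    ctx <- element$plasmid_context
    for (b in seq_len(n_plasmid)) {
      k <- sample(seq.int(params$frag_len_range[1], params$frag_len_range[2]), 1L)
      amp <- paste0(revcomp(substr(elem, 1L, pe)), substr(ctx, 1L, k))
      if (params$library_type == "adapter") {
        amp <- paste0(amp, revcomp(random_dna(6, 0.5)), revcomp(ADAPTER_SEQ))
      }
      amps <- c(amps, amp)
      map[[length(map) + 1L]] <- tibble::tibble(event_id = NA_character_, origin = "plasmid")
    }
    chr <- ref_seq(refs, "chr1")
    for (b in seq_len(n_rand)) {
      len <- sample(150:450, 1L)
      s <- sample.int(nchar(chr) - len, 1L)
      frag <- substr(chr, s, s + len - 1L)
      if (stats::runif(1) < 0.5) frag <- revcomp(frag)
      amps <- c(amps, frag)
      map[[length(map) + 1L]] <- tibble::tibble(event_id = NA_character_, origin = "genomic_background")
    }

    pairs <- tibble::tibble(
      read_id = sprintf("rd%06d", seq_along(amps)),
      seq1 = vapply(amps, function(a) substr(a, 1L, min(rl, nchar(a))), character(1), USE.NAMES = FALSE),
      seq2 = vapply(amps, function(a) revcomp(substr(a, max(1L, nchar(a) - rl + 1L), nchar(a))), character(1), USE.NAMES = FALSE)
    )
    if (params$error_rate > 0) {
      pairs$seq1 <- vapply(pairs$seq1, apply_errors, character(1), rate = params$error_rate, USE.NAMES = FALSE)
      pairs$seq2 <- vapply(pairs$seq2, apply_errors, character(1), rate = params$error_rate, USE.NAMES = FALSE)
    }
    pairs$qual1 <- strrep("?", nchar(pairs$seq1))  # constant Q30
    pairs$qual2 <- strrep("?", nchar(pairs$seq2))
    read_map <- dplyr::bind_rows(map) |>
      dplyr::mutate(read_id = pairs$read_id, .before = 1)
    pairs$origin <- read_map$origin
    truth$n_reads_emitted <- n_reads
    structure(list(pairs = pairs, read_map = read_map, truth = truth,
                   library_type = params$library_type),
              class = "tre_reads")
  })
}

# ---- plain-text IO ------------------------------------------------------------

#' Write references as FASTA
#' @param refs Reference tibble (`ref_id`, `kind`, `seq`).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_refs_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$seq)
  names(x) <- paste0(refs$ref_id, " kind=", refs$kind)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read references from FASTA
#' @param path FASTA path; the description may carry `kind=...`.
#' @return Reference tibble.
#' @export
read_refs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*", "", nm)
  kind <- ifelse(grepl("kind=", nm), sub(".*kind=(\\S+).*", "\\1", nm), "chromosome")
  new_refs(id, kind, unname(as.character(x)))
}

#' Write paired reads as FASTQ
#' @param reads A `tre_reads` object or a pairs tibble.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  pairs <- if (inherits(reads, "tre_reads")) reads$pairs else reads
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  w(pairs$seq1, pairs$qual1, pairs$read_id, r1_path)
  w(pairs$seq2, pairs$qual2, pairs$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ into a pairs tibble
#' @param r1_path,r2_path FASTQ paths (read 1 / read 2).
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  stopifnot(length(r1) == length(r2))
  tibble::tibble(
    read_id = sub("\\s.*", "", names(r1)),
    seq1 = unname(as.character(r1)),
    qual1 = unname(as.character(Biostrings::quality(r1))),
    seq2 = unname(as.character(r2)),
    qual2 = unname(as.character(Biostrings::quality(r2)))
  )
}

#' Write / read the planted truth table
#'
#' TSV with a header comment recording the seed and the distance convention.
#' @param truth Truth tibble (see [plant_integrations()]).
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return The path (writer) or the truth tibble (reader).
#' @export
write_truth <- function(truth, path, seed = NA_integer_) {
  readr::write_lines(c(
    "# treprofiler truth table",
    paste0("# seed: ", seed),
    "# distance: bases strictly between element 5' terminus (excluding extras) and the target +1"
  ), path)
  readr::write_tsv(truth, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE) |>
    dplyr::mutate(extras = dplyr::coalesce(as.character(.data$extras), ""))
}
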