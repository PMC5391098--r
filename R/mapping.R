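# Junction-fragment mapping: seed-and-extend local alignment plus the
# hit-acceptance rules (unique hits; multi-hits only when the second-best
# score is at most 75% of the best and the fragment aligns over at least 95%
# of its length; exact score ties confined to one duplicate group are
# accepted as a group placement).

#' Mapping parameters
#'
#' @param seed_k Exact seed k-mer size (default 11).
#' @param match,mismatch Match/mismatch scores (+1/-1).
#' @param gap_open,gap_extend Gap penalties as positive costs; a gap of
#'   length g costs `gap_open + g * gap_extend` (defaults 2 and 1).
#' @param second_best_ratio A multi-hit fragment is accepted only when the
#'   second-best score is `<= second_best_ratio * best` (default 0.75,
#'   boundary inclusive).
#' @param min_query_coverage Minimum aligned fraction of the fragment
#'   (default 0.95, boundary inclusive).
#' @param apply_coverage_to_unique Apply the coverage rule to unique hits as
#'   well as multi-hits (default `TRUE`; switchable because the original
#'   filter wording lists it only under multi-hits).
#' @param seed_stride Sample a seed k-mer every this many query positions
#'   (default 4).
#' @param window_pad Reference padding around a seed cluster before
#'   extension (default 40).
#' @param max_diag_gap Seeds whose diagonals differ by at most this are
#'   clustered together (default 15).
#' @param min_seed_count Minimum seeds per cluster before extension
#'   (default 2; singleton seed hits are overwhelmingly spurious in
#'   A+T-rich DNA and are skipped). Queries shorter than 50 nt fall back to
#'   single-seed clusters, since a mismatch can leave only one clean seed.
#' @return A list of class `map_params`.
#' @export
map_params <- function(seed_k = 11L, match = 1, mismatch = -1,
                       gap_open = 2, gap_extend = 1,
                       second_best_ratio = 0.75, min_query_coverage = 0.95,
                       apply_coverage_to_unique = TRUE,
                       seed_stride = 4L, window_pad = 40L, max_diag_gap = 15L,
                       min_seed_count = 2L) {
  stopifnot(second_best_ratio > 0, second_best_ratio <= 1,
            min_query_coverage > 0, min_query_coverage <= 1,
            seed_k >= 4, seed_stride >= 1, min_seed_count >= 1)
  structure(list(
    seed_k = as.integer(seed_k), match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    second_best_ratio = second_best_ratio,
    min_query_coverage = min_query_coverage,
    apply_coverage_to_unique = isTRUE(apply_coverage_to_unique),
    seed_stride = as.integer(seed_stride), window_pad = as.integer(window_pad),
    max_diag_gap = as.integer(max_diag_gap),
    min_seed_count = as.integer(min_seed_count)
  ), class = "map_params")
}

#' Build an exact k-mer index over references
#'
#' @param refs Reference tibble (`ref_id`, `kind`, `seq`).
#' @param params A [map_params()] object (supplies `seed_k`).
#' @return A list of class `tre_index` with one position environment per
#'   reference.
#' @export
index_references <- function(refs, params = map_params()) {
  check_refs(refs)
  if (!nrow(refs)) stop("empty reference set")
  k <- params$seed_k
  envs <- purrr::map(seq_len(nrow(refs)), function(i) {
    seq <- refs$seq[i]
    n <- nchar(seq) - k + 1L
    if (n < 1L) return(new.env(parent = emptyenv()))
    starts <- seq_len(n)
    kmers <- substring(seq, starts, starts + k - 1L)
    keep <- !stringr::str_detect(kmers, "N")
    list2env(split(starts[keep], kmers[keep]), envir = new.env(parent = emptyenv()))
  })
  structure(list(k = k, ref_ids = refs$ref_id, envs = envs, refs = refs),
            class = "tre_index")
}

# Extension alignment of query vs one reference window; returns a hit row.
extend_in_window <- function(query, refs_seq, ref_id, w_lo, w_hi, strand, qlen, mat, params) {
  subj <- substr(refs_seq, w_lo, w_hi)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subj), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  prange <- IRanges::ranges(Biostrings::pattern(pa))
  srange <- IRanges::ranges(Biostrings::subject(pa))
  qs <- BiocGenerics::start(prange); qe <- BiocGenerics::end(prange)
  if (strand == "-") {  # convert from revcomp(query) coordinates to fragment coordinates
    qs2 <- qlen - qe + 1L; qe <- qlen - qs + 1L; qs <- qs2
  }
  tibble::tibble(
    ref_id = ref_id,
    start = w_lo + BiocGenerics::start(srange) - 1L,
    end = w_lo + BiocGenerics::end(srange) - 1L,
    strand = strand,
    score = BiocGenerics::score(pa),
    q_start = qs, q_end = qe,
    coverage = BiocGenerics::width(prange) / qlen,
    identity = Biostrings::nmatch(pa) / BiocGenerics::width(prange)
  )
}

#' Align junction fragments to the references
#'
#' Seed-and-extend local alignment: exact `seed_k`-mers of the fragment (both
#' orientations) are looked up in the index, clustered by diagonal, and each
#' cluster window is extended with a local alignment under the configured
#' scoring. All reachable placements are returned, best first; deterministic.
#'
#' @param frags Fragment tibble with `read_id` and `genomic_part` (see
#'   [prep_reads()]).
#' @param index A [index_references()] object over the mapping references.
#' @param params A [map_params()] object.
#' @return Tibble of hits: `read_id`, `ref_id`, `start`, `end`, `strand`,
#'   `score`, `q_start`, `q_end`, `coverage`, `identity`, sorted by
#'   descending score within read.
#' @export
align_fragments <- function(frags, index, params = map_params()) {
  stopifnot(inherits(index, "tre_index"))
  k <- index$k
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch,
                                                  baseOnly = FALSE)
  res <- vector("list", nrow(frags))
  for (f in seq_len(nrow(frags))) {
    frag <- frags$genomic_part[f]
    qlen <- nchar(frag)
    if (is.na(frag) || qlen < k) next
    hits <- list()
    for (strand in c("+", "-")) {
      query <- if (strand == "+") frag else revcomp(frag)
      qpos <- unique(c(seq.int(1L, qlen - k + 1L, by = params$seed_stride), qlen - k + 1L))
      kmers <- substring(query, qpos, qpos + k - 1L)
      for (ri in seq_along(index$envs)) {
        env <- index$envs[[ri]]
        seeds <- list()
        for (j in seq_along(kmers)) {
          hit <- get0(kmers[j], envir = env, ifnotfound = NULL)
          if (!is.null(hit)) seeds[[length(seeds) + 1L]] <- cbind(qpos[j], hit)
        }
        if (!length(seeds)) next
        sm <- do.call(rbind, seeds)
        diag <- sm[, 2] - sm[, 1]
        ord <- order(diag)
        diag <- diag[ord]; sm <- sm[ord, , drop = FALSE]
        grp <- cumsum(c(1L, diff(diag) > params$max_diag_gap))
        refseq <- index$refs$seq[ri]
        rlen <- nchar(refseq)
        min_seeds <- if (qlen < 50L) 1L else params$min_seed_count
        for (g in unique(grp)) {
          rows <- sm[grp == g, , drop = FALSE]
          if (nrow(rows) < min_seeds) next
          # exact-placement shortcut: a single diagonal whose implied window
          # reproduces the query verbatim needs no DP extension
          diags <- unique(rows[, 2] - rows[, 1])
          if (length(diags) == 1L) {
            s0 <- diags + 1L
            if (s0 >= 1L && s0 + qlen - 1L <= rlen &&
                substr(refseq, s0, s0 + qlen - 1L) == query) {
              qs <- 1L; qe <- qlen
              hits[[length(hits) + 1L]] <- tibble::tibble(
                ref_id = index$ref_ids[ri], start = s0, end = s0 + qlen - 1L,
                strand = strand, score = params$match * qlen,
                q_start = qs, q_end = qe, coverage = 1, identity = 1
              )
              next
            }
          }
          w_lo <- max(1L, min(rows[, 2] - rows[, 1] + 1L) - params$window_pad)
          w_hi <- min(rlen, max(rows[, 2] + (qlen - rows[, 1])) + params$window_pad)
          hits[[length(hits) + 1L]] <-
            extend_in_window(query, refseq, index$ref_ids[ri], w_lo, w_hi,
                             strand, qlen, mat, params)
        }
      }
    }
    if (!length(hits)) next
    h <- dplyr::bind_rows(hits) |>
      dplyr::distinct(.data$ref_id, .data$start, .data$end, .data$strand, .keep_all = TRUE) |>
      dplyr::arrange(dplyr::desc(.data$score))
    h$read_id <- frags$read_id[f]
    res[[f]] <- h
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    return(tibble::tibble(read_id = character(0), ref_id = character(0),
                          start = integer(0), end = integer(0), strand = character(0),
                          score = numeric(0), q_start = integer(0), q_end = integer(0),
                          coverage = numeric(0), identity = numeric(0)))
  }
  dplyr::relocate(out, "read_id")
}

#' Apply the hit-acceptance rules to one fragment's hits
#'
#' A unique hit is accepted if its query coverage passes. With multiple hits
#' the best is accepted iff the second-best score does not exceed
#' `second_best_ratio` times the best (inclusive) and coverage passes. Exact
#' score ties among the top hits are accepted as a single *group placement*
#' iff all tied hits carry the same non-missing duplicate-group label.
#'
#' @param hits Hit tibble for one read, sorted by descending score.
#' @param params A [map_params()] object.
#' @param groups Optional character vector parallel to `hits` giving the
#'   duplicate-group label of the target nearest each hit (`NA` when none).
#' @return A one-row tibble: the accepted hit plus `accepted`, `reason`,
#'   `group_placement`, `duplicate_group`; or a rejection row with
#'   `accepted = FALSE`.
#' @export
accept_hits <- function(hits, params = map_params(), groups = NULL) {
  rejection <- function(reason) {
    tibble::tibble(accepted = FALSE, reason = reason,
                   group_placement = FALSE, duplicate_group = NA_character_)
  }
  if (is.null(hits) || nrow(hits) == 0L) return(rejection("unmapped"))
  ord <- order(-hits$score)
  hits <- hits[ord, , drop = FALSE]
  if (!is.null(groups)) groups <- groups[ord]
  best <- hits[1, ]
  eps <- 1e-9
  cov_ok <- best$coverage >= params$min_query_coverage - eps
  if (nrow(hits) == 1L) {
    if (params$apply_coverage_to_unique && !cov_ok) return(rejection("low_coverage"))
    return(dplyr::bind_cols(best, tibble::tibble(accepted = TRUE, reason = "unique",
                                                 group_placement = FALSE,
                                                 duplicate_group = NA_character_)))
  }
  tied <- which(hits$score >= best$score - eps)
  if (length(tied) > 1L) {
    g <- if (!is.null(groups)) unique(groups[tied]) else NA_character_
    if (length(g) == 1L && !is.na(g)) {
      if (!cov_ok) return(rejection("low_coverage"))
      return(dplyr::bind_cols(best, tibble::tibble(accepted = TRUE, reason = "duplicate_group_tie",
                                                   group_placement = TRUE,
                                                   duplicate_group = g)))
    }
    return(rejection("ambiguous"))
  }
  if (hits$score[2] > params$second_best_ratio * best$score + eps) {
    return(rejection("second_best_too_close"))
  }
  if (!cov_ok) return(rejection("low_coverage"))
  dplyr::bind_cols(best, tibble::tibble(accepted = TRUE, reason = "best_clear",
                                        group_placement = FALSE,
                                        duplicate_group = NA_character_))
}

#' Classify an accepted placement
#'
#' Placements on the plasmid reference (the transformed element copy with its
#' promoter context, including the retained-UTR region) are
#' `plasmid_actin6`: they are excluded from integration calling but counted.
#' Other accepted placements are `target_genome`; rejected fragments are
#' `unplaced`.
#'
#' @param placements Placement tibble (from [map_fragments()]).
#' @param refs Reference tibble (supplies `kind`).
#' @return The tibble with a `category` column.
#' @export
classify_placement <- function(placements, refs) {
  kind <- refs$kind[match(placements$ref_id, refs$ref_id)]
  placements$category <- dplyr::case_when(
    !placements$accepted ~ "unplaced",
    kind == "plasmid" ~ "plasmid_actin6",
    TRUE ~ "target_genome"
  )
  placements
}

# Duplicate-group label of the nearest facing target for each hit (used for
# tie resolution); NA when no target is within max_dist.
hit_group_labels <- function(hits, catalog, max_dist = 250L) {
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    j <- if (h$strand == "+") h$start else h$end
    cand <- catalog[catalog$ref_id == h$ref_id & catalog$strand == h$strand, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- if (h$strand == "+") cand$plus_one - j else j - cand$plus_one
    ok <- d >= 1 & d <= max_dist
    if (!any(ok)) return(NA_character_)
    cand$duplicate_group[ok][which.min(d[ok])]
  }, character(1))
}

#' Map fragments and apply acceptance and classification
#'
#' Convenience wrapper: [align_fragments()], then [accept_hits()] per read
#' (with duplicate-group labels derived from the catalog), then
#' [classify_placement()].
#'
#' @param frags Fragment tibble (see [prep_reads()]).
#' @param index A [index_references()] object.
#' @param catalog Target catalog (for duplicate-group tie resolution).
#' @param params A [map_params()] object.
#' @param max_assign_distance Distance cap used for group labelling.
#' @return A list of class `tre_map`: `placements` (one row per fragment),
#'   `hits` (all alignments), `counts`.
#' @export
map_fragments <- function(frags, index, catalog, params = map_params(),
                          max_assign_distance = 250L) {
  hits <- align_fragments(frags, index, params)
  if (!nrow(frags)) {
    placements <- tibble::tibble(read_id = character(0), ref_id = character(0),
                                 start = integer(0), end = integer(0),
                                 strand = character(0), score = numeric(0),
                                 q_start = integer(0), q_end = integer(0),
                                 coverage = numeric(0), identity = numeric(0),
                                 accepted = logical(0), reason = character(0),
                                 group_placement = logical(0),
                                 duplicate_group = character(0),
                                 category = character(0))
    return(structure(list(placements = placements, hits = hits,
                          counts = tibble::tibble(category = character(0), count = integer(0))),
                     class = "tre_map"))
  }
  placements <- purrr::map(seq_len(nrow(frags)), function(f) {
    h <- hits[hits$read_id == frags$read_id[f], , drop = FALSE]
    g <- if (nrow(h)) hit_group_labels(h, catalog, max_assign_distance) else NULL
    acc <- accept_hits(h, params, groups = g)
    acc$read_id <- frags$read_id[f]
    acc
  }) |> dplyr::bind_rows() |> dplyr::relocate("read_id")
  placements <- classify_placement(placements, index$refs)
  counts <- placements |> dplyr::count(.data$category, name = "count")
  structure(list(placements = placements, hits = hits, counts = counts),
            class = "tre_map")
}
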