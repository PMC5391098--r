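# Pol III integration-target catalog.
#
# Targets are tRNA genes, 5S genes, or bare A/B-box promoter loci. A target is
# anchored at the +1 nucleotide of the (real or hypothetical) Pol III
# transcript; integration distances are measured to this base. Throughout the
# package coordinates are 1-based, both ends inclusive, on the plus strand;
# only BED output converts to 0-based half-open.

#' Catalog-building parameters
#'
#' @param spacing_min,spacing_max Allowed A/B-box spacing in bp, counted as the
#'   bases strictly between the last base of the A box and the first base of
#'   the B box on the box strand. Defaults 30 and 60, the range compatible
#'   with efficient Pol III transcription; observed tRNA gene spacings fall in
#'   32-57 bp.
#' @param plus_one_offset The +1 nucleotide sits this many bp upstream of the
#'   A-box start (default 7, i.e. the A box starts at position +8).
#' @param flank_len_for_duplicates Loci whose upstream flanks of this length
#'   are identical strings are merged into one duplicate group (default 200).
#' @param scan_both_strands Scan both strands when building catalogs (default
#'   `TRUE`).
#' @param b_box_motif,a_box_permissive,a_box_stringent IUPAC motifs used by
#'   the scanner.
#' @param include_solo_b Promote solo B boxes (no A-box partner) to targets
#'   (default `FALSE`; solo B boxes are poor integration targets and are only
#'   recorded).
#' @return A list of class `catalog_params`.
#' @export
catalog_params <- function(spacing_min = 30L, spacing_max = 60L,
                           plus_one_offset = 7L,
                           flank_len_for_duplicates = 200L,
                           scan_both_strands = TRUE,
                           b_box_motif = "GTTCRANNC",
                           a_box_permissive = "TNNNNNANNNG",
                           a_box_stringent = "TRRYNNARYNG",
                           include_solo_b = FALSE) {
  stopifnot(spacing_min > 0, spacing_min <= spacing_max, plus_one_offset > 0,
            flank_len_for_duplicates > 0)
  structure(list(
    spacing_min = as.integer(spacing_min), spacing_max = as.integer(spacing_max),
    plus_one_offset = as.integer(plus_one_offset),
    flank_len_for_duplicates = as.integer(flank_len_for_duplicates),
    scan_both_strands = isTRUE(scan_both_strands),
    b_box_motif = check_iupac(b_box_motif),
    a_box_permissive = check_iupac(a_box_permissive),
    a_box_stringent = check_iupac(a_box_stringent),
    include_solo_b = isTRUE(include_solo_b)
  ), class = "catalog_params")
}

# Does `seq` (already extracted, plus-strand) match `motif` exactly at pos 1?
matches_iupac_at <- function(refs_seq, start, strand, motif) {
  w <- nchar(motif)
  sub <- substr(refs_seq, start, start + w - 1L)
  if (nchar(sub) < w) return(FALSE)
  if (strand == "-") sub <- revcomp(sub)
  grepl(paste0("^", iupac_to_regex(motif), "$"), sub)
}

#' Find A-box partners upstream of a B-box match
#'
#' Scans upstream of a B box (on the B box's strand) for permissive A-box
#' motif matches at a spacing inside `[spacing_min, spacing_max]`, where
#' spacing is the number of bases strictly between the A-box end and the
#' B-box start. Matches that also satisfy the stringent motif at the same
#' position are labelled `"stringent"`.
#'
#' @param refs Reference tibble (`ref_id`, `kind`, `seq`).
#' @param b_box One-row tibble or list with `ref_id`, `start`, `end`, `strand`
#'   as returned by [scan_motif()].
#' @param params A [catalog_params()] object.
#' @return Tibble with columns `a_start`, `a_end`, `strand`, `spacing`,
#'   `a_box_class` (`"stringent"` or `"permissive"`); empty when no partner.
#' @export
find_a_box_partners <- function(refs, b_box, params = catalog_params()) {
  check_refs(refs)
  seq <- ref_seq(refs, b_box$ref_id)
  wa <- nchar(params$a_box_permissive)
  if (b_box$strand == "+") {
    # a_end in [b_start - spacing_max - 1, b_start - spacing_min - 1]
    lo <- b_box$start - params$spacing_max - wa
    hi <- b_box$start - params$spacing_min - 1L
    win_lo <- max(1L, lo)
    if (hi < win_lo) return(empty_partners())
    window <- new_refs("w", "chromosome", substr(seq, win_lo, hi))
    hits <- scan_motif(window, params$a_box_permissive, both_strands = FALSE)
    if (!nrow(hits)) return(empty_partners())
    a_start <- hits$start + win_lo - 1L
    a_end <- a_start + wa - 1L
    spacing <- b_box$start - a_end - 1L
  } else {
    # upstream on the minus strand = higher plus coordinates; the minus-sense
    # A-box end is its plus-strand start
    lo <- b_box$end + params$spacing_min + 1L
    hi <- b_box$end + params$spacing_max + wa
    hi <- min(hi, nchar(seq))
    if (hi < lo) return(empty_partners())
    window_seq <- substr(seq, lo, hi)
    window <- new_refs("w", "chromosome", window_seq)
    hits <- scan_motif(window, params$a_box_permissive, both_strands = TRUE) |>
      dplyr::filter(.data$strand == "-")
    if (!nrow(hits)) return(empty_partners())
    a_start <- hits$start + lo - 1L
    a_end <- a_start + wa - 1L
    spacing <- a_start - b_box$end - 1L
  }
  keep <- spacing >= params$spacing_min & spacing <= params$spacing_max
  a_start <- a_start[keep]; a_end <- a_end[keep]; spacing <- spacing[keep]
  if (!length(a_start)) return(empty_partners())
  stringent <- vapply(a_start, function(s) {
    matches_iupac_at(seq, s, b_box$strand, params$a_box_stringent)
  }, logical(1))
  tibble::tibble(
    a_start = a_start, a_end = a_end, strand = b_box$strand,
    spacing = spacing,
    a_box_class = ifelse(stringent, "stringent", "permissive")
  )
}

empty_partners <- function() {
  tibble::tibble(a_start = integer(0), a_end = integer(0), strand = character(0),
                 spacing = integer(0), a_box_class = character(0))
}

#' Place the +1 nucleotide relative to an A box
#'
#' The +1 lies `plus_one_offset` bp upstream of the A-box start on the box
#' strand: `a_start - offset` on the plus strand, `a_end + offset` on the
#' minus strand.
#'
#' @param a_start,a_end A-box interval (plus-strand coordinates).
#' @param strand `"+"` or `"-"`.
#' @param params A [catalog_params()] object.
#' @param ref_len Reference length; a +1 outside `[1, ref_len]` returns `NA`
#'   with a warning (the locus is dropped).
#' @return Integer +1 coordinate, or `NA`.
#' @export
assign_plus_one <- function(a_start, a_end, strand, params = catalog_params(),
                            ref_len = Inf) {
  p1 <- ifelse(strand == "+", a_start - params$plus_one_offset,
               a_end + params$plus_one_offset)
  bad <- p1 < 1L | p1 > ref_len
  if (any(bad)) {
    warning(sum(bad), " locus/loci dropped: +1 position falls outside the reference")
    p1[bad] <- NA_integer_
  }
  as.integer(p1)
}

#' Build an A/B-box target catalog by motif scanning
#'
#' Scans references for B boxes, searches each for upstream A-box partners at
#' a legal spacing, and emits one `ab_box` target per B box that has at least
#' one partner. When several partners exist the stringent one is preferred
#' (then the one nearest the spacing midpoint); ties go to the smaller
#' spacing. Solo B boxes (no partner) are recorded in the `"solo_b"`
#' attribute of the result and are not targets unless
#' `params$include_solo_b` is set.
#'
#' @param refs Reference tibble.
#' @param params A [catalog_params()] object.
#' @return Catalog tibble with columns `target_id`, `ref_id`, `plus_one`,
#'   `strand`, `target_class`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `a_box_class`, `family`, `duplicate_group`, plus a `"solo_b"` tibble
#'   attribute.
#' @export
build_ab_box_catalog <- function(refs, params = catalog_params()) {
  check_refs(refs)
  bb <- scan_motif(refs, params$b_box_motif, both_strands = params$scan_both_strands)
  rows <- list(); solo <- list()
  for (i in seq_len(nrow(bb))) {
    b <- bb[i, ]
    partners <- find_a_box_partners(refs, b, params)
    if (!nrow(partners)) {
      solo[[length(solo) + 1L]] <- b
      if (!params$include_solo_b) next
      partners <- tibble::tibble(a_start = NA_integer_, a_end = NA_integer_,
                                 strand = b$strand, spacing = NA_integer_,
                                 a_box_class = "absent")
      # no A box: anchor the +1 a midpoint-spacing upstream of the B box
      mid <- as.integer(round((params$spacing_min + params$spacing_max) / 2))
      off <- mid + nchar(params$a_box_permissive) + params$plus_one_offset
      p1 <- if (b$strand == "+") b$start - off else b$end + off
    } else {
      mid <- (params$spacing_min + params$spacing_max) / 2
      partners <- partners |>
        dplyr::arrange(dplyr::desc(.data$a_box_class == "stringent"),
                       abs(.data$spacing - mid), .data$spacing)
      partners <- partners[1, ]
      p1 <- assign_plus_one(partners$a_start, partners$a_end, b$strand, params,
                            ref_len = nchar(ref_seq(refs, b$ref_id)))
      if (is.na(p1)) next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      ref_id = b$ref_id, plus_one = as.integer(p1), strand = b$strand,
      target_class = "ab_box",
      a_start = partners$a_start, a_end = partners$a_end,
      b_start = b$start, b_end = b$end,
      a_box_class = partners$a_box_class, family = "ab_box"
    )
  }
  cat <- if (length(rows)) dplyr::bind_rows(rows) else empty_catalog()[, -1]
  if (nrow(cat)) {
    cat <- cat |>
      dplyr::arrange(.data$ref_id, .data$plus_one) |>
      dplyr::mutate(
        target_id = sprintf("abx_%s_%d_%s", .data$ref_id, .data$plus_one, ifelse(.data$strand == "+", "p", "m")),
        duplicate_group = .data$target_id,
        .before = 1
      )
  } else {
    cat <- empty_catalog()
  }
  attr(cat, "solo_b") <- if (length(solo)) dplyr::bind_rows(solo) else
    tibble::tibble(ref_id = character(0), start = integer(0), end = integer(0), strand = character(0))
  cat
}

empty_catalog <- function() {
  tibble::tibble(
    target_id = character(0), ref_id = character(0), plus_one = integer(0),
    strand = character(0), target_class = character(0),
    a_start = integer(0), a_end = integer(0),
    b_start = integer(0), b_end = integer(0),
    a_box_class = character(0), family = character(0),
    duplicate_group = character(0)
  )
}

#' Validate catalog invariants
#'
#' Checks that every target satisfies the structural invariants: +1 exactly
#' `plus_one_offset` upstream of the A-box start (when an A box is present),
#' A/B spacing within the configured bounds (when both boxes are present),
#' and legal class labels.
#'
#' @param catalog Catalog tibble.
#' @param params A [catalog_params()] object.
#' @return Invisibly `TRUE`; stops with a message naming offending targets.
#' @export
validate_catalog <- function(catalog, params = catalog_params()) {
  stopifnot(all(c("target_id", "ref_id", "plus_one", "strand", "target_class") %in% names(catalog)))
  bad <- character(0)
  ok_class <- catalog$target_class %in% c("trna", "five_s", "ab_box")
  bad <- c(bad, catalog$target_id[!ok_class])
  has_a <- !is.na(catalog$a_start)
  off <- ifelse(catalog$strand == "+",
                catalog$a_start - catalog$plus_one,
                catalog$plus_one - catalog$a_end)
  bad <- c(bad, catalog$target_id[has_a & off != params$plus_one_offset])
  both <- has_a & !is.na(catalog$b_start)
  sp <- ifelse(catalog$strand == "+",
               catalog$b_start - catalog$a_end - 1L,
               catalog$a_start - catalog$b_end - 1L)
  bad <- c(bad, catalog$target_id[both &
    (sp < params$spacing_min | sp > params$spacing_max)])
  if (length(bad)) stop("catalog invariant violations: ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Group loci that short reads cannot distinguish
#'
#' Two targets share a `duplicate_group` if and only if their upstream flanks
#' of `flank_len_for_duplicates` bases (taken on the target strand) are
#' identical strings -- e.g. mirrored loci on the two arms of the rDNA
#' palindrome, which PCR cannot discriminate.
#'
#' @param catalog Catalog tibble.
#' @param refs Reference tibble.
#' @param params A [catalog_params()] object.
#' @return The catalog with `duplicate_group` filled; grouped loci share the
#'   id `dupNN`, unambiguous loci keep their own `target_id`.
#' @export
group_duplicate_loci <- function(catalog, refs, params = catalog_params()) {
  if (!nrow(catalog)) return(catalog)
  check_refs(refs)
  fl <- params$flank_len_for_duplicates
  flank <- purrr::pmap_chr(catalog, function(ref_id, plus_one, strand, ...) {
    seq <- ref_seq(refs, ref_id)
    if (strand == "+") {
      s <- substr(seq, max(1L, plus_one - fl), plus_one - 1L)
    } else {
      s <- revcomp(substr(seq, plus_one + 1L, min(nchar(seq), plus_one + fl)))
    }
    s
  })
  grp <- match(flank, flank)  # first index with identical flank
  sizes <- table(grp)
  multi <- as.integer(names(sizes)[sizes > 1])
  gid <- catalog$target_id
  for (k in seq_along(multi)) {
    gid[grp == multi[k]] <- sprintf("dup%02d", k)
  }
  catalog$duplicate_group <- gid
  catalog
}

# ---- catalog IO --------------------------------------------------------------

interval_str <- function(s, e) ifelse(is.na(s), ".", paste0(s, "-", e))

parse_interval <- function(x) {
  s <- rep(NA_integer_, length(x)); e <- rep(NA_integer_, length(x))
  ok <- x != "." & !is.na(x)
  s[ok] <- as.integer(sub("-.*", "", x[ok]))
  e[ok] <- as.integer(sub(".*-", "", x[ok]))
  list(start = s, end = e)
}

#' Write a target catalog as BED6+
#'
#' BED columns are 0-based half-open; the BED interval spans the +1 and both
#' boxes. Extra columns carry the 1-based `plus_one` anchor, box intervals,
#' class labels and duplicate group, so [read_target_catalog()] round-trips
#' losslessly. Header comments record the coordinate and spacing conventions.
#'
#' @param catalog Catalog tibble.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_target_catalog <- function(catalog, path) {
  span_lo <- pmin(catalog$plus_one, catalog$a_start, catalog$b_start, na.rm = TRUE)
  span_hi <- pmax(catalog$plus_one, catalog$a_end, catalog$b_end, na.rm = TRUE)
  bed <- tibble::tibble(
    chrom = catalog$ref_id,
    chromStart = as.integer(span_lo) - 1L,   # 0-based half-open
    chromEnd = as.integer(span_hi),
    name = catalog$target_id,
    score = 0L,
    strand = catalog$strand,
    class = catalog$target_class,
    plus_one = catalog$plus_one,
    a_box = interval_str(catalog$a_start, catalog$a_end),
    b_box = interval_str(catalog$b_start, catalog$b_end),
    a_class = catalog$a_box_class,
    family = catalog$family,
    dup_group = catalog$duplicate_group
  )
  header <- c(
    "# treprofiler target catalog (BED6+)",
    "# coordinates: BED columns 0-based half-open; plus_one/a_box/b_box 1-based inclusive, plus strand",
    "# spacing convention: bases strictly between A-box end and B-box start on the box strand"
  )
  readr::write_lines(header, path)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read a target catalog written by [write_target_catalog()]
#'
#' @param path BED6+ catalog file.
#' @return Catalog tibble; malformed records abort with their line number.
#' @export
read_target_catalog <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) return(empty_catalog())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L)) {
    stop("malformed catalog record at line ", body[which(nf != 13L)[1]],
         ": expected 13 tab-separated fields, got ", nf[nf != 13L][1])
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(as.integer(m[, 8]))
  if (any(is.na(num))) {
    stop("malformed catalog record at line ", body[which(is.na(num))[1]],
         ": plus_one is not an integer")
  }
  if (!all(m[, 6] %in% c("+", "-"))) {
    stop("malformed catalog record at line ", body[which(!(m[, 6] %in% c("+", "-")))[1]],
         ": bad strand")
  }
  a <- parse_interval(m[, 9]); b <- parse_interval(m[, 10])
  tibble::tibble(
    target_id = m[, 4], ref_id = m[, 1], plus_one = num, strand = m[, 6],
    target_class = m[, 7], a_start = a$start, a_end = a$end,
    b_start = b$start, b_end = b$end, a_box_class = m[, 11],
    family = m[, 12], duplicate_group = m[, 13]
  )
}

#' Export a target catalog as GFF3
#'
#' Each target becomes one feature anchored at its +1; box intervals and
#' classes go into GFF attributes. Requires the rtracklayer package.
#'
#' @param catalog Catalog tibble.
#' @param path Output .gff3 file.
#' @return The path, invisibly.
#' @export
write_catalog_gff3 <- function(catalog, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("write_catalog_gff3() requires the rtracklayer and GenomicRanges packages")
  }
  span_lo <- pmin(catalog$plus_one, catalog$a_start, catalog$b_start, na.rm = TRUE)
  span_hi <- pmax(catalog$plus_one, catalog$a_end, catalog$b_end, na.rm = TRUE)
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$ref_id,
    ranges = IRanges::IRanges(start = span_lo, end = span_hi),
    strand = catalog$strand
  )
  gr$ID <- catalog$target_id
  gr$type <- "pol_III_target"
  gr$target_class <- catalog$target_class
  gr$plus_one <- catalog$plus_one
  gr$a_box <- interval_str(catalog$a_start, catalog$a_end)
  gr$b_box <- interval_str(catalog$b_start, catalog$b_end)
  gr$a_box_class <- catalog$a_box_class
  gr$duplicate_group <- catalog$duplicate_group
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Plain-text report of solo B boxes
#'
#' @param catalog Catalog returned by [build_ab_box_catalog()] (carries the
#'   `"solo_b"` attribute).
#' @param path Output text file.
#' @return The path, invisibly.
#' @export
write_solo_b_report <- function(catalog, path) {
  solo <- attr(catalog, "solo_b")
  lines <- c("# solo B boxes (no A-box partner at legal spacing); not integration targets",
             sprintf("# n = %d", if (is.null(solo)) 0L else nrow(solo)))
  if (!is.null(solo) && nrow(solo)) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", solo$ref_id, solo$start, solo$end, solo$strand))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
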