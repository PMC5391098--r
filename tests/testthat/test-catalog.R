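# Helpers to build toy loci with exact box placements.
locus_with_boxes <- function(b_start, a_instance = "TAGGCGATTAG", spacing = 45,
                             total = 200, filler = "C") {
  a_len <- nchar(a_instance)
  a_start <- b_start - spacing - a_len
  seq <- strrep(filler, total)
  seq <- paste0(substr(seq, 1, a_start - 1), a_instance,
                substr(seq, a_start + a_len, b_start - 1), "GTTCAAACC",
                substr(seq, b_start + 9, total))
  tibble::tibble(ref_id = "toy", kind = "chromosome", seq = seq)
}

test_that("find_a_box_partners honours the spacing window", {
  refs <- locus_with_boxes(b_start = 100, spacing = 45)
  b <- list(ref_id = "toy", start = 100L, end = 108L, strand = "+")
  partners <- find_a_box_partners(refs, b)
  expect_equal(nrow(partners), 1L)
  expect_equal(partners$spacing, 45L)
  expect_equal(partners$a_box_class, "permissive")

  # same A box ending only 25 bp upstream: below spacing_min
  refs2 <- locus_with_boxes(b_start = 100, spacing = 25)
  expect_equal(nrow(find_a_box_partners(refs2, b)), 0L)
})

test_that("stringent A boxes are labelled", {
  refs <- locus_with_boxes(b_start = 100, a_instance = "TGGCTTAGTTG", spacing = 45)
  b <- list(ref_id = "toy", start = 100L, end = 108L, strand = "+")
  partners <- find_a_box_partners(refs, b)
  expect_equal(partners$a_box_class, "stringent")
})

test_that("+1 placement is 7 bp upstream of the A box, mirrored on minus", {
  cp <- catalog_params()
  expect_equal(assign_plus_one(108L, 118L, "+", cp), 101L)
  expect_equal(assign_plus_one(8L, 18L, "+", cp), 1L)
  expect_equal(assign_plus_one(490L, 500L, "-", cp), 507L)
  expect_warning(p <- assign_plus_one(5L, 15L, "+", cp, ref_len = 1000),
                 "outside the reference")
  expect_true(is.na(p))
})

test_that("minus-strand +1 matches a reverse-complemented construction", {
  # build a plus-strand locus, embed its revcomp, and check mirrored arithmetic
  refs <- locus_with_boxes(b_start = 100, a_instance = "TGGCTTAGTTG", spacing = 40)
  cat_plus <- build_ab_box_catalog(refs)
  expect_equal(nrow(cat_plus), 1L)
  rc_refs <- tibble::tibble(ref_id = "toy_rc", kind = "chromosome", seq = revcomp(refs$seq))
  cat_minus <- build_ab_box_catalog(rc_refs)
  cat_minus <- cat_minus[cat_minus$strand == "-", ]
  expect_equal(nrow(cat_minus), 1L)
  L <- nchar(refs$seq)
  expect_equal(cat_minus$plus_one, L - cat_plus$plus_one + 1L)
})

test_that("build_ab_box_catalog emits targets and records solo B boxes", {
  # three B boxes: one stringent partner, one permissive partner, one solo
  l1 <- locus_with_boxes(b_start = 100, a_instance = "TGGCTTAGTTG", spacing = 40)
  l2 <- locus_with_boxes(b_start = 100, a_instance = "TAGGCGATTAG", spacing = 45)
  solo <- tibble::tibble(ref_id = "toy", kind = "chromosome",
                         seq = paste0(strrep("C", 120), "GTTCAAACC", strrep("C", 80)))
  refs <- dplyr::bind_rows(
    dplyr::mutate(l1, ref_id = "s1"), dplyr::mutate(l2, ref_id = "s2"),
    dplyr::mutate(solo, ref_id = "s3")
  )
  cat <- build_ab_box_catalog(refs)
  expect_equal(nrow(cat), 2L)
  expect_setequal(cat$a_box_class, c("stringent", "permissive"))
  expect_equal(nrow(attr(cat, "solo_b")), 1L)
  expect_equal(attr(cat, "solo_b")$ref_id, "s3")
  expect_true(validate_catalog(cat))
})

test_that("an all-N reference yields an empty catalog", {
  refs <- tibble::tibble(ref_id = "n", kind = "chromosome", seq = strrep("N", 500))
  cat <- build_ab_box_catalog(refs)
  expect_equal(nrow(cat), 0L)
})

test_that("duplicate grouping keys on identical upstream flanks", {
  g <- make_genome(sim_params(genome_len = 24000, n_trna_genes = 6,
                              palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L,
                              seed = 3), seed = 3)
  cat <- g$catalog
  # palindrome left/right twins share a group; chromosomal genes do not
  pal <- cat[cat$ref_id == "palindrome", ]
  expect_true(all(table(pal$duplicate_group) == 2L))
  chr <- cat[cat$ref_id == "chr1", ]
  expect_true(all(table(chr$duplicate_group) == 1L))

  # flanks differing at one base split the group
  refs <- tibble::tibble(ref_id = "r", kind = "chromosome",
                         seq = paste0(strrep("A", 300), "G", strrep("A", 299), "G", strrep("A", 100)))
  toy <- tibble::tibble(target_id = c("x", "y"), ref_id = "r",
                        plus_one = c(301L, 601L), strand = "+", target_class = "trna",
                        a_start = NA_integer_, a_end = NA_integer_,
                        b_start = NA_integer_, b_end = NA_integer_,
                        a_box_class = "absent", family = "f", duplicate_group = NA_character_)
  grouped <- group_duplicate_loci(toy, refs, catalog_params(flank_len_for_duplicates = 200))
  expect_equal(grouped$duplicate_group, c("dup01", "dup01"))  # identical 200-A flanks
  grouped2 <- group_duplicate_loci(toy, refs, catalog_params(flank_len_for_duplicates = 300))
  expect_false(grouped2$duplicate_group[1] == grouped2$duplicate_group[2])  # G at different offset
})

test_that("catalog BED round-trips and malformed records are rejected", {
  g <- make_genome(sim_params(genome_len = 24000, n_trna_genes = 5,
                              palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L,
                              seed = 5), seed = 5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_target_catalog(g$catalog, path)
  back <- read_target_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(g$catalog))

  bad <- withr::local_tempfile(fileext = ".bed")
  readr::write_lines(c("# header", "chr1\t10\t20\tx\t0\t+"), bad)
  expect_error(read_target_catalog(bad), "line 2")
})

test_that("GFF3 export writes one feature per target", {
  skip_if_not_installed("rtracklayer")
  g <- make_genome(sim_params(genome_len = 24000, n_trna_genes = 5,
                              palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L,
                              seed = 5), seed = 5)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_catalog_gff3(g$catalog, path)
  lines <- readr::read_lines(path)
  expect_equal(sum(!startsWith(lines, "#")), nrow(g$catalog))
})
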