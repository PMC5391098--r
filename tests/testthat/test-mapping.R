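test_that("a verbatim fragment maps uniquely with full coverage and identity", {
  refs <- random_refs(1, 5000, seed = 51)
  refs$kind <- "chromosome"
  idx <- index_references(refs)
  frag <- substr(refs$seq, 2101, 2160)
  hits <- align_fragments(tibble::tibble(read_id = "f1", genomic_part = frag), idx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2101L)
  expect_equal(hits$end, 2160L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$coverage, 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$score, 60)
})

test_that("a palindrome-arm fragment yields two equal-score mirrored hits", {
  arm <- with_seed_test(53, random_dna(3000, gc = 0.25))
  pal <- tibble::tibble(ref_id = "pal", kind = "palindrome_arm",
                        seq = paste0(arm, revcomp(arm)))
  idx <- index_references(pal)
  frag <- substr(arm, 1001, 1080)
  hits <- align_fragments(tibble::tibble(read_id = "f1", genomic_part = frag), idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(diff(range(hits$score)), 0)
  expect_setequal(hits$strand, c("+", "-"))
  L <- 6000L
  plus <- hits[hits$strand == "+", ]; minus <- hits[hits$strand == "-", ]
  expect_equal(minus$start, L - plus$end + 1L)
  expect_equal(minus$end, L - plus$start + 1L)
})

test_that("random fragments absent from the references go unmapped", {
  refs <- random_refs(1, 50000, seed = 55)
  idx <- index_references(refs)
  frags <- tibble::tibble(read_id = sprintf("r%d", 1:20),
                          genomic_part = with_seed_test(56, replicate(20, random_dna(60, gc = 0.5))))
  hits <- align_fragments(frags, idx)
  placed <- unique(hits$read_id)
  expect_lt(length(placed), 3L)  # spurious seed-chains are rare, not impossible
})

test_that("seeded best score equals the DP oracle for planted fragments", {
  refs <- random_refs(1, 4000, seed = 57)
  idx <- index_references(refs)
  with_seed_test(58, {
    for (i in 1:25) {
      flen <- sample(30:80, 1)
      s <- sample(nchar(refs$seq) - flen, 1)
      frag <- substr(refs$seq, s, s + flen - 1)
      # mutate up to 2 bases to exercise the extension path
      nmut <- sample(0:2, 1)
      if (nmut > 0) for (p in sample(5:(flen - 5), nmut)) {
        substr(frag, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(frag, p, p)), 1)
      }
      hits <- align_fragments(tibble::tibble(read_id = "x", genomic_part = frag), idx)
      expect_gt(nrow(hits), 0)
      expect_equal(max(hits$score), dp_local_best_score(frag, refs$seq),
                   tolerance = 1e-9)
    }
  })
})

test_that("accept_hits applies the second-best and coverage boundaries", {
  mk <- function(scores, coverage = 1) {
    tibble::tibble(read_id = "r", ref_id = "chr1", start = seq_along(scores) * 1000L,
                   end = seq_along(scores) * 1000L + 59L, strand = "+",
                   score = scores, q_start = 1L, q_end = 60L,
                   coverage = coverage, identity = 1)
  }
  expect_false(accept_hits(mk(c(100, 80)))$accepted)        # 80 > 75
  expect_true(accept_hits(mk(c(100, 75)))$accepted)         # boundary inclusive
  expect_true(accept_hits(mk(c(100, 75), coverage = 0.95))$accepted)  # 95% inclusive
  expect_false(accept_hits(mk(c(100, 75), coverage = 0.94))$accepted)
  expect_true(accept_hits(mk(100))$accepted)                # unique hit
  expect_false(accept_hits(mk(100, coverage = 0.90))$accepted)
  expect_equal(accept_hits(mk(integer(0))[0, ])$reason, "unmapped")
})

test_that("exact ties inside one duplicate group become a group placement", {
  two <- tibble::tibble(read_id = "r", ref_id = "palindrome",
                        start = c(18638L, 22168L), end = c(18697L, 22227L),
                        strand = c("+", "-"), score = c(100, 100),
                        q_start = 1L, q_end = 60L, coverage = 1, identity = 1)
  acc <- accept_hits(two, groups = c("dup01", "dup01"))
  expect_true(acc$accepted)
  expect_true(acc$group_placement)
  expect_equal(acc$duplicate_group, "dup01")
  # same tie across different groups stays ambiguous
  expect_false(accept_hits(two, groups = c("dup01", "dup02"))$accepted)
  expect_false(accept_hits(two)$accepted)
})

test_that("accept_hits is monotone in the second-best score", {
  with_seed_test(59, {
    for (i in 1:200) {
      best <- runif(1, 50, 150)
      s2 <- runif(1, 0, best)
      cov <- sample(c(1, 0.97, 0.9), 1)
      hits <- tibble::tibble(read_id = "r", ref_id = c("a", "b"), start = c(1L, 500L),
                             end = c(60L, 560L), strand = "+",
                             score = c(best, s2), q_start = 1L, q_end = 60L,
                             coverage = cov, identity = 1)
      acc1 <- accept_hits(hits)$accepted
      bumped <- hits; bumped$score[2] <- min(best, s2 + runif(1, 0, best - s2))
      acc2 <- accept_hits(bumped)$accepted
      expect_false(!acc1 && acc2)  # raising s2 never flips reject -> accept
    }
  })
})

test_that("placements classify into genome, plasmid and unplaced", {
  cfg <- tiny_config(seed = 61, n_events = 8, background_fraction = 0.3)
  g <- make_genome(cfg$sim, seed = 61)
  reads <- simulate_amplicons(plant_integrations(g, seed = 61), seed = 61)
  prep <- prep_reads(reads, g$element, "tdna", primers = g$primers)
  idx <- index_references(g$refs)
  mp <- map_fragments(prep$fragments, idx, g$catalog)
  joined <- dplyr::left_join(mp$placements, reads$read_map, by = "read_id")
  expect_true(all(joined$category[joined$origin == "plasmid"] == "plasmid_actin6"))
  expect_true(all(joined$category[joined$origin == "junction"] == "target_genome"))
})

test_that("error-free fragments all map to their planted coordinates", {
  cfg <- tiny_config(seed = 63, n_events = 15, background_fraction = 0)
  g <- make_genome(cfg$sim, seed = 63)
  sim <- plant_integrations(g, seed = 63)
  reads <- simulate_amplicons(sim, seed = 63)
  prep <- prep_reads(reads, g$element, "tdna", primers = g$primers)
  idx <- index_references(g$refs)
  mp <- map_fragments(prep$fragments, idx, g$catalog)
  expect_true(all(mp$placements$accepted))
  truth_by_read <- dplyr::left_join(reads$read_map, sim$truth, by = "event_id")
  pl <- dplyr::left_join(mp$placements, truth_by_read, by = "read_id")
  junction_coord <- ifelse(pl$strand.x == "+", pl$start, pl$end)
  expected <- ifelse(pl$strand.y == "+", pl$plus_one - pl$distance, pl$plus_one + pl$distance)
  expect_equal(junction_coord, expected)
})

test_that("an empty reference set is a configuration error", {
  expect_error(index_references(tibble::tibble(ref_id = character(0), kind = character(0),
                                               seq = character(0))), "empty reference")
})
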