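q_of <- function(s) strrep("?", nchar(s))

pair_from_fragment <- function(frag, read_len) {
  tibble::tibble(
    read_id = "p1",
    seq1 = substr(frag, 1, min(read_len, nchar(frag))),
    qual1 = q_of(substr(frag, 1, min(read_len, nchar(frag)))),
    seq2 = revcomp(substr(frag, max(1, nchar(frag) - read_len + 1), nchar(frag))),
    qual2 = q_of(substr(frag, max(1, nchar(frag) - read_len + 1), nchar(frag)))
  )
}

test_that("pair merging reconstructs the fragment across the overlap", {
  frag <- with_seed_test(5, random_dna(110, gc = 0.4))
  pairs <- pair_from_fragment(frag, 60)   # 10-nt exact overlap
  m <- merge_pairs(pairs)
  expect_equal(m$status, "merged")
  expect_equal(m$seq, frag)
  expect_equal(nchar(m$qual), 110L)
})

test_that("pseudoreads shorter than the length cutoff are discarded", {
  frag <- with_seed_test(6, random_dna(90, gc = 0.4))
  m <- merge_pairs(pair_from_fragment(frag, 60))
  expect_equal(m$status, "short_pseudoread")   # 90 < 100
})

test_that("disjoint reads are rejected as no_overlap", {
  pairs <- tibble::tibble(read_id = "p1",
                          seq1 = strrep("ACGT", 30), qual1 = strrep("?", 120),
                          seq2 = strrep("TTAAG", 24), qual2 = strrep("?", 120))
  expect_equal(merge_pairs(pairs)$status, "no_overlap")
})

test_that("merge consensus prefers the higher-quality base and Ns ties", {
  frag <- with_seed_test(7, random_dna(150, gc = 0.4))
  pairs <- pair_from_fragment(frag, 100)    # overlap 50: positions 51..100
  # corrupt read 1 inside the overlap with lower quality: read 2 wins
  s1 <- pairs$seq1
  substr(s1, 60, 60) <- if (substr(s1, 60, 60) == "A") "C" else "A"
  q1 <- pairs$qual1; substr(q1, 60, 60) <- "#"
  low <- merge_pairs(dplyr::mutate(pairs, seq1 = s1, qual1 = q1))
  expect_equal(low$seq, frag)
  # same corruption at equal quality: N
  tie <- merge_pairs(dplyr::mutate(pairs, seq1 = s1))
  expect_equal(substr(tie$seq, 60, 60), "N")
})

test_that("require_primer is orientation-agnostic and bounded by mismatches", {
  primer <- "ACGTACGTACGTACGTACGT"
  mk <- function(insert) tibble::tibble(read_id = "x", status = "merged",
                                        seq = paste0(strrep("T", 50), insert, strrep("A", 50)),
                                        qual = strrep("?", 100 + nchar(insert)))
  expect_equal(require_primer(mk(primer), primer)$status, "merged")
  expect_equal(require_primer(mk(revcomp(primer)), primer)$status, "merged")
  one_mm <- paste0("T", substr(primer, 2, 20))
  expect_equal(require_primer(mk(one_mm), primer)$status, "merged")
  two_mm <- paste0("TT", substr(primer, 3, 20))
  expect_equal(require_primer(mk(two_mm), primer)$status, "no_primer")
})

test_that("element trimming recovers planted truncations exactly", {
  cfg <- tiny_config(seed = 31, n_events = 12, background_fraction = 0)
  g <- make_genome(cfg$sim, seed = 31)
  sim <- plant_integrations(g, seed = 31)
  reads <- simulate_amplicons(sim, seed = 31)
  ps <- merge_pairs(reads$pairs)
  fr <- locate_and_trim_element(ps, g$element)
  expect_true(all(fr$status == "merged"))
  truth_by_read <- dplyr::left_join(reads$read_map, sim$truth, by = "event_id")
  expect_equal(fr$truncation, truth_by_read$truncation)
  # partition: element part + tail reconstruct each pseudoread exactly
  expect_equal(paste0(substr(fr$seq, 1, fr$element_len), fr$tail), fr$seq)
})

test_that("reads without element sequence are rejected with a reason", {
  g <- make_genome(tiny_config(seed = 33)$sim, seed = 33)
  ps <- tibble::tibble(read_id = "bg", status = "merged",
                       seq = substr(g$refs$seq[1], 1000, 1299),
                       qual = strrep("?", 300))
  fr <- locate_and_trim_element(ps, g$element)
  expect_equal(fr$status, "no_element")
})

test_that("a read entirely within the element yields an empty tail", {
  g <- make_genome(tiny_config(seed = 33)$sim, seed = 33)
  elem <- g$element$full_sequence
  pe <- g$element$orf1_primer_site[2]
  ps <- tibble::tibble(read_id = "orf", status = "merged",
                       seq = revcomp(substr(elem, pe - 149, pe)),
                       qual = strrep("?", 150))
  fr <- locate_and_trim_element(ps, g$element)
  expect_equal(fr$status, "merged")
  expect_equal(fr$tail, "")
  lf <- length_filter(dplyr::mutate(fr, genomic_part = fr$tail))
  expect_equal(lf$status, "short_fragment")
})

test_that("target-end trimming removes primers and adapters", {
  primer <- "GATTACAGATTACAGATTAC"
  fr <- tibble::tibble(read_id = "a", status = "merged", seq = NA_character_,
                       element_len = 10L, truncation = 0L,
                       tail = paste0(strrep("A", 60), primer))
  out <- trim_target_end(fr, "tdna", primers = tibble::tibble(target_id = "t1", primer = primer))
  expect_true(out$primer_found)
  expect_equal(out$genomic_part, strrep("A", 60))
  expect_equal(out$trimmed_primer, "t1")

  # adapter + hexamer: suffix revcomp(adapter), 6 random bases before it
  adap_tail <- paste0(strrep("G", 50), "TTTCCA", revcomp(ADAPTER_SEQ))
  fr2 <- dplyr::mutate(fr, tail = adap_tail)
  out2 <- trim_target_end(fr2, "adapter")
  expect_true(out2$primer_found)
  expect_equal(out2$genomic_part, strrep("G", 50))

  # nothing recognizable: unchanged but flagged
  fr3 <- dplyr::mutate(fr, tail = strrep("A", 80))
  out3 <- trim_target_end(fr3, "tdna", primers = tibble::tibble(target_id = "t1", primer = primer))
  expect_false(out3$primer_found)
  expect_equal(out3$genomic_part, strrep("A", 80))
})

test_that("length filter boundary is 40 nt inclusive", {
  fr <- tibble::tibble(read_id = c("a", "b", "c"), status = "merged",
                       genomic_part = c(strrep("A", 40), strrep("A", 39), ""))
  out <- length_filter(fr)
  expect_equal(out$status, c("merged", "short_fragment", "short_fragment"))
})

test_that("partition conservation holds for every retained fragment", {
  cfg <- tiny_config(seed = 35, n_events = 10, error_rate = 0.003)
  g <- make_genome(cfg$sim, seed = 35)
  reads <- simulate_amplicons(plant_integrations(g, seed = 35), seed = 35)
  prep <- prep_reads(reads, g$element, "tdna", primers = g$primers)
  fr <- prep$fragments
  primer_len <- ifelse(fr$primer_found, nchar(fr$tail) - nchar(fr$genomic_part), 0L)
  expect_true(all(fr$element_len + nchar(fr$genomic_part) + primer_len == nchar(fr$seq)))
})

test_that("higher error rates retain fewer fragments", {
  frac <- vapply(c(0, 0.02, 0.08), function(er) {
    cfg <- tiny_config(seed = 37, n_events = 25, error_rate = er, background_fraction = 0)
    g <- make_genome(cfg$sim, seed = 37)
    reads <- simulate_amplicons(plant_integrations(g, seed = 37), seed = 37)
    prep <- prep_reads(reads, g$element, "tdna", primers = g$primers)
    nrow(prep$fragments) / nrow(reads$pairs)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
  expect_equal(frac[1], 1)
})

test_that("adapter-library prep enforces the nested primer", {
  cfg <- tiny_config(seed = 39, n_events = 10, library_type = "adapter",
                     background_fraction = 0.4)
  g <- make_genome(cfg$sim, seed = 39)
  reads <- simulate_amplicons(plant_integrations(g, seed = 39), seed = 39)
  prep <- prep_reads(reads, g$element, "adapter", params = prep_params())
  st <- prep$all
  genomic_bg <- reads$read_map$read_id[reads$read_map$origin == "genomic_background"]
  expect_true(all(st$status[st$read_id %in% genomic_bg] == "no_primer"))
  junction <- reads$read_map$read_id[reads$read_map$origin == "junction"]
  expect_true(all(st$status[st$read_id %in% junction] == "merged"))
})
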