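test_that("genome generation is byte-identical under a fixed seed", {
  p <- sim_params(genome_len = 24000, n_trna_genes = 6, palindrome_arm_len = 3600,
                  n_palindrome_ab_loci = 1L, seed = 1)
  g1 <- make_genome(p, seed = 1)
  g2 <- make_genome(p, seed = 1)
  expect_identical(g1$refs$seq, g2$refs$seq)
  expect_identical(as.data.frame(g1$catalog), as.data.frame(g2$catalog))
  g3 <- make_genome(p, seed = 2)
  expect_false(identical(g1$refs$seq, g3$refs$seq))
})

test_that("full simulation is deterministic end to end", {
  cfg <- tiny_config(seed = 9, n_events = 8)
  g <- make_genome(cfg$sim, seed = 9)
  r1 <- simulate_amplicons(plant_integrations(g, seed = 9), seed = 9)
  r2 <- simulate_amplicons(plant_integrations(g, seed = 9), seed = 9)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(as.data.frame(r1$truth), as.data.frame(r2$truth))
})

test_that("planted targets are rediscovered by the motif scanner", {
  g <- make_genome(sim_params(genome_len = 24000, n_trna_genes = 6,
                              palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L,
                              seed = 4), seed = 4)
  hits <- scan_motif(g$refs, "GTTCRANNC", both_strands = TRUE)
  found <- dplyr::inner_join(g$catalog, hits,
                             by = dplyr::join_by(ref_id, b_start == start, strand))
  expect_equal(nrow(found), nrow(g$catalog))  # every planted B box recovered
  # every planted +1 is a G on the target strand
  plus1 <- purrr::pmap_chr(g$catalog, function(ref_id, plus_one, strand, ...) {
    s <- substr(g$refs$seq[match(ref_id, g$refs$ref_id)], plus_one, plus_one)
    if (strand == "-") revcomp(s) else s
  })
  expect_true(all(plus1 == "G"))
})

test_that("ab-box catalog building rediscovers palindrome loci mirror-symmetrically", {
  g <- make_genome(sim_params(genome_len = 24000, n_trna_genes = 6,
                              palindrome_arm_len = 3600, n_palindrome_ab_loci = 2L,
                              seed = 8), seed = 8)
  pal <- g$refs[g$refs$ref_id == "palindrome", ]
  built <- build_ab_box_catalog(pal)
  planted <- g$catalog[g$catalog$ref_id == "palindrome", ]
  # every planted palindrome locus (both arms) appears at its +1
  found <- dplyr::inner_join(planted, built,
                             by = dplyr::join_by(ref_id, plus_one, strand))
  expect_equal(nrow(found), nrow(planted))
})

test_that("gc_content 0 yields an A/T-only background", {
  p <- sim_params(genome_len = 24000, n_trna_genes = 6, gc_content = 0,
                  palindrome_arm_len = 3600, n_palindrome_ab_loci = 1L, seed = 2)
  g <- make_genome(p, seed = 2)
  # outside planted genes the chromosome is pure A/T; G/C appear only in the
  # planted gene bodies (boxes carry G/C by construction)
  chr <- g$refs$seq[g$refs$ref_id == "chr1"]
  cat_chr <- g$catalog[g$catalog$ref_id == "chr1", ]
  lo <- pmin(cat_chr$plus_one, cat_chr$b_start) - 60L
  hi <- pmax(cat_chr$plus_one, cat_chr$b_end) + 60L
  masked <- chr
  for (i in seq_along(lo)) {
    masked <- paste0(substr(masked, 1, lo[i] - 1), strrep("A", hi[i] - lo[i] + 1),
                     substr(masked, hi[i] + 1, nchar(masked)))
  }
  expect_false(grepl("[GC]", masked))
})

test_that("degenerate distance and forced extras propagate to the truth table", {
  cfg <- tiny_config(seed = 12, n_events = 10,
                     distance_dist = dist_fixed(47), p_extra_nt = 1,
                     extra_len_range = c(1L, 1L))
  g <- make_genome(cfg$sim, seed = 12)
  sim <- plant_integrations(g, seed = 12)
  expect_true(all(sim$truth$distance == 47L))
  expect_true(all(nchar(sim$truth$extras) == 1L))
})

test_that("element orientation: the element 5' end is junction-proximal", {
  cfg <- tiny_config(seed = 14, n_events = 6, p_truncation = 0, p_extra_nt = 0)
  g <- make_genome(cfg$sim, seed = 14)
  sim <- plant_integrations(g, seed = 14)
  elem <- g$element$full_sequence
  for (e in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[e, ]
    hap <- sim$refs$seq[sim$refs$ref_id == tr$hap_id]
    refseq <- ref_seq(g$refs, tr$ref_id)
    # gene-sense: [element 5' terminus][gap of d bases][+1 ...]
    gene_sense_block <- paste0(revcomp(substr(elem, 1, 30)))
    probe <- if (tr$strand == "+") {
      paste0(gene_sense_block,
             substr(refseq, tr$plus_one - tr$distance, tr$plus_one))
    } else {
      revcomp(paste0(gene_sense_block,
                     revcomp(substr(refseq, tr$plus_one, tr$plus_one + tr$distance))))
    }
    expect_true(grepl(probe, hap, fixed = TRUE), label = paste("event", tr$event_id))
  }
})

test_that("error-free junction reads are exact substrings of their haplotype", {
  cfg <- tiny_config(seed = 16, n_events = 8, background_fraction = 0)
  g <- make_genome(cfg$sim, seed = 16)
  sim <- plant_integrations(g, seed = 16)
  reads <- simulate_amplicons(sim, seed = 16)
  for (i in seq_len(nrow(reads$pairs))) {
    ev <- reads$read_map$event_id[i]
    hap <- sim$refs$seq[sim$refs$ref_id == sim$truth$hap_id[sim$truth$event_id == ev]]
    r1 <- reads$pairs$seq1[i]
    hapc <- paste0(hap, "|", revcomp(hap))
    expect_true(grepl(r1, hapc, fixed = TRUE) || grepl(revcomp(r1), hapc, fixed = TRUE))
  }
})

test_that("background fraction controls the share of background pairs", {
  cfg <- tiny_config(seed = 18, n_events = 12, background_fraction = 0.5)
  g <- make_genome(cfg$sim, seed = 18)
  reads <- simulate_amplicons(plant_integrations(g, seed = 18), seed = 18)
  n_bg <- sum(reads$pairs$origin != "junction")
  n_j <- sum(reads$pairs$origin == "junction")
  expect_equal(n_bg, round(n_j * 0.5 / 0.5))
})

test_that("truth distances follow the configured distribution (chi-square)", {
  d <- with_seed_test(77, sample_distances(dist_gaussian(), 10000))
  pmf <- distance_pmf(dist_gaussian())
  # pool support into bins with expected counts >= 5
  obs <- table(factor(d, levels = pmf$distance))
  expc <- pmf$prob * length(d)
  pool <- expc >= 5
  obs2 <- c(as.numeric(obs[pool]), sum(obs[!pool]))
  exp2 <- c(expc[pool], sum(expc[!pool]))
  pval <- stats::chisq.test(obs2, p = exp2 / sum(exp2))$p.value
  expect_gt(pval, 0.01)
  # and the planted truth table uses the same sampler
  cfg <- tiny_config(seed = 19, n_events = 400)
  g <- make_genome(cfg$sim, seed = 19)
  tr <- plant_integrations(g, seed = 19)$truth
  expect_true(all(tr$distance >= 23 & tr$distance <= 181))
  expect_lt(abs(mean(tr$distance) - 47), 1)
})

test_that("fastq and truth round-trip through files", {
  cfg <- tiny_config(seed = 21, n_events = 5)
  g <- make_genome(cfg$sim, seed = 21)
  reads <- simulate_amplicons(plant_integrations(g, seed = 21), seed = 21)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_equal(back$seq1, reads$pairs$seq1)
  expect_equal(back$qual2, reads$pairs$qual2)

  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_truth(reads$truth, tpath, seed = 21)
  tback <- read_truth(tpath)
  expect_equal(tback$distance, reads$truth$distance)
  expect_equal(tback$extras, reads$truth$extras)

  fpath <- withr::local_tempfile(fileext = ".fasta")
  write_refs_fasta(g$refs, fpath)
  rback <- read_refs_fasta(fpath)
  expect_equal(rback$seq, g$refs$seq)
  expect_equal(rback$kind, g$refs$kind)
})
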