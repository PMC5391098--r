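---
title: "Models and methods behind treprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind treprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

treprofiler turns paired-end LAM-PCR amplicon reads into per-locus
retrotransposon integration calls at RNA polymerase III genes. This
vignette describes the underlying models, the conventions and numerical
choices the implementation commits to, what the synthetic-data generator
does and does not emulate, and the package's known limits.

## Coordinates and conventions

All coordinates are 1-based, both ends inclusive, on the plus strand of the
reference; only BED output converts to 0-based half-open at the boundary.
Three conventions recur throughout and are worth stating once:

* **A/B-box spacing** is the number of bases strictly between the last base
  of the A box and the first base of the B box, on the box strand. The
  literature quotes functional spacings of 30–60 bp without defining the
  measurement endpoints; this package picks the strictly-between convention,
  records it in every catalog header, and exposes the bounds
  (`catalog_params(spacing_min, spacing_max)`) so alternative conventions
  remain comparable.
* **+1 placement.** The first transcribed nucleotide sits
  `plus_one_offset = 7` bp upstream of the A-box start (the A box is fixed
  at +8 of the mature transcript). On the minus strand the arithmetic
  mirrors: `+1 = a_box_end + 7`.
* **Integration distance** is the count of bases strictly between the
  element's 5'-terminal nucleotide and the target's +1. Non-templated extra
  nucleotides are element-side (they arrive with the cDNA) and are
  *excluded* from the distance; target-site-duplication bases are genomic
  and count. A junction figure showing an element "46 bp upstream" of a
  gene therefore corresponds to distance 46 here. Because published
  distances never state whether extras or TSD bases were counted, calls
  under a different convention may differ by 1–2 bp from externally
  reported values; within the package the convention is exactly
  self-consistent (plant at *d* ⇒ call *d*, verified for every
  *d* in 23–181).

## Target catalog

B boxes are found by scanning the IUPAC motif `GTTCRANNC` (both strands;
overlapping matches all reported; an `N` in the reference conservatively
fails every non-N motif position). For each B box, permissive A-box matches
(`TNNNNNANNNG`) upstream at legal spacing are collected and labelled
stringent when they also match `TRRYNNARYNG`. One `ab_box` target is
emitted per B box with at least one partner — the stringent partner is
preferred, then the partner nearest the spacing midpoint, ties to the
smaller spacing. Solo B boxes are catalogued separately but are *not*
targets by default: an isolated B box binds TFIIIC but assembles a full
transcription complex poorly and is a correspondingly poor integration
target. `catalog_params(include_solo_b = TRUE)` promotes them for
sensitivity analyses.

Loci whose upstream flanks of `flank_len_for_duplicates = 200` bp are
identical strings are merged into one *duplicate group*: no 300-bp read can
tell them apart, exactly as mirrored positions on the two arms of the rDNA
palindrome (or its internally duplicated segments) cannot be distinguished
by PCR. Downstream, events are keyed by duplicate group, so a call at a
mirrored locus is reported once, at the group.

## Read preparation

Pairs merge across their best overlap (longest acceptable overlap of at
least `min_overlap = 10` nt with mismatch rate at most 0.1), consensus
taking the higher-quality base. At *equal-quality* conflicts the consensus
base becomes `N`, and a fragment whose junction-critical zone (the last two
element bases and the first six tail bases) contains an `N` is dropped as
`ambiguous_junction`: those positions determine the event key (truncation,
extras, distance), and a read that cannot resolve them reliably should not
vote. With error-free input this policy is a no-op. Merged pseudoreads
shorter than `min_pseudoread_len = 100` nt are discarded, matching the
profiling pipeline's cutoff; after element and primer/adapter trimming,
fragments with genomic parts shorter than `min_trimmed_len = 40` nt are
discarded to avoid imprecise mapping in A+T-rich intergenic DNA (both
boundaries inclusive: 40 is kept).

The element part is located by local alignment against the element model
(match +1, mismatch −1, gap open 2, gap extend 1; at least
`element_min_match_len = 20` aligned nt at ≤ 10% divergence). Element
position 1 is the first base of the retained 42-bp 5'-UTR, so the distance
from position 1 to the 5'-most aligned element base *is* the truncation.
An exact longest-common-prefix fast path handles intact reads (the amplicon
always begins at the LAM primer end); a short look-ahead detects
substitution bridges and falls back to full alignment, so the fast path
never changes a result, only the time to reach it. Bases between the
element match and the eventual genomic alignment cannot be attributed at
this stage — only genome alignment can say which side they belong to — so
extras resolution is deferred to integration calling.

Primer matching (nested primer requirement in the adapter library; tDNA
primer and adapter trimming) tolerates `primer_max_mismatches = 1`
substitution by default; the source pipelines do not state a tolerance, so
exact matching is available by configuration.

## Junction mapping and hit acceptance

The aligner is seed-and-extend: exact 11-mers of the fragment (both
orientations, sampled every 4 positions plus the terminal position) are
looked up in a reference index, clustered by diagonal (gap tolerance
15 bp), and each cluster window (±40 bp padding) is extended by local
alignment under the declared scoring. Clusters need at least two seeds —
singleton 11-mer hits in A+T-rich DNA are overwhelmingly spurious — except
for queries under 50 nt, where one mismatch can leave only a single clean
seed. A single-diagonal cluster whose window reproduces the query verbatim
shortcuts to an exact placement with the identical score the alignment
would produce.

Acceptance implements the published filter with both boundaries read
inclusively: "the second-best score should not exceed 75% of the best"
becomes `s2 <= 0.75 * s1`, and "at least 95% of its length" becomes
`coverage >= 0.95`. The published wording lists the coverage rule only
under multi-hits; it is applied to unique hits as well by default
(`map_params(apply_coverage_to_unique = FALSE)` restores the literal
reading). Score ties confined to one duplicate group are treated as an
extension of the unique-hit rule — a unique hit *on the group* — mirroring
how mirrored palindrome loci are reported as a pair. Because the 75% rule
operates on whatever score the aligner reports, the ratio is
scheme-relative: changing match/mismatch/gap scores changes which second
hits pass. The scheme is therefore part of the declared parameter set, not
a hidden constant.

## Integration calling

Fragments are stored junction-first (the gene's 5'→3' sense), so the first
aligned base of an accepted placement is the genomic base adjacent to the
element 5' terminus: the junction. Unaligned fragment prefix bases are the
resolved extras. The junction is assigned to the nearest catalog target
downstream on the facing strand (orientation-specific integration; the
element 5' end faces the target 5' end), within
`max_assign_distance = 250` bp — comfortably above the observed 23–181 bp
integration window while rejecting junctions that no plausible target
explains. Events deduplicate by (duplicate group, distance, truncation,
extras); single-read events are retained but flagged, since read support
cannot distinguish PCR amplification from independent insertions.

## The synthetic-data generator

The generator is the package's study stand-in and its defaults are the
study conditions: an A+T-rich background (GC 0.25), 40 tRNA genes (eight
families) on a 100-kb chromosome, each gene built as +1 G, A box at +8
(a stringent-consensus instance), a sampled 32–57 bp spacer, a B box
instance, tail and T₅ terminator; a mirror-symmetric palindrome
(arm + reverse-complemented arm) carrying A/B-box loci and a 5S-like gene
on both arms; and a plasmid reference holding the transformed element
behind its promoter context. Insertion distances come from an integer
Gaussian centred at 47 bp (sd 2) truncated to 23–181 bp; 25% of insertions
carry a geometric 5' truncation; half carry 1–3 non-templated extras; TSDs
are 0–15 bp (lengths are not published; the range is configurable);
amplicons follow the LAM geometry (element part to the LAM primer at
element position 250, then extras, gap, and either the tDNA primer site or
a random adapter-ligated position); reads are 300 bp at constant Q30 with
uniform substitution errors; background pairs are half plasmid/promoter
fragments (testing the promoter-category classifier) and half unrelated
genome.

Three generator choices deserve explanation:

* **Per-event haplotypes.** Events come from independent cells, so each
  planted insertion mutates its own allele window rather than one shared
  genome; reads are exact substrings of their haplotype, and multiple
  events at one target never interfere.
* **Unambiguous junctions.** An extra nucleotide identical to the adjacent
  genomic base, or to the next truncated element base, is *undetectable in
  principle* — any observer would attribute it to the other side. The
  generator therefore only plants extras that are anti-matched to the bases
  a leftward genome-alignment extension would pair them with, and only
  truncations whose element-side extension walk scores at most −1 at every
  prefix. The second condition is deliberately one notch stronger than
  needed for error-free data: a merge conflict masks a base to `N` (worth
  −0.5 instead of −1 to the aligner), and the −1 margin keeps even a masked
  junction from making an extension profitable. This is what makes exact
  truth recovery a fair test of the caller rather than of junction
  ambiguity.
* **Distinguishable genes by default.** Each tRNA gene gets its own
  internal sequence (families are labels); `share_family_sequence = TRUE`
  emulates identical family copies, in which case short-distance fragments
  correctly fail the 75% second-best rule — useful for studying the
  filter, hostile to recovery benchmarks.

What the generator does *not* emulate, and what passing tests therefore do
not show: PCR chimeras between the promoter context and genomic DNA (real
adapter libraries contain many; here background reads are simple plasmid
fragments), amplification bias beyond a uniform 1–5 reads per event (the
observed hot-spot bias is attributed to PCR or clonal expansion without a
model, so none is simulated), quality-score structure (constant Q30),
indel sequencing errors, and natural (untagged) element copies in the
genome.

## Problem sizes and numerical checks

The test suite runs at desk scale by the package's own choice: the
truth-recovery check uses 500 error-free events on the default 100-kb
genome plus a per-distance sweep over the full 23–181 bp range; motif
scanning is cross-checked against an independent regular-expression oracle
on 1,000 random 2-kb sequences with the B-box density compared to its
analytic expectation ((1/4)⁶·(1/2) per strand-position) within three
standard errors; the seeded aligner is compared to an independent
full-dynamic-programming local aligner (vectorised Gotoh) on 200 random
mutated fragments; acceptance boundaries and monotonicity run on 1,000
randomised hit lists; and a fixed-seed regression holds recall ≥ 0.95 and
precision ≥ 0.99 at a 0.5% substitution rate. `scripts/acceptance.R`
re-runs the default pipeline from scratch and writes the headline
quantities as JSON.

## Limitations

Chimeric fragments are rejected, not split-aligned. Hot-spot significance
is summarised (loci above the uniform expectation and their read share)
but not tested — no model for the bias exists. The displayed hot-spot
average is rounded to an integer while the exact value is kept internally.
Events keyed identically across duplicate-group members are inherently
unresolvable and are reported at the group. Whether the genome-wide B-box
count should include both strands is not settled in the source material;
`scan_motif` reports per-strand counts so either convention can be formed.
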