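---
title: "Simulating and diagnosing ChIP-exo protocol variants"
author: "chipexosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing ChIP-exo protocol variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipexosim)
```

## The problem this package models

ChIP-exo assays digest sonicated, formaldehyde-crosslinked chromatin with
lambda exonuclease, which chews 5'→3' until it halts at a protein-DNA
crosslink. The 5' end of Read_1 therefore marks the exonuclease *stop
site*, a near-base-pair signature of where the protein sat. The many ways
of building these libraries differ in mechanisms that leave distinct,
diagnosable fingerprints in the sequenced tags:

* **Shouldering** — molecules that escape digestion keep their sonication
  5' ends and look like ChIP-seq signal hundreds of bp from the site.
* **Tn5 tagmentation bias** — transposase-built libraries inherit the
  enzyme's sequence preference at its 19-bp recognition window, visible in
  Read_2 5'-end base composition, and react preferentially with longer
  molecules, shifting the insert-size distribution upward.
* **Carryover** — spent transposase holds cut sub-fragments noncovalently,
  so tag 5' ends appear on both strands downstream of the crosslink and
  the clean blue/red strand partition around a motif degrades.
* **Barcode erosion** — ChIP-nexus reads start with a 5-nt random barcode
  plus a fixed `CTGA` spacer (positions 6–9 of Read_1); over-active
  3'→5' end-polishing erodes the spacer from its genomic-proximal end
  (A, then G, T, C), frame-shifting the read so it fails the barcode
  filter.
* **Pentamer displacement** — single-stranded-ligation libraries that
  begin Read_1 with a random pentamer make the mapped stop site appear
  5 bp more 5' than it is.

`chipexosim` simulates each mechanism from first principles on synthetic
genomes with planted motifs, carrying ground truth through to every
record, and implements the diagnostics that expose the fingerprints:
strand-separated motif-anchored profiling, nucleotide-frequency bias
calling, barcode QC, insert-size statistics, and duplicate-rate
accounting. Because simulated records carry truth coordinates, every
diagnostic can be validated exactly, with no alignment step in between.

## The generative model

A library is simulated in four stages, all driven by one seeded generator
in a fixed order (`simulate_library()`):

**1. Sonication and immunoprecipitation** (`simulate_fragments()`).
Fragment sizes follow a lognormal parameterized by its mode (default 180
bp) and SD (default 80 bp), truncated to 100–500 bp — truncation by
redraw, so no probability mass piles on the range boundaries. Each
fragment is site-derived with probability

$$P(\text{site}) = \frac{(1-b)\,E}{(1-b)\,E + b},$$

where $b$ (`background_frac`, default 0.985) is the crosslink-free
fraction of input chromatin and $E$ (`enrichment`, default 12) the
immunoprecipitation weight of crosslinked molecules. The defaults give a
motif-proximal read fraction around 15%, typical of a well-behaved
factor IP. Site fragments cover the motif midpoint and carry one
crosslink per strand at midpoint ∓ `crosslink_offset`; background
fragments are placed uniformly, avoiding sites.

**2. Digestion geometry** (`exo_process()`). One strand is digested per
molecule (uniform over the crosslinks present). With probability
`1 - p_shoulder` the Read_1 5' end is `crosslink - stop_offset` (plus
strand; mirrored on minus); otherwise digestion fails and the sonication
end is kept. Read_2 is always the opposite sonication end. The defaults
`crosslink_offset = 8`, `stop_offset = 6` are package choices — the
figures this mimics show stop-site stripes but print no offsets — and
place the outer stop peaks at ±14 bp. A fraction `p_inner` (default
0.25) of site molecules crosslink at the motif midpoint instead, creating
the inner, secondary stop; these enter the library only with probability
`p_inner_ligation`, which is low (0.10) in the 4.x single-stranded
ligation versions to reproduce their missing inner peak — a mechanism
chosen here as per-stop ligation efficiency; the underlying biology is
unresolved. `p_shoulder` defaults encode the observed protocol ranking:
0.10 for versions 1.1/5.0/nexus, 0.40 for 3.1/4.x.

**3. Tagmentation** (`tagment()`, versions `mentation` and `exo3.1`).
A fragment of length $L$ reacts with probability $1-(1-p)^L$
(`p_tagment_per_bp`, default 0.004), which is what biases tagmented
libraries toward longer inserts; unreacted fragments carry no adapter and
are dropped. The cut position is drawn proportional to a 19-bp
position-weight matrix match score (the transposase recognition window;
the default matrix carries a strong synthetic core preference).
Sonication boundaries are kept on the record — the spent transposase
holds the cut molecule together through library construction — while the
cut determines where Read_2 *sequencing* begins, so Read_2 5'-end base
composition carries the Tn5 preference. This deliberately decouples the
Read_2 truth coordinate (sonication end) from the Read_2 sequence anchor
(cut site) — a modelling simplification that keeps insert-size truth and
sequence bias simultaneously faithful to what the protocols show. With
probability `p_carry` (default 0.15 for ChIPmentation, 0 for 3.1, whose
chaotropic washes strip the transposase) the distal sub-fragment is also
sequenced, emitting interior tag ends of both strands — the mechanism
that erodes the strand-segregation score. The 0.15 default keeps the net
insert-size shift positive, as observed in tagmentation libraries, while
producing a clearly measurable segregation decrease.

**4. Barcodes, displacement and PCR** (`apply_barcode_scheme()`,
`pcr_duplicate()`). ChIP-nexus Read_1 = 5 random nt + `CTGA` + genomic
sequence from the stop site; with probability `p_overtrim` a geometric
depth `k ≤ 4` of spacer bases is eroded in the order A, G, T, C and the
read frame-shifts. A trimmed read whose first genomic base happens to be
`A` recreates the spacer and silently passes the filter, exactly as a
real frame-shifted read would — the barcode filter's truth relationship
is therefore one-sided (all untrimmed reads pass; all failing reads are
trimmed). Version 4.0 prepends the random pentamer and displaces the
mapped coordinate 5 bp in the read's 5' direction. Each molecule is then
amplified `1 + Poisson(dup_mean - 1)` times (the duplication model is a
package choice); copies are byte-identical in both sequences, matching
the sequence-identity definition of PCR duplicates used downstream.

## Diagnostics

* `dedupe()` removes duplicates by identical Read_1+Read_2 sequences (the
  canonical definition) or by coordinate/strand pairs, keeping the first
  record of each class.
* `nt_freq()` / `call_bias()` profile 5'-proximal base composition and
  flag a nucleotide wherever its frequency strictly exceeds
  `background × (1 + margin)`. The margin is **relative**: with the
  yeast-like background of A/T 31% and G/C 19% and the default 10%
  margin, the displayed thresholds round to >34% and >21%. The rule is
  evaluated unrounded; only the display rounds. Flag sets are summarized
  as an IUPAC string.
* `nexus_filter()` / `barcode_qc()` apply the positions-6–9 `CTGA` test
  and profile the passing and failing partitions; the failing partition's
  spacer-base presence (C@6 ≥ T@7 ≥ G@8 ≥ A@9) is reported directly so
  progressive erosion is a one-line check.
* `insert_sizes()` / `insert_mode_sd()` compute outer-span inserts
  (rightmost covered base − leftmost + 1 from the two 5' ends; the
  convention matches the usual paired-end "insert size"; a 5'-to-5'
  reading would differ by one read length) and summarize them as mode ±
  population SD, the mode being the smallest most-frequent integer size.
* `anchor_matrix()` bins tag 5' ends at motif-relative offsets,
  stratified by tag strand *relative to the motif strand*; minus-strand
  sites flip the offset axis. The midpoint convention is
  `start + floor(width/2)` (right-of-center for even widths); tags near
  two sites count at each (pileup semantics). `composite()`,
  `peak_offsets()`, `peak_shift()`, `shoulder_fraction()` and
  `strand_segregation_score()` reduce the matrices to the comparison
  metrics; `sort_rows()` computes one linked row order (reference-dataset
  or average-rank) applied to every heatmap.

## What the synthetic data does and does not emulate

The generator reproduces: base composition (A/T 31%, G/C 19%), oriented
motif anchors, 100–500 bp sonication spans, 2 × 40 bp paired reads,
version-specific 5'-end geometry and barcodes, shouldering, Tn5
preference/length-bias/carryover, and sequence-identical PCR duplicates.

It does not emulate: degenerate motif instances (planted sites are exact
text — the default motif is chosen so that this artificial homogeneity
does not register as 5'-end chemistry bias at the default site fraction;
with much higher enrichment values a real pipeline *would* see motif
letters in the profile and so does this one), base-call errors,
mappability, chromatin structure beyond motif placement, or real genome
sequence. Passing tests therefore validate the analysis logic and the
mechanistic directions of the protocol differences, not quantitative
agreement with any particular deposited dataset.

## Numerical choices and degenerate inputs

* Ties in `peak_offsets()` break toward the smaller |offset|, then the
  negative one; an all-zero stratum reports an absent peak (`NA`) rather
  than a fabricated one, and downstream shift computations refuse absent
  peaks.
* `insert_mode_sd()` is the raw integer argmax. For broad size
  distributions (sonication SD 80 bp) the argmax of ~50k draws wanders
  over tens of bp because the density is nearly flat at the top; the
  package's parameter-recovery tests therefore use a narrow (SD 10 bp)
  size distribution to validate the statistic itself. Treat the reported
  mode of a broad library as having comparable uncertainty.
* `call_bias()` at small read counts is noisy: at n = 1000 reads the
  per-position SE (~1.5 points) approaches the G/C margin (1.9 points).
  The package's null-behavior guarantees are stated at n = 50,000, where
  the margin dominates sampling noise.
* Offset-0 tags split evenly between the upstream and downstream terms of
  the segregation score, keeping the statistic antisymmetric.
* Zero-coverage profile positions are excluded (NA), never imputed.
* Fragments whose reads would cross a genome edge are dropped (counted in
  the metadata); sites too close to an edge for the configured geometry
  are a placement error.

## Problem sizes

The shipped tests and the acceptance script simulate libraries of
10,000–50,000 fragments over a 600 kb genome with 200 planted sites —
sizes at which every stochastic check has at least 3-SE headroom while a
full run stays in the minutes range on one core. All simulations are
deterministic under their configured seed.

## A worked run

```{r example, eval = FALSE}
g <- generate_genome(6e5, seed = 11)
p <- plant_motifs(g, default_motif(), n_sites = 200,
                  min_spacing = 1500, seed = 12)

lib50 <- simulate_library(p$sequence, p$sites,
                          sim_config("exo5.0", n_fragments = 50000,
                                     seed = 101))
lib40 <- simulate_library(p$sequence, p$sites,
                          sim_config("exo4.0", n_fragments = 50000,
                                     seed = 101))

ends <- five_prime_ends(dedupe(lib50$tags), "read1")
m50 <- anchor_matrix(ends, p$sites, window = 500)
peak_offsets(composite(m50))       # same -14, opposite +14
m40 <- anchor_matrix(five_prime_ends(dedupe(lib40$tags), "read1"),
                     p$sites, window = 500)
peak_shift(composite(m40), composite(m50))$mean_abs  # 5 bp

run_qc(lib50$tags)
```
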