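---
title: "Methods: codon composition, 5'-mRNA folding and host fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon composition, 5'-mRNA folding and host fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfit)
```

## The scientific problem

When a bacterium acquires a gene horizontally, the donor's synonymous-codon
spelling meets the host's translation machinery and the host's 5'
untranslated region. Two codon-level properties can then decide whether the
transfer helps or hurts: *codon optimality* (how well the gene's codons
match the host's tRNA pool and usage preferences) and the *folding
stability of the 5'-end mRNA* (a stable hairpin across the ribosome-binding
region suppresses translation initiation). `codonfit` implements an
analysis pipeline for an experimental design that isolates these effects:
a combinatorial library of synonymous variants of an essential
antibiotic-target gene (dihydrofolate reductase, the target of
trimethoprim), integrated into the host chromosome behind the host's own
regulatory region, competed through serial passages across a range of
sub-inhibitory drug concentrations, and read out by deep sequencing of the
variant frequencies.

The pipeline covers: codon-optimality scores, minimum-free-energy folding
profiles of the 5' transcript, library enumeration and read counting,
enrichment statistics (log2 fold-change fitness proxies, population mean
fitness, Shannon diversity), feature-fitness rank associations,
growth-curve and IC50 phenotyping, a Moran-process competition simulator,
and a synthetic-data generator that stands in for the wet-lab experiment.

## Coordinates and sequence conventions

Transcript positions follow the biological convention with no position 0:
`+1` is the first CDS nucleotide and transcription starts at `-25` by
default (the host folA arrangement), so a slice from `-25` to `+5` is
exactly 30 nt. RNA input (`U`) is accepted everywhere and stored as DNA
(`T`). All internal storage is 0-based with the bijection confined to
`tx_slice()`.

## Codon-optimality scores

* **CAI.** `relative_adaptiveness()` turns reference codon counts into
  weights `w_c = count_c / max(family counts)`, so every synonymous family
  has maximum weight exactly 1. Zero counts receive a 0.5 pseudocount
  before normalization to keep the geometric mean finite. `gene_score()`
  on the CAI scale excludes ATG, TGG and stops (codons without synonymous
  freedom), the standard convention for this index.
* **tAI.** `tai_weights()` computes absolute adaptiveness
  `W_c = sum (1 - s_ij) * tGCN_ij` over the Watson-Crick anticodon plus
  the standard wobble anticodon for the codon's third base, with the
  published prokaryotic selective constraints
  (`s`: Watson-Crick 0, G34:U 0.41, I34:C 0.28, I34:A 0.9999, U34:G 0.68;
  editable via the `s_values` argument, and the tGCN table is a plain TSV
  so donor-specific pools can be loaded). Codons with no decoding
  capacity get the geometric mean of the nonzero weights. The gene score
  excludes stop codons only.

Both gene-level scores are geometric means, hence order-invariant and in
(0, 1].

## Folding engine

`mfe()` computes the minimum free energy over non-pseudoknotted secondary
structures by a Zuker-style dynamic program with an explicit, simplified
nearest-neighbor model: a 6x6 helix-stacking table over pair types
(AU/UA/CG/GC/GU/UG, kcal/mol, 37 °C), logarithmic hairpin and
interior/bulge loop penalties (minimum hairpin loop 3 nt, interior loops
capped at 12 nt), and an affine multiloop cost. The parameter table is data
(`folding_params()`), shared verbatim with `mfe_enumerate()`, an
exhaustive enumerator over all structures that scores each explicit pair
set by loop decomposition. The two implementations are algorithmically
independent and are required to agree exactly on short sequences - this is
the engine's primary correctness check.

Absolute energies from the simplified model differ from full
Turner-parameter tools; every downstream use here is comparative (window
profiles, ORG-MOD differences, rank correlations), which is robust to a
consistent engine. An external tool can be plugged in through
`folding_engine()` (same contract, its id recorded in every profile).

Profiles: `window_profile()` slides a 30-nt window (a ribosome footprint)
in 1-nt steps from the transcription start; 100 windows is the whole-gene
default, 110 the library-construct default. `fragment_dg()` folds one
contiguous fragment, default `-25..+120` (145 nt, covering diversified
codons 1-30); `-25..+90` is supported by argument since both extents are
in common use, and no claim is made that either is canonical.
`ddg_profile()` reports `dG_MOD - dG_ORG` per window; negative values mean
the frequent-codon recoding overstabilized the 5' end.

## Libraries and counting

A `variant_library` is defined by a synonymous ORG/MOD pair and a
diversified codon interval (1-15 or 16-30); variants are bitmasks over the
differing positions, with `"M"`/`"O"` aliases for the all-MOD/all-ORG
sequences. Any non-synonymous ORG/MOD difference is an error naming the
codon. Read assignment is exact-match over the diversified region after
discarding reads shorter than the expected length; no mismatch tolerance
is allowed because library variants differ at single positions, so a
1-error correction could silently mis-assign. Counts are conserved:
assigned + unassigned + discarded equals input reads.

## Enrichment statistics

Frequencies are `f_i = n_i / N` per (timepoint, condition). Fitness
proxies are `FC_day1 = f(day1)/f(day0)` and `FC_day2 = f(day2)/f(day1)`,
reported as log2. Variants with zero reads at both timepoints of a passage
are excluded; if any included variant has a single-timepoint zero, a 0.5
pseudocount is added to every included count, which keeps fold changes
finite and preserves ranks.

Population mean fitness is the frequency-weighted mean enrichment
`w-bar = sum f_i(current day) * FC_i`, defined as 1 at day 0. Weighting by
the *current* day is a deliberate choice: weighting by the baseline day
collapses the sum to 1 identically (`sum f0 * f1/f0 = sum f1 = 1`) and
could not register any selection response. Under current-day weighting
`w-bar >= 1` within a passage (Cauchy-Schwarz), so it measures the
sharpening of the frequency distribution. Shannon diversity is
`H = -sum p ln p` in nats, normalized to the naive (day 0) library.

## Associations

Spearman rank tests (exact permutation p for n <= 9, t-approximation
otherwise) relate log2(FC) to CAIg, tAIg, GC content, fragment dG and
per-window dG. Constant inputs (e.g. windows that no diversified codon
touches) return an NA error state rather than an exception so window
sweeps can proceed. Raw per-window p-values are the primary output,
matching how such profiles are usually read; a Benjamini-Hochberg column
is emitted alongside. Windows whose dG is a deterministic function of the
same causal codon choice tie exactly in rank correlation; rankings should
therefore be read with a tie tolerance, as the bundled tests do.

## Growth and dose-response

Growth is quantified by the trapezoidal AUC of OD over 0-15 h (no
extrapolation). Curves are fit to the modified Gompertz model
(`od0 + A exp(-exp(mu*e/A (lag - t) + 1))`) - a standard bacterial growth
model chosen here for its interpretable rate/lag/asymptote parameters -
with slope start values estimated over ~1-h spans (10-min sampling makes
point-to-point slopes too noisy) and the best-RSS fit over a small start
grid retained; flat curves yield a flagged non-convergent record.
Dose-response: AUCs normalized by the no-drug AUC are fit to
`g(c) = 1/(1 + (c/IC50)^h)` with free Hill slope; `g(IC50) = 0.5` by
construction, and monotone-increasing growth with dose is flagged
unreliable rather than summarized by an IC50.

Polysome engagement: per fraction the relative transcript abundance is
`2^(-dCt)` with `dCt = Ct(target) - Ct(reference)`; the reported statistic
is `log2(polysomal/total) = dCt_total - dCt_polysomal`, positive when the
transcript is more engaged with polysomes.

## Competition simulator

`simulate_moran()` is a generation-synchronous Moran-type simulator:
offspring are drawn multinomially with probabilities proportional to
`n_i * w_i`; dilutions are exact multivariate-hypergeometric downsampling
(without replacement). The census grows each generation by a factor chosen
so the population reaches the cap at the next bottleneck -
`(n_cap/n_init)^(1/12)` for the initial phase (1e6 to 1e8 cells over 12
generations), then `dilution_factor^(1/dilution_every)` for each
subsequent 1/100-dilution/6-generation cycle. A fixed growth factor across
both phases would make the census decay tenfold per cycle, so the
per-cycle factor is the only self-consistent reading of the protocol. A
`deterministic` mode (expected counts, real-valued) is available for
sensitivity analysis. The properties validated - selection response
matching the replicator recursion at large N, neutral frequency
conservation, bottleneck drift, the inverse coupling of mean fitness and
diversity, insensitivity to initial-frequency bias - are properties of
fitness-proportional sampling plus downsampling, not of per-cell event
granularity; the engine id is recorded in trajectories.

## The synthetic-data generator

`gen_weight_tables()` draws internally consistent CAI/tAI tables; with
`gc_bias > 0.5`, G/C-ending codons are more frequent and their anticodons
more abundant, reproducing the optimality-stability collinearity of
GC-rich genomes (stable mRNA needs G/C, frequent codons end in G/C). With
`gc_bias = 0.5` the two axes decouple, which is the regime where
optimality-driven selection is distinguishable from stability-driven
selection.

`synth_library()` builds a synthetic folA-like ORG/MOD pair (55 codons;
sequences are constructed, not natural). The second codon is a serine:
its six synonyms split into AG- and TC-starting groups, and the synthetic
regulatory region carries a 5-nt tract complementary to the AG-starting
spelling of the start region, so the codon-2 choice closes or opens a
helix across the start codon and window-1 dG genuinely varies within the
library. Default k = 9 diversified positions (512 variants), matching the
scale of real combinatorial libraries.

`gen_library_experiment()` assigns true per-variant log2 fitness
`s_i = beta_dg(c) z(dG_window1) + beta_opt(c) z(tAIg) + N(0, noise_sd)`,
with betas scaling linearly from 0 at no drug to their maxima at the
highest concentration - encoding the observation that codon-composition
fitness effects only appear under sub-inhibitory drug. Frequencies evolve
as `f <- f * 2^(G s_i)` per passage with G = 10 generations (a 1/100
dilution regrown to saturation is ~6.6 doublings; 10 leaves margin, and
the paper-style 16-h passage is not otherwise pinned down). Counts are
multinomial at fixed depth (default 1e5 reads). Defaults
`beta_dg_max = 0.4`, `noise_sd = 0.05` give day-1 mean-fitness responses
and diversity losses of the magnitude seen in drug-selected libraries
while keeping the no-drug condition nearly neutral. The hidden truth is
returned on a separate channel from the counts so recovery tests cannot
leak.

What the generator does **not** emulate: PCR jackpots and sequencing
error beyond read truncation, variant-specific DNA-extraction bias,
epistasis between codon positions, de novo mutation, and any
protein-level mechanism (degradation, aggregation, toxicity). Passing
recovery tests therefore demonstrate that the pipeline's statistics
recover the encoded structure, not that real libraries are free of those
confounders.

## Problem sizes and numerical choices

The test suite and acceptance script run on desk-scale sizes chosen as
the package's own defaults for reproducible checks: libraries of k = 7-9
(128-512 variants) at 1e5 reads; 40-110 windows; Moran census 1e4 -> 1e6
(the full 1e6 -> 1e8 protocol is available by configuration and used for
the large-N replicator check); 50-seed recovery sweeps; 1e4 null
simulations for p-value calibration. Ties in ranked associations are
compared with a 1e-6 relative tolerance; folding energies are exact
doubles with no rounding.

## Known limitations

* The folding model omits dangling ends, coaxial stacking and
  temperature dependence; only comparative statements are supported.
* tAI wobble rules use the standard prokaryotic set; organisms with
  unusual modified-base decoding (e.g. lysidine handling of AUA) are
  approximated.
* The IC50 logistic has no floor parameter; complete-resistance plateaus
  above zero would bias the fit.
* `w-bar` compares consecutive timepoints; it is not an absolute growth
  rate and is normalized per condition.
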