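---
title: "Quantifying antisense ribosomal siRNAs: models, choices, limits"
author: "risiRNAkit developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antisense ribosomal siRNAs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risiRNAkit)
```

## The problem

Ribosomal RNA is transcribed by RNA polymerase I as one long precursor
spanning, 5' to 3', the 5' external transcribed spacer (5'ETS), 18S,
internal transcribed spacer 1 (ITS1), 5.8S, ITS2, 26S and the 3'ETS.
When rRNA surveillance fails — mutations in the RNA exosome (*dis-3*,
*exos-1*), in the cytoplasmic 3'→5' exonuclease DISL-2, or in the 26S
methyltransferase RRP-8 — erroneous rRNA species recruit RNA-dependent
RNA polymerases and *C. elegans* produces **risiRNAs**: small RNAs
antisense to the rDNA transcription unit, with the hallmarks of the 22G
class (22 nt long, 5'-guanosine). risiRNAs load the nuclear Argonaute
NRDE-3 and silence rDNA co-transcriptionally.

Quantifying them from small-RNA sequencing poses two specific problems
this package addresses:

1. **Strand and identity.** Most reads matching rRNA are *sense*
   degradation fragments of the enormously abundant rRNA itself. Only
   antisense reads are siRNAs. Classification must therefore be
   strand-aware, and the library-size denominator must not be inflated
   by degradation products.
2. **Normalization.** Total read count is meaningless when one
   category (sense rRNA) fluctuates for trivial reasons. The
   normalization number used here is *total mapped reads minus sense
   rRNA reads minus sense mRNA reads* — by the category partition this
   equals `risiRNA + antisense mRNA`, i.e. the bona fide siRNA
   population. risiRNA abundance is reported per million of this
   denominator.

## The coordinate system

The ~50 genomic rDNA copies are collapsed into one representative
repeat unit (`rdna_unit`): the copies are essentially identical, so
per-copy read assignment carries no information, and one unit matches
how occupancy and coverage are displayed along a single transcription
unit. Coordinates are 0-based, half-open, BED-compatible; the plus
strand is the sense pre-rRNA. The seven regions must tile the unit
exactly — gaps or overlaps are validation errors, and `locate()`
resolves any position to its unique region.

Region lengths of the default reference
(700/1750/500/160/350/3500/150 nt) are *schematic stand-ins* chosen to
echo the relative sizes of the *C. elegans* regions; no authoritative
per-region lengths are hard-coded, and `build_default_reference()`
accepts measured lengths. 5.8S is a region of the unit (sense 5.8S
fragments are rRNA degradation), while 5S — an RNA polymerase III
transcript from a separate locus — lives in the decoy set.

## The classifier

Mapping is **exact matching with zero mismatches** on both strands of
every target, returning all hits. This stands in for conventional
short-read alignment with default parameters, and is a deliberate
design choice: it is deterministic, it is oracle-checkable (the test
suite proves the mapper identical to a brute-force substring scan at
every offset), and it is lossless on synthetic data, which the default
reference generator guarantees by rejecting decoys sharing any ≥ 18 nt
substring with the unit on either strand. Reads containing `N` never
match. Real libraries (e.g. from GEO) can be mapped externally and fed
in as classified tables, but the built-in matcher is the tested path.

Each read receives exactly one category by a fixed priority: antisense
hit on the unit or 5S → `risiRNA`; else sense rRNA hit → `sense_rRNA`;
else mRNA-decoy hit, split by strand. Multi-mapping reads count once,
via the first hit of the winning class in (target, start, strand)
order — a deterministic stand-in for an unstated multi-mapper policy;
it is exposed, not buried.

Boundary-spanning risiRNAs are assigned to the region containing the
alignment **midpoint**, `floor((start + end - 1) / 2)`; the choice
between 5'-end and midpoint assignment is not dictated by any published
rule, and the midpoint is symmetric and deterministic, with ties broken
toward the lower coordinate. With ≤ 30 nt reads on a 3500 nt 26S the
difference between the two rules is bounded by a fraction of a
percentage point.

## What the simulator states — and does not

`simulate_library()` emits the statistical structure the analysis
assumes, against a seeded reference:

* category mixture (multinomial over risiRNA / sense rRNA / sense mRNA /
  antisense mRNA / unmapped);
* risiRNA placement: a region drawn from `region_weights`, the read
  placed **wholly inside** that region (a positively weighted region
  must be at least as long as the longest read — violating this is an
  error, not a silent clip), the read being the exact reverse
  complement of the unit window;
* read length from `length_dist`, default mode 22 nt with support
  18–30 (support up to 16–35 is allowed so the clean-read filter can be
  exercised);
* 5'-G bias: with probability `p_first_G` (default 0.75) the placement
  is drawn among in-region positions whose antisense 5' base is G.
  Forcing the base itself would break exact matching and the noise-free
  recovery invariant, so the bias is realised by *conditioning the
  position*, which makes the first-nucleotide marginal exactly
  `p_first_G` while every read remains a perfect reference match. The
  published characterisation is only that the "majority" of these RNAs
  start with G; 0.75 is a configurable stand-in.

Genotype presets ship as editable JSON (`inst/extdata/presets/`). The
only two proportions anchored to printed values are disl-2 (65% of
antisense mass in 26S) and the eri-1;rrp-8 NRDE-3-IP preset (90%); the
other weights follow qualitative descriptions (exosome mutants
ITS-dominated) and are package choices, fixed once. The wild-type
preset spreads antisense mass proportional to region length with a low
(2%) risiRNA fraction.

The simulator deliberately omits: sequencing errors, PCR duplicates,
quality variation (constant Phred 'I' — the analysis never reads
quality), 5'-phosphate chemistry, and rDNA copy-number variation. A
green recovery test therefore establishes that the *arithmetic* of the
pipeline is right — not that the pipeline is robust to real-world
noise, mismatches, or multi-mapping across a full genome.

Each simulation consumes a purpose-scrambled sub-seed ("reference",
"library", "qpcr" streams are decoupled), so building a reference and
simulating a library with the same user seed can never share an RNG
stream — an identical stream once caused "random" unmapped reads to
reappear verbatim inside a decoy transcript.

## qPCR arithmetic

All Ct arithmetic assumes amplification efficiency 2 (no
standard-curve correction is modelled because none is published for
these assays):

* **percent input** = `100 * 2^((ct_input - log2(1/f)) - ct_ip)` for
  input dilution `f` (1% input: the input Ct is shifted by log2(100)
  before comparison). Identity case and one-doubling case are exact.
* **fold change** = case / control enrichment; replicates combine by
  mean-of-ratios (paired by replicate index), matching "mean ± s.d."
  of fold changes; ratio-of-means is offered as an option.
* **two-stage ChIP ratio**: locus / reference-gene (*eft-3*) within
  each condition, then +dsRNA / −dsRNA across conditions.
* **ΔΔCt** relative expression with a *required* reference gene
  argument — the reference for expression panels is not fixed by the
  package.
* **Student's two-tailed t-test** with pooled variance (not Welch, as
  "Student's t-test" is the stated method). Zero pooled variance with
  equal means gives t = 0, p = 1; with unequal means the statistic is
  undefined and the low-level function errors, while the replicate
  summarizer reports `NA` for that comparison (the noise-free simulated
  designs hit this case by construction).

The Ct simulator places the IP well `log2(1/f) + log2(enrichment)`
cycles below the input well, where `enrichment` is the fraction of
dilution-corrected input recovered — so noise-free data return
`100 * enrichment` percent input exactly, and Gaussian Ct noise
(default SD 0.15 cycles, a typical technical-replicate spread)
propagates multiplicatively.

## Numerical and degenerate-input policy

* Zero risiRNA reads: region proportions and 5'-nt tables are emitted
  all-zero with an `undefined` attribute rather than NaN.
* Zero normalization basis (no antisense reads at all) is an error:
  RPM is undefined and silently returning 0 would be misleading.
* `N` at the first read position is excluded from the 5'-nt
  denominator.
* All proportions are validated to sum to 1 within 1e-9 at
  construction.

## What the tests establish

Unit tests check every operation against an independent oracle
(brute-force mapper scan, exhaustive `locate` scan, amount-space
percent-input arithmetic, exact permutation t-test, truth-table
recovery within 3 binomial SDs). The acceptance suite re-runs the whole
pipeline at desk scale: 100,000-read libraries recover the 65% and 90%
26S proportions within 1 percentage point, the default library's modal
risiRNA length is 22 nt with G the leading 5' base, and the clean-read
filter passes exactly 18–30 nt. None of these numbers is asserted from
a lookup table; each is recomputed by simulation and classification at
test time.

## Known limitations

* Exact matching cannot process reads from a real sequencer without an
  upstream aligner; mismatch tolerance is out of scope by design.
* One collapsed rDNA unit cannot express per-copy heterogeneity.
* The permutation/t-test agreement is loosest for p around 0.5–0.7,
  where the permutation null is most skewed relative to the
  t-distribution; the documented 0.02 agreement applies to separated
  groups.
* Presets describe plausible, not measured, mixtures for every
  quantity except the two anchored 26S proportions.
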