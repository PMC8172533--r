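---
title: "Methods: BDA qPCR/Sanger confirmation of low-frequency variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BDA qPCR/Sanger confirmation of low-frequency variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdaconfirm)
```

## Scope and model

`bdaconfirm` models the confirmation of putative somatic variants called at
0.5–5% VAF in whole exome sequencing, using blocker displacement
amplification (BDA) to enrich the variant allele, qPCR ΔCq values to
quantify it, and the Sanger trace of the enriched amplicon to identify it.
The package deliberately models assays *abstractly* — by per-cycle
amplification yields and a blocker-overhead calibration — rather than by
blocker thermodynamics: oligo design is upstream, proprietary, and out of
scope, as are read alignment, variant calling, annotation and chromatogram
parsing. WES calls enter as a VCF-style table with AD/DP evidence; Sanger
evidence enters as a per-assay dominant-allele call table.

## The quantification model

Each reaction pair yields `ΔCq = with_blocker Cq − no_blocker Cq`. The
no-blocker reaction measures total amplifiable input; with blocker, only
the variant fraction amplifies efficiently. Assuming the variant allele
doubles per cycle with blocker, a sample whose ΔCq exceeds that of its
pure-variant (100% VAF) gBlock calibrator by *d* cycles contains a variant
fraction of `2^-d`, i.e.

> VAF = 100% · 2^(ΔCq_gBlock − ΔCq_sample).

The published closed form with the subtraction outside the exponent,
`100%/(2^ΔCq_sample − 2^ΔCq_gBlock)`, cannot be the intended estimator: it
divides by zero for a pure-variant sample (where the answer must be 100%)
and is negative whenever the sample amplifies earlier than the calibrator.
Re-deriving from the doubling assumption gives the exponent-difference
form, which equals the typeset form when the subtraction is read inside
the exponent. We implement the exponent-difference form and retain the
literal one behind `estimate_vaf(..., literal = TRUE)`; a regression test
documents the divergence at ΔCq_sample = ΔCq_gBlock.

Two further numerical policies:

* **Replicate aggregation.** Replicates (≥2 per reaction) are averaged on
  the Cq scale *before* ΔCq is formed — standard qPCR practice. With
  per-replicate noise small relative to one cycle, mean-first and
  ΔCq-per-replicate-then-mean differ only in second order; both orderings
  are unit-tested for near-agreement. Replicates that never crossed
  threshold are dropped (and counted); if all replicates of a reaction are
  at the sentinel, the reaction has no Cq and the candidate either fails
  QC or — when the Sanger trace is wildtype — is classified absent, since
  complete with-blocker suppression is exactly what a variant-free
  template looks like.
* **Boundaries.** Estimates above 100% (possible under noise for
  near-pure samples) clamp to 100% with a warning rather than erroring.
  `dcq_sample` may fall below `dcq_gblock` by at most a tolerance of
  3·`cq_noise_sd` (default 0.45 cycles) before the input is rejected as
  physically impossible.

## Enrichment and assay validation

With per-cycle yields `m` (mutant, in (1,2]) and `w` (wildtype, in
[1,m)), `n` cycles multiply the mutant:wildtype ratio by `(m/w)^n`
(`enrichment_fold`), and a pre-enrichment fraction `f` becomes
`f' = fE/(fE + 1 − f)` (`post_enrichment_fraction`). Defaults `m = 2`,
`w = 1.5`, `n = 30` were chosen as a round parameterization comfortably
exceeding the 1000-fold enrichment expected of a working assay
(≈ 5600-fold); all three are per-assay configurable. The two operations
satisfy the algebra one would demand of them — fold is multiplicative in
cycles, and applying folds E1 then E2 equals one application of E1·E2 —
and both are property-tested.

An assay is validated (`validate_assay`) only if the with-blocker Cq of
the wildtype gDNA negative control exceeds that of the copy-matched
gBlock positive control by *strictly more than* 10 cycles (the strict
reading of the validation rule; a margin of exactly 10 fails).
`normalize_gblock` implements the copy-matching itself under the same
doubling assumption: scale the gBlock concentration by
`2^(gblock_cq − gdna_cq)`.

## Three-outcome classification

The enriched Sanger allele decides each candidate:

| trace allele matches | status |
|---|---|
| the WES-reported alt | confirmed (ΔCq VAF estimate attached) |
| the reference | absent |
| neither, with ≥3 concordant replicate reactions | misidentified |
| neither, with fewer replicates | failed_qc (`pending_replicates`) |

"Repeated at least twice" is operationalized as ≥3 total concordant
non-reference, non-expected calls; unvalidated assays and unresolvable
sentinel Cq values also yield `failed_qc`, never silent omission, so
confirmed + absent + misidentified + failed_qc always equals the number of
candidates. VAF estimates are attached to confirmed results only:
quantification without a confirmed identity is not reported.

## The synthetic cohort

The generator produces a mirrored fresh-frozen (FF)/FFPE pair with known
truth. What it emulates, and the defaults (all `sim_config()` arguments):

* **Shared tumor variants** (`n_true_variants = 1700`) with true VAF
  log-uniform over 0.5–5% (`vaf_range`), the band in which candidates are
  examined; log-uniform spreads mass evenly across the decade rather than
  piling onto the upper edge. The FF-to-FFPE VAF relationship for shared
  variants is not identifiable from call tables alone, so it is a
  configurable scaling (`vaf_scale_ffpe`, default 1) rather than an
  assertion.
* **FF-only variants** (`n_ff_only = 300`) and **FFPE-only damage
  artifacts** (`n_artifact_variants = 6500`, reflecting that the FFPE call
  set is several-fold larger). Artifacts take the C:G>T:A deamination
  classes with probability `deamination_excess = 0.8`.
* **Misidentified calls** (`n_misidentified = 5`): the truth is an
  anchored single-base insertion whose inserted base the simulated caller
  reports as a substitution. Planting this at the truth level
  (`reported_alt ≠ true_alt`) is the simplest mechanism that reproduces
  the observed phenomenon; no caller errors are simulated mechanistically.
* **Read sampling**: locus depth is negative-binomial with means 824 (FF)
  and 243 (FFPE) and dispersion `depth_dispersion = 4` — the depth
  summaries give means and wide ranges, not a distribution, and the
  negative binomial is the standard overdispersed choice; alt reads are
  binomial at the true VAF plus background error reads at
  `per_base_error_rate = 1e-4`; a call needs `min_alt_reads = 3` (set 4
  to mimic stricter FF behaviour).
* **qPCR**: all templates are copy-matched at `base_cq = 25` (a typical
  10 ng input); the with-blocker Cq adds the assay's blocker overhead
  (default 3 cycles) plus `−log2(VAF)`; zero-VAF templates sit at the
  no-amplification sentinel `max_cycles = 45` (the cycling protocol
  length). Per-replicate Gaussian noise `cq_noise_sd = 0.15` cycles is a
  typical bench replicate SD (not given by the protocol); with
  triplicates it yields a median ~1.1-fold deviation of estimated from
  true VAF, comfortably inside the 1.5-fold accuracy expected of ΔCq
  quantification against ddPCR.
* **Sanger**: the trace calls the true variant allele when its
  post-enrichment fraction reaches `dominant_threshold = 0.2`, the upper
  end of raw Sanger's 5–20% LoD band (a conservative choice for calling a
  secondary peak dominant).

What it does **not** emulate: read-level data (no FASTQ), chromatogram
waveforms, FFPE coverage-uniformity/fragment-length effects beyond the
depth-mean difference, caller-specific artifact spectra, or germline
contamination. Passing tests therefore demonstrate the *arithmetic and
classification logic* on data satisfying the model's own assumptions — not
that the model captures every failure mode of real FFPE exomes. In
particular the synthetic disconfirmed rate is governed by
`per_base_error_rate` and the planted false positives, not calibrated to
any cohort's observed rate.

## Candidate selection and reporting

Selection takes *all* calls under the VAF cutoff (strictly `< 5%`) in the
supplied cancer-related gene list (case-insensitive exact symbol match,
one per line), plus `n_random` uniformly sampled (seeded, without
replacement) other low-VAF calls; per-sample quotas are parameters since a
joint draw is not distinguishable from per-sample draws downstream.
Concordance between mirrored samples is exact (chrom, pos, ref, alt)
identity on pre-normalized calls, partitioned at a VAF threshold
(default 20%).

Reports count confirmed/absent/misidentified per stratum —
sample, cancer-gene class, VAF bracket (default edges 0.5, 1, 2, 3, 4, 5
percent, plus a binary split at 3%; the bracket edges are a display
choice, configurable), functional category (unknown labels fall back to
"other" with a warning), and strand-collapsed alteration class (six
substitution classes plus "indel"; equal-length multi-base changes are
"other"). Disconfirmed = absent + misidentified; rates are rounded
half-up to integer percent with raw fractions retained; `failed_qc` rows
are excluded from denominators and reported alongside. Misidentified
variants are counted within their WES-assigned category and alteration
class (the class the caller reported, since that is the unit being
audited). The false-negative analysis takes FF-only low-VAF calls
re-tested on the FFPE template and counts confirmed results as WES false
negatives in FFPE.

## Problem sizes and determinism

Tests run the generator at tens-to-hundreds of variants and the accuracy
simulation at 200 assays — sizes at which every statistical check is
stable yet the whole suite completes in seconds. Every stochastic step
(truth generation, read sampling, Cq noise, candidate sampling) is seeded
through `sim_config(seed=)` or an explicit seed argument; identical seeds
reproduce identical outputs byte for byte, which the suite asserts end to
end.

## Known limitations

* Enrichment is deterministic given the assay parameters; no per-assay
  design failures or efficiency variability are modelled (how often real
  designs fail the 10-ΔCq gate is not modelled at all).
* The Sanger model is a threshold on the enriched allele fraction; it
  cannot produce miscalled bases, mixed traces, or strand-specific
  artifacts.
* Discordant replicate Cq values are adjudicated by the mean of
  non-sentinel replicates, with `failed_qc` only when all replicates
  fail; this is a stated policy choice, not an observed protocol.
* Indel identity is exact string match on pre-normalized alleles; no
  left-alignment is performed.
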