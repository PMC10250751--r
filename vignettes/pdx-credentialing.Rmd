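---
title: "Credentialing a PDX panel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credentialing a PDX panel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxforge)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their units
and defaults, what the synthetic-data generators emulate (and what they do
not, hence what a green test does and does not establish), and the design
choices made where the problem was genuinely open.

# The problem

A patient-derived xenograft (PDX) panel is only useful if each model is
*credentialed*: shown to carry the patient's genome (STR identity), its
somatic alterations characterized (variant filtering, tumor mutational
burden, allele-specific copy number, focal events), its transcriptional
subtype established (expression clustering, signature scores), and its
drug response quantified in vivo (growth metrics, mRECIST). Each of these
is a standard computation, but published panels rarely deposit raw data,
so this package pairs every analysis stage with a forward simulator whose
ground truth is known. All claims in the test suite are therefore
recovery claims: the generator states a world, the analysis must invert
it.

# Somatic variant post-filtering

A variant record carries the call-quality and population-frequency fields
the six filter rules consume. A record is retained iff

* QSS ≥ 20 — average base quality of the variant-supporting bases;
* tumor depth ≥ 10 reads;
* VAF in tumor ≥ 0.05 **and** ≥ 5 mutated reads (one joint rule);
* gnomAD global AF < 1e-5 (strict);
* in-house database AF < 0.01 (strict);
* coding consequence.

All "≥" bounds are inclusive and the population bounds strict, matching
the stated inequality directions; the boundary record (QSS 20, depth 10,
VAF 0.05 with 5 reads) is retained, a gnomAD AF of exactly 1e-5 is
rejected. Three design choices were open:

* **Absent population AFs are treated as 0.** A variant missing from
  gnomAD is novel; absence cannot justify rejection.
* **Rejection attribution** uses the first failing rule in the listed
  order, making per-rule tallies deterministic (a record failing several
  rules is counted once).
* **"Coding"** is a boolean derived upstream from a configurable set of
  consequence labels (missense, stop-gained, frameshift, in-frame indel,
  splice-site, stop/start-lost); the filter itself only sees the flag.

TMB is retained count / callable Mb, reported to two decimals. The
callable size is study-specific and undeposited for the reference panel,
so it is a required input with a conventional 50 Mb whole-exome default —
published per-sample TMB values cannot be reproduced without the true
target size, and the package does not pretend otherwise.

# Allele-specific copy number

## Signal model

At a germline-heterozygous SNP, a tumor segment with allele-specific
copies (a, m), diluted by a fraction c of normal cells, yields

* total copy ratio r = (2c + (1−c)(a+m)) / 2,
* LRR = log2(r) − log2(ψ/2), with ψ the length-weighted mean total copy
  number (this term reproduces the median-centering an array pipeline
  applies — the raw log ratio is only defined up to a profile-wide
  offset),
* BAF = (c + (1−c)·b)/(2c + (1−c)(a+m)) for b copies of the B allele, or
  its mirror image: arrays do not phase, so the simulator flips a fair
  seeded coin per site. Homozygous sites emit BAF near 0 or 1 and carry
  no allelic information; they are excluded from BAF segmentation.

## Segmentation

Circular binary segmentation is implemented from scratch (the classical
Bioconductor implementation is not a dependency here): the best circular
arc under the two-sample statistic
|mean_in − mean_out| / (s·sqrt(1/k + 1/(n−k))) is found by exhaustive
O(n²) scan (compiled), and accepted when its permutation p-value is below
alpha. Defaults: alpha = 0.01, 1000 permutations, minimum segment width 3,
seeded permutation stream. These are conventional CBS settings; the
algorithm's name, not its parameters, is fixed by the field. The scan is
validated against an independent brute-force R enumeration in the test
suite. LRR breakpoints (all sites) and mBAF breakpoints (het sites only)
are merged; an mBAF breakpoint is dropped when an LRR breakpoint falls in
the same heterozygote-free gap, since both then mark one boundary that
the denser LRR track localizes better. A consequence, visible in
noise-free tests: a fitted boundary can sit anywhere inside the
het-free gap around the true boundary, so a few homozygous edge sites may
fall on the wrong side. Micro-segments produced by boundary uncertainty
carry negligible length weight.

## Ploidy, contamination and the lattice fit

The fit is a re-derivation in the spirit of Genome Alteration Print
(ploidy, contamination, and per-segment integer states from segmented
LRR/mBAF), not a port of its published pattern-recognition code. For each
candidate contamination (grid 0–0.94, step 0.01) and LRR offset (window
−1 to 3, step 0.02, then polished in closed form), every segment is
assigned the lattice state (a ≥ m ≥ 0, a ≤ 8) minimizing

    (ΔLRR)² / SE_LRR² + (ΔmBAF)² / SE_mBAF²

with per-segment standard errors SE_LRR = lrr_sd/√n_sites and SE_mBAF =
baf_sd/√n_het. Two numerical points matter:

* **Folded-BAF bias.** Mirrored BAF of a balanced segment does not
  average 0.5 but 0.5 + baf_sd·√(2/π), because mirroring folds the noise
  upward. The model expectation is folded-normal-corrected; without this
  the fit systematically distorts contamination. With sd = 0 (noise-free
  input) the correction vanishes and exact inputs score exactly 0.
* **Offset reparameterization.** The searched offset absorbs both the
  array baseline shift and log2(ψ̂/2) (ψ̂ depends on the assignment,
  which would otherwise make the model circular); the centering term is
  backed out after the fit and reported as `baseline_shift`.

**Identifiability and canonicalization.** The model family has exact
degeneracies: multiplying every state by an integer k (whole-genome
doubling and beyond) at contamination c′ = kc/(1+(k−1)c), and subtracting
one copy of each allele at c′ = (c+f)/(c+2f), f = 1−c, reproduce the data
*exactly* — the overall scale is absorbed by the offset. No amount of
data resolves these; what resolves them in practice is genome structure:
an LOH segment (minor = 0) blocks the subtraction and an odd-copy state
blocks the division. The fit therefore canonicalizes its grid optimum by
applying these transforms toward lower ploidy while they reproduce the
score (within 5%, evaluated from the analytically mapped assignment), and
flags the result `ambiguous` when a transform remains applicable at the
end — an all-balanced or LOH-free profile is reported at its lowest
consistent ploidy with the flag set, the Occam convention of
allele-specific callers. Transform validity is judged on segments
carrying ≥ 95% of genome length so that CBS micro-segments cannot veto a
transform, and a subtraction that would empty the tumor entirely (ploidy
< 1) is never taken. Ploidy is the length-weighted *median* of fitted
totals; ψ̂ the length-weighted mean.

Real tumor genomes essentially always contain LOH and odd-copy segments,
so the canonical solution is the true one; the synthetic test genomes
include both anchors deliberately, and the recovery criteria (ploidy
±0.2, contamination ±0.05, ≥95% site-status accuracy across ploidies
2–4 and contaminations 0–0.4 at array-like noise) are met on that stated
world. A green recovery test does *not* establish performance on profiles
without anchors — those are reported, correctly, as ambiguous.

## Threshold calls and summaries

Gain/loss use the empirical rule total > ploidy + 0.5 / < ploidy − 0.5
applied to fitted integer totals (the continuous-mean variant is a
configuration away but not the default); LOH requires minor = 0 with at
least 3 heterozygous sites of support, so copy-neutral LOH is a neutral
segment with the flag set. FAG is the genome-length fraction in
non-neutral-or-LOH segments. FAA needs an arm definition the source
material never gives: an arm counts aberrant when ≥ 50% of its covered
length is aberrant — recorded here as an explicit, configurable
assumption.

The coverage track smooths bait log ratios with the same CBS, takes the
modal smoothed value as the zero level (Gaussian kernel density argmax,
bandwidth 0.05 — a mode of continuous data needs a density estimate), and
calls gains/deletions beyond ±0.3 and high-amplification / homozygous
deletion beyond ±5 s.d. of smoothed values in normal regions (explicit
regions if supplied, else the neutral band; if the smoothed normal values
are degenerate — a single noise-free segment — the raw bin s.d. stands
in). Labels are hierarchical: an amplification is also a gain.

# STR identity

Profiles are locus → allele multisets; homozygous diploid loci are
recorded as the allele twice so denominators stay consistent. The default
score is Tanabe (100·2·shared/(n_a+n_b)); Masters (vs the reference
profile) is provided because the source material states only "% match in
alleles", and the choice is logged in each report. Amelogenin is scored
when typed in both profiles (it is amplified with the STR loci) and can
be excluded. Authentication is strict: score > 80 passes, exactly 80
fails. A locus with more than two alleles (ploidy drift, as in tetraploid
models) is compared on allele sets with a warning rather than invented
weights.

# Pharmacodynamics

Tumor volume is length·width²·π/6; ΔT/ΔC is the ratio of arm-mean volume
changes from baseline, in percent, at a specific day, with bands
response < 0%, partial 0–50% (closed band, boundaries included), none
> 50%. It is undefined (a diagnostic, not a silent NA) when the control
arm has not grown. Missing days are linearly interpolated within an
animal's observed range and never extrapolated.

BestResponse and BestAvgResponse default to the running-minimum
definitions of the mRECIST framework (minimum percent volume change, and
minimum running mean of it, over post-baseline days ≥ t_min); a
`last_day` mode uses only the final measurement, matching the literal
"change at the last day" phrasing that coexists with the framework's
definitions. The mode is recorded in every output. mRECIST tests CR, PR,
SD in order (CR: best < −95 and avg < −40; PR: < −50 and < −20; SD: < 35
and < 30) and falls through to PD, which makes it a total, monotone
classifier.

Ethical censoring truncates the *whole study* at the first measurement
day on which any animal exceeds the 1500 mm³ cap (that day is kept — it
was measured); treated-vs-control metrics are then computed on the common
window.

The growth simulator draws initial volumes uniformly from 65–270 mm³
(the conventional randomization window), grows volumes exponentially at
the control rate times a per-arm multiplier, applies multiplicative
lognormal noise (tumor-volume error is proportional, hence lognormal; CV
default 0.15), and re-decomposes each observed volume into a caliper
pair. The decomposition uses a per-animal shape factor s = width/length
drawn once from [0.7, 1], with length = (6·TV/(π·s²))^(1/3) and width =
s·length — this is the algebraically exact decomposition for that shape
convention (a superficially simpler variant reconstructs TV·s instead of
TV, so exactness fixed the formula). Twice-weekly measurement days (0, 3,
7, 10, ...) mirror practice. What the simulator does not emulate:
measurement dropout, caliper operator bias, tumor regrowth after
response, or body-weight endpoints; the ethical cap is the only stopping
rule.

# Expression

TPM divides counts by gene length in kb and scales each sample to 10⁶.
All downstream work uses log2(TPM+1) — a standard variance-stabilizing,
zero-anchored transform chosen because the source names none. The
most-variant-gene selection ranks by per-gene variance (ties broken by
gene label so results are deterministic); clustering uses 1 − Pearson
correlation between samples and average linkage (configurable to
Euclidean/Ward — "unsupervised hierarchical clustering" fixes neither).
Signature scores are means of direction-signed per-gene z-scores;
zero-variance genes contribute 0 rather than NaN. Cluster contrasts are
fold-change-only by design: the reference panel's first cluster has a
single sample, so no replicate-based test is honest there, and the
differential counts produced by proprietary platforms are not expected to
be reproduced by a fold-change stand-in.

The count simulator uses negative-binomial genes (lognormal baseline
means, dispersion 0.1 by default) with a chosen signature shifted by a
log2 fold change in cluster 2. Because TPM is compositional, boosting the
signature mass slightly depresses every other gene in cluster 2 — the
tests acknowledge this rather than asserting an impossible zero
false-positive rate at the fold-change threshold. Cluster recovery is
exact at effect ≥ 4 log2 units with ≥ 50 signature genes across seeds;
that claim is about this generative world, not about subtle real-world
subtype boundaries.

# Pipeline and reproducibility

`run_pipeline()` orchestrates the stages over a built-in five-sample
synthetic panel (diploid low-burden; tetraploid with an MMR-gene-like
homozygous deletion planted for the coverage track; a pre/post pair
sharing a mutation subset; responder and non-responder growth studies);
`demo_cohort()` is the one-call version that also writes every artifact
and a JSON run report. A single global seed fans out to per-stage seeds
through a Lehmer-style mixer (`derive_seed`), so each stage's stream is
reproducible independently of stage order; every generator is a pure
function of (spec, seed). All hand-off formats are plain text (TSV, CSV,
SEG, JSON) and each writer's output is re-read by its own reader in the
tests. The package exposes its functionality as an R API; the
command-line entry point is the acceptance script plus ordinary
`Rscript -e` calls, which is the natural interface for an analysis
package of this kind.

# Known limitations

* The copy-number fit assumes one dominant clone; subclonal states (non-
  integer effective copies) are fit to the nearest lattice point.
* Contamination above ~0.95 is rejected as unidentifiable by
  construction, and very high contamination with few aberrations will be
  flagged ambiguous rather than resolved.
* CBS boundary placement within heterozygote-free gaps is inherently
  uncertain; segment-level statuses are robust to it, base-pair-exact
  breakpoints are not.
* TMB depends on a callable-size input the user must supply.
* The simulators state convenient worlds (exponential growth, NB counts,
  Gaussian array noise); green tests certify inversion of those worlds,
  not immunity to every artifact of real instruments.
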