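---
title: "Methods: simulated embryo genomic selection in sheep"
author: "embryogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated embryo genomic selection in sheep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Preimplantation genomic selection genotypes a few trophectoderm cells
biopsied from a blastocyst, amplifies the picograms of DNA by whole-genome
amplification (WGA), reads the product on a SNP array, and predicts the
embryo's genetic merit before transfer. Whether that works hinges on a
chain of quantitative questions: how badly does the WGA channel corrupt
the chip genotypes as a function of biopsy cell number; can imputation
against a phased reference panel repair the damage; and do breeding values
estimated from the biopsy agree with those estimated from the born lamb's
blood sample. `embryogs` implements that chain end to end on a simulated
ovine cohort with known ground truth, so every stage can be checked
against either an exact oracle or the generating model.

## The simulated cohort

No genotype data accompany the study this design follows, so the package
generates its own, with these study conditions as defaults: a 5,000-SNP
biallelic panel spread over 5 chromosomes (a desk-scale stand-in for a 50K
ovine array), 200 phenotyped reference animals, and 40 embryo/lamb pairs.
An embryo and its lamb are *the same true genotype observed through two
channels*: the biopsy/WGA channel and an almost-clean blood channel (0.2%
call error, 1% missingness). This duality is the structure behind both the
concordance/IBD analysis and the GEBV comparison.

Founder haplotypes are drawn site-independently with per-site alt-allele
frequencies uniform on [0.05, 0.5]; there is deliberately no founder
linkage disequilibrium. Offspring receive recombinant gametes (Markov
switch probability 0.001 per adjacent marker, roughly one crossover per
chromosome at the default marker spacing), so the haplotype sharing that
the imputation HMM exploits arises from pedigree co-inheritance rather
than population LD. The phased reference panel holds the true haplotypes
of the reference cohort *and* of the offspring, mirroring a self-cohort
sequencing panel. Traits follow `y = mu + a + e`: 300 causal SNPs per
trait with normal effects, breeding values rescaled so their realized
variance equals `sigma2_a` exactly, residuals i.i.d. normal. Eight growth
traits (birth weight; weights at 90/180/240 days; average daily gains
over 0–90, 90–180, 180–240 and 0–240 days) use heritabilities of
0.20–0.35, typical for ovine growth.

### The WGA noise model and its calibration

The biopsy channel is a per-copy capture model: each of the two allele
copies at a site is captured by each of the `n_cells` cells independently
with failure probability `q` per cell, so a copy is missed with
probability `m = q^n_cells`. Both copies missed gives a missing call; one
copy of a heterozygote gives a false homozygote (allelic dropout); a
residual error `eps` then replaces any called genotype with a uniformly
different one. This makes expected call rate `1 - m^2` and het-dropout
probability `2m(1 - m)` — monotone in cell number in opposite directions,
which is the empirically observed signature of biopsy genotyping.

The two published anchors for a 10-cell biopsy (call rate about 93.7%,
mismatch about 2.4%) cannot be met simultaneously by *any* independent
per-copy model: forcing the call rate to 93.7% forces `m = 0.25` and
hence roughly 13% mismatch. Real WGA failure is site-correlated (locus
dropout), which breaks the `1 - m^2` link; modelling that correlation is
out of scope. We calibrate to the error anchor instead — `q = 0.72`,
`eps = 0.003`, giving 10-cell mismatch near 2.8% and a call rate that
saturates faster than the published curve — because downstream GEBV
agreement is governed by genotype error far more than by missingness,
and missingness is the component imputation repairs anyway. The
consequence to keep in mind: the simulated 10-cell arm is *less missing*
than real biopsies, so call-rate improvements and rescue counts from
imputation are smaller than field values, while the monotone cell-number
trends (the qualitative claim the tests assert) are preserved.

## Quality control

`apply_qc()` re-implements the array QC with PLINK's semantics and
documented order: sample missingness (`--mind` 0.1), then SNP missingness
(`--geno` 0.1), then MAF (`--maf` 0.05, ties kept), then the
Hardy-Weinberg exact test (`--hwe` 1e-5), each recomputed on the data
surviving earlier filters. The HWE exact p-value is the Wigginton-style
conditional test (sum of heterozygote-count probabilities no larger than
the observed one); a chi-square alternative is exposed but not used by
default. HWE counts are restricted to the reference cohort, since
WGA-distorted biopsy genotypes would otherwise inflate apparent
disequilibrium. The operation is idempotent, and an emptying outcome is
flagged rather than fatal.

## Concordance and identity-by-descent

Pair concordance is computed over sites called in both members; any call
inequality counts once (no partial credit for a shared allele), so
consistency and mismatch sum to one by construction — this also fixes the
otherwise-ambiguous denominator question in favour of excluding
half-missing sites. IBD uses the PLINK method-of-moments estimator:
observed IBS0/1/2 counts against their allele-frequency expectations
under each IBD state, with exact without-replacement allele-count
products as the finite-sample correction, negative solutions truncated to
[0, 1] and renormalized, and `pi_hat = P(IBD=2) + P(IBD=1)/2`.
Frequencies come from the reference cohort; pairs with fewer than 200
usable SNPs are flagged low-confidence. The pipeline pools pairs across
all cell-number arms before regressing consistency on `pi_hat`, because
the spread that makes the regression informative comes from variable
biopsy quality.

## Imputation

`impute_sample()` is a diploid Li–Stephens copying model: the hidden
state is an ordered pair of panel haplotypes; each copy switches between
markers with probability `switch_rate` (default 0.01) to a uniformly
chosen haplotype; the genotype implied by the pair is compared with the
observed call through a per-allele error channel (`emit_error`, default
0.01); missing sites emit a constant. Posteriors come from scaled
forward–backward (per-site normalization of both message passes — the
messages sum to one at every site by construction, checked to 1e-9 in the
tests), implemented in compiled code using the rank-one structure of the
transition matrix so one update costs O(K^2). Panels larger than `top_k`
(default 20) haplotypes are first reduced to the `top_k` most IBS-similar
haplotypes, with deterministic ties by panel order; results are identical
to the full state space whenever `top_k` covers the panel, which the
tests assert. A call is emitted (or an existing call changed) only where
the genotype posterior reaches `posterior_call_min` (default 0.9, safely
above the uninformative 1/3); otherwise the original observation is kept,
so call rates can only rise.

Evaluation reports the call-rate change in percentage points,
post-imputation concordance with truth, the rescue rate (missing before,
called correctly after), and the correction rate. The "percentage of
erroneous calls corrected" has two defensible denominators — erroneous
pre-imputation calls, or all pre-imputation calls — and published
headline values are ambiguous between them, so both are always emitted,
explicitly labelled.

## GBLUP

`build_G()` is VanRaden method 1: `G = M M' / sum(2 p_i (1 - p_i))` with
`M` centered by `2 p_i`. Monomorphic and frequency-undefined SNPs are
excluded; missing entries center to zero and are counted. Centering
frequencies are estimated once from the phenotyped reference cohort and
reused for embryo and lamb matrices, so the two channels are centered
identically. G is invariant to which allele is labelled ALT, so using
alt-allele rather than strict minor-allele frequencies is immaterial (and
avoids relabelling instability near 0.5).

`fit_gblup()` solves the mean-plus-animal mixed-model equations with
`lambda = sigma2_e / sigma2_a`; variance components are user inputs (the
evaluation-system convention), not estimated — no REML is in scope.
Because G is rank-deficient whenever individuals outnumber independent
SNP contrasts, the inverse uses a ridge `delta = 1e-6` on the diagonal,
falling back to a 1% identity blend if the matrix is still
ill-conditioned; the matrix actually inverted is kept on the fit object
so the test oracle (direct generalized-least-squares through
`V = Z G Z' sigma2_a + I sigma2_e`) sees the same effective prior.
PEV is the random-effect diagonal of the inverse coefficient matrix times
`sigma2_e`; reliability is `1 - PEV / sigma2_a`, clamped to [0, 1] with
clamps counted.

Embryos and lambs are evaluated in *separate* fits (reference + embryos,
reference + lambs), so the embryo-on-lamb GEBV regression compares the
two genotyping channels rather than sharing information through one G;
when the channels carry identical genotypes the two fits coincide
exactly, which the tests assert.

## Numerical and design choices, in brief

- Genotypes are alt-allele dosages {0, 1, 2} with a missing sentinel,
  making the `g - 2p` centering direct.
- Filter order mind → geno → maf → hwe follows the named tool's
  documented behaviour; only the flags are published.
- The HMM oracle in the test suite is brute-force path enumeration
  (chunked over the first-site state), fully independent of the
  forward–backward code path it checks.
- Per-stage seeds are derived deterministically from one master seed, so
  stages can be re-run in isolation with identical results; every
  stochastic operation is bit-reproducible given (seed, parameters).
- The accuracy experiment (correlation between true and estimated
  breeding values over a heritability and cohort-size grid) uses a
  *pedigreed* reference cohort — offspring of a 20-founder pool — because
  with site-independent founder haplotypes an unrelated cohort shares no
  information between animals and cohort size cannot matter; relatedness
  is what makes it matter, as in any real breeding population.

## Problem sizes

Default analyses run at 5,000 SNPs, 200 reference animals and 40 pairs —
chosen because every estimator here (moments of G, MME solutions, HMM
posteriors, IBD moments) reaches its asymptotic behaviour well below 50K
markers, and the published reference scale (tens of thousands of SNPs,
nearly a thousand reference animals) adds nothing but runtime to the
mathematical checks. The acceptance analyses state their own sizes
inline (e.g. 500 x 5,000 for the G-matrix moments, 50 random instances
of n <= 30 for the GLS equivalence).

## Limitations

The generator omits founder LD, sex chromosomes, genotyping-intensity
(A/B cluster) structure, biopsy mosaicism, and site-correlated WGA
failure; passing tests therefore demonstrate correctness of the
estimators and the qualitative robustness of the pipeline, not
field-accurate error magnitudes. Imputation metrics in particular sit at
the optimistic end because the panel contains each sample's own true
haplotypes — exactly the self-cohort panel design the pipeline emulates,
but a best case for any HMM imputer.
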