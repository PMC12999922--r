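---
title: "Temporal mutational-signature analysis: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal mutational-signature analysis: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigtempo)
```

## The problem

A metastatic cancer patient sampled at several tumor sites carries somatic
mutations laid down at different times: mutations acquired before
dissemination are inherited by every lesion, while mutations acquired after
dissemination appear only in some lesions. sigtempo operationalizes this
with a sharing rule: a single-nucleotide variant present in **all** of a
patient's tumor samples is classed *early*, and one absent from at least
one sample is classed *late*. Early mutations are expected to carry the
mutational-process fingerprint of the primary site; late mutations mix
processes from primary and metastatic environments. The package asks, for
each patient and timing class, *which tumor site's expected mutational
signatures best explain the observed mutation spectrum* — and quantifies
that with a frequency-weighted score.

## The model

### SBS96 profiles

Each SNV is mapped to one of the 96 pyrimidine-centric single-base
substitution channels `X[P>Q]Y` (P ∈ {C,T}); purine-reference mutations
are reverse-complemented together with their trinucleotide context. The
canonical channel order is the COSMIC convention — substitution classes
C>A, C>G, C>T, T>A, T>C, T>G, and within each class the 16 flank pairs in
lexicographic (5', 3') order — fixed bit-exactly so catalog columns and
profiles can never be silently misaligned. No trinucleotide-opportunity
renormalization is applied: fitting works on raw counts converted to
proportions, which is the appropriate scale when the reference catalog and
the observations come from the same assay class.

### Site-prioritized refitting

Signature refitting estimates non-negative fractions $S_i$ of known
reference signatures whose combination best reconstructs an observed
profile. `refit_signatures()` implements a deterministic two-stage
procedure:

1. **Restricted NNLS.** Only signatures *expected* at the prioritized
   tumor site — positive prevalence in the cancer type the site maps to —
   enter the fit. The profile's proportion vector is approximated in the
   Euclidean sense by non-negative least squares, coefficients are
   normalized to fractions, fractions below `prune_threshold` are removed,
   and the fit is re-solved on the survivors until stable.
2. **Rescue.** If the reconstruction's cosine similarity (CS) to the
   observed profile falls below `rescue_cs_threshold`, out-of-site catalog
   signatures are admitted greedily, one at a time, always the candidate
   with the largest CS gain (ties broken by catalog order), stopping when
   the best gain drops below `rescue_gain`.

The Euclidean objective was chosen over a cosine objective because it is
convex, has a unique solution up to catalog degeneracy, and is directly
checkable against exact linear solves and exhaustive subset search; cosine
similarity is reserved for the acceptance/rescue decision and for
reporting. The procedure is deterministic throughout — there is no random
initialization — so reruns on the same inputs are byte-identical.

### The Signature Score

Cosine similarity alone cannot tell sites apart: a dominant signature that
fits well yields high CS whichever site's expected list was used. The
Signature Score weights each detected signature by its population
prevalence $f_i$ (the fraction of patients of the prioritized cancer type
carrying it, estimated in a reference cohort of size $N_i$):

$$SS_m = CS_m \sum_i S_i f_i, \qquad
  SE_m = CS_m \sqrt{\sum_i S_i^2 \frac{f_i (1-f_i)}{N_i}}.$$

A fit composed of signatures implausible for the tissue is penalized even
when it reconstructs the spectrum well. The SE propagates only the
binomial sampling error of the prevalences, treated as independent;
fractions and CS enter as point estimates, so the SE — and every p-value
built on it — is an underestimate, and comparison output carries a fixed
note saying so. Score comparisons use a two-sided z-test on the pooled-SE
standardized difference: the SEs are analytic, not sample-based, so no
finite degrees of freedom are defined and the normal reference is the
coherent choice. No multiple-testing correction is applied by default
(pairwise p-values are reported raw); `apply_bh = TRUE` adds a
Benjamini–Hochberg column.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_mutant_reads` | 1 read | mutant-base presence threshold per sample |
| `min_mutations` | 100 | minimum early *and* late counts for a patient to be analyzed |
| `min_freq` | 0 (any $f>0$) | prevalence needed to count as site-expected |
| `prune_threshold` | 0.01 | fraction below which a signature is dropped and the fit re-solved |
| `rescue_cs_threshold` | 0.85 | CS below which out-of-site signatures may be admitted |
| `rescue_gain` | 0.02 | minimum CS improvement to admit another signature |

Presence is deliberately a bare detection rule (≥ 1 mutant read) with the
threshold exposed, because tolerance to sequencing noise is
study-specific; raising the threshold can only shrink the early set, never
grow it. A sample with no row at a position is treated as
assayed-and-absent rather than missing. The pruning and rescue defaults
keep solutions sparse at the two-decimal granularity at which signature
fractions are conventionally reported.

## The synthetic cohort generator

`generate_cohort()` produces complete, pipeline-ready inputs whose
statistical structure matches what the analysis assumes: per patient, a
primary sample plus metastatic samples; early mutations drawn from a
mixture dominated by one primary-site-associated signature; late mutations
from a broader mixture; presence vectors that make early mutations shared
by all samples and late mutations carried by a uniformly drawn proper
non-empty sample subset; and Poisson read depths with binomial mutant
counts (floored at one read where present).

Defaults describe a small metastatic whole-exome cohort: 7 patients, 4
samples each (1 primary + 3 metastatic sites), 300 early and 200 late
mutations per patient (comfortably above the 100-mutation QC bound, and at
the scale WES yields per timing class), an early mixture of 0.7/0.3 with
the dominant signature prevalent in 80% of the primary cancer type's
reference cohort ($N = 500$) and absent from every metastatic type, a late
mixture of 0.40/0.35/0.25, and mean depth 60×. The bundled toy signatures
concentrate 90% of their mass on disjoint channel blocks, giving pairwise
cosine similarity around 0.11 — deliberately well conditioned.

What the generator does **not** emulate: clonal phylogenies (late presence
subsets are uniform rather than tree-structured), copy number, selection,
caller artifacts, and the high pairwise similarity of some real COSMIC
signatures (e.g. flat or near-collinear signatures). Passing tests
therefore demonstrate that the estimator and pipeline are correct and well
behaved under the stated generative model, not that real tumor profiles
decompose this cleanly; with nearly collinear real signatures, recovered
fractions are less identifiable even when the reconstruction is good.

## Numerical choices and degenerate inputs

* NNLS is solved by Lawson–Hanson active-set iteration
  (`pracma::lsqnonneg`) on proportion vectors; coefficients are
  renormalized to fractions, so results are invariant to the profile's
  total.
* Ties — in greedy rescue, in the dominant signature, in top-k lists — are
  broken by catalog column order, which is stable and documented.
* A fraction vector whose entries all fall below the pruning threshold
  keeps its single largest contributor rather than emptying the model.
* An all-zero profile, a zero-norm vector in cosine similarity, an
  unmapped tumor site, and a single-sample patient are refused with
  errors, not silently coerced. Two fits whose SEs are both zero yield a
  comparison flagged degenerate (p undefined) rather than p = 0.
* Extreme z-scores clamp the p-value to the smallest positive double so
  that p stays in (0, 1].
* Catalog columns must sum to 1 within 10⁻³ (then are renormalized
  exactly); shuffled channel rows are accepted and re-sorted because
  channels are named.

Two conventions were genuinely open and are fixed as follows: fitted
exposures are reported as *normalized shares* over the detected signatures
(so quoted percentages sum to 100), and the prevalence table supports a
per-signature cohort size $N_i$, with a single shared $N$ per cancer type
as the ordinary case.

## Verification scale

The test suite exercises, among others: exact recovery of noiseless ≤3
signature mixtures (tolerance 10⁻⁶); equivalence of the prune-and-rescue
fit with an exhaustive ≤3-subset NNLS oracle on a 6-signature catalog
(CS within 0.01); stochastic recovery of a 0.7/0.3 mixture from 2,000
sampled mutations within ±0.05 in ≥90% of 100 seeded replicates; the
early/late rule against a brute-force all-samples-present check on 1,000
random presence matrices; z-test calibration under a pure
prevalence-noise null (1,000 replicates against the exact binomial 95%
band at α = 0.05); and an end-to-end run of 50 simulated patients with
1,000 early mutations each, in which at least 90% must show a dominant
early signature and a higher primary-site than metastatic-site Signature
Score. These sizes keep the whole suite under a minute on one CPU while
leaving the Monte-Carlo bands meaningful.

## Known limitations

* The early/late split is sensitive to sampling completeness: unsampled
  metastatic lesions can promote truly late mutations to "shared by all".
* The SE (and the z-tests built on it) understate uncertainty, since
  fraction and CS error are not propagated.
* Restricted fitting trades reconstruction quality for plausibility by
  design: when the expected set fits at a CS just above the rescue
  threshold, the fit can sit below the unrestricted optimum. That is the
  intended behavior, not an optimizer failure.
* De novo signature extraction, clone-phylogeny inference, branch-level
  signature mapping, and variant calling are out of scope; the package
  starts from called SNVs and a reference catalog.
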