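# sigtempo

Temporal mutational-signature analysis for multi-sample tumor cohorts.

In metastatic cancer, mutations shared by **all** of a patient's tumor
samples ("early") were likely acquired before dissemination, while
mutations absent from at least one sample ("late") are enriched for events
that arose afterwards, possibly under metastatic-site mutational
processes. sigtempo stratifies per-patient somatic SNVs by this sharing
rule, builds SBS96 trinucleotide profiles for each timing class, refits
them against a reference signature catalog while prioritizing the
signatures expected at a chosen tumor site, and scores each fit so that
the sites whose expected signatures genuinely explain the spectrum stand
out. It is aimed at analysts studying how mutational processes shift
between primary and metastatic environments, and at anyone prototyping
signature-based tumor-origin reasoning.

## The model

Each profile is decomposed by restricted non-negative least squares into
fractions $S_i$ of reference signatures, using only the signatures with
positive prevalence in the cancer type the prioritized site maps to;
fractions below 0.01 are pruned and the fit re-solved. If the
reconstruction's cosine similarity $CS_m$ falls below 0.85, a greedy
rescue admits out-of-site signatures one at a time while each admission
improves $CS_m$ by at least 0.02. The fit is then scored by the
frequency-weighted **Signature Score**

$$SS_m = CS_m \sum_i S_i f_i, \qquad
  SE_m = CS_m \sqrt{\textstyle\sum_i S_i^2 f_i (1-f_i) / N_i},$$

where $f_i$ is the fraction of patients of that cancer type carrying
signature $i$ in a reference cohort of size $N_i$. High $SS_m$ requires
both a good reconstruction and a biologically plausible composition;
pairwise score differences are tested with a z-statistic on the pooled
SEs. See the vignette (`vignettes/temporal-signatures.Rmd`) for
assumptions and design details.

## Worked example

Simulate a small metastatic cohort (7 patients, 4 sites each, early
mutations dominated by a primary-site signature), split one patient's
mutations by timing, and refit the early profile under two site
prioritizations:

```r
library(sigtempo)

cfg <- simulation_config(seed = 7)
sim <- generate_cohort(cfg)

p   <- sim$cohort[["SIM001"]]
ann <- classify_early_late(p)
table(ann$timing)
#> EARLY  LATE
#>   300   200

prof <- build_profile96(ann[ann$timing == "EARLY", ], "SIM001:EARLY")
fit  <- refit_signatures(prof, sim$catalog, sim$prevalence, sim$mapping, "Lung")
fit
#> Site-prioritized signature refit
#>   profile: SIM001:EARLY (300 mutations)
#>   prioritized site: Lung -> lung
#>   fractions:
#> SBS-A SBS-B
#>  0.65  0.35
#>   CS = 0.899  SS = 0.656  (SE = 0.0125 )

fit_met <- refit_signatures(prof, sim$catalog, sim$prevalence, sim$mapping, "Brain")
fit_met
#> ...
#>   CS = 0.899  SS = 0.22  (SE = 0.00644 )
#>   rescue stage admitted out-of-site signature(s)

compare_scores(fit, fit_met)
#> Score comparison: delta = 0.4362244  z = 30.98788  p = < 2.22e-16
```

Both prioritizations reconstruct the spectrum equally well (CS 0.90) and
recover the generating 0.7/0.3 mixture, but only the primary site expects
the dominant signature — at the metastatic site it enters via the rescue
stage and earns prevalence weight zero, so the Signature Score drops from
0.66 to 0.22. That asymmetry, not raw goodness-of-fit, is what localizes
the early mutational process to the primary site.

The whole pipeline — QC filter, per-site refits for both timing classes,
score and comparison tables, run report — is one call:

```r
res <- run_cohort(sim$cohort, sim$catalog, sim$prevalence, sim$mapping,
                  out_dir = "results/run1")
head(res$scores)
```

A thin command-line wrapper with `run`, `simulate` and `score`
subcommands ships in `inst/scripts/sigtempo`.

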