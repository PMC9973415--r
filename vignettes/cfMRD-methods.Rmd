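---
title: "Methods: multi-modal cfDNA monitoring with cfMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal cfDNA monitoring with cfMRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cfMRD implements a longitudinal liquid-biopsy analysis for minimal residual
disease monitoring: per-sample metrics computed from plasma cell-free DNA
(cfDNA) — copy number, fragment size, fragment-ratio profiles,
targeted-locus ratios, site-centered coverage, and a tumor-methylation
score — each expressed as a z-score against a healthy reference panel, and
finally integrated by a mixed-effect logistic model across serial
timepoints. This vignette records the models, their assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open.

## The cfMeDIP methylation caller

cfMeDIP-seq enriches methylated cfDNA; read counts in non-overlapping
300 bp windows therefore mix two populations. The caller models the count
$c_i$ of window $i$ as a two-component negative-binomial (NB) mixture:

* **Unmethylated component**: $\log \mu_0 = \beta_0 + \beta_1 \cdot
  \mathrm{GC}_i$, dispersion $\phi_0$ (variance $\mu + \mu^2/\phi$). It is
  fit once by NB regression (`MASS::glm.nb`) on windows with **zero CpGs** —
  which cannot be methylated, so they identify the background
  enrichment as a function of GC alone — and then frozen.
* **Methylated component**: $\log \mu_1 = \gamma_0 + \gamma_1 \cdot
  \mathrm{CpG}_i$, dispersion $\phi_1$. CpG count, not GC, is the covariate:
  immunoprecipitated signal scales with the number of methylatable sites.
* **Mixing weight** $\pi$: a single global probability that a CpG-bearing
  window is methylated. Posterior membership
  $r_i = \pi f_1(c_i) / (\pi f_1(c_i) + (1-\pi) f_0(c_i))$
  depends on both CpG density (through $f_1$) and coverage, which is how
  per-window methylation probability becomes a function of both without a
  covariate-dependent prior (which would not be identifiable here).

Estimation is EM: the E-step computes $r_i$ over CpG-bearing windows; the
M-step sets $\pi = \bar r$ and updates $(\gamma_0, \gamma_1, \phi_1)$ by a
weighted NB maximum-likelihood step (BFGS with analytic gradients, warm
started at the previous parameters and bounded to 15 iterations — a
generalized EM update, so the observed-data log-likelihood is
non-decreasing by construction; the trace is asserted in-loop by the test
suite). Iteration stops when the log-likelihood changes by less than `tol`
(default `1e-6`) or after `max_iter` (default 200). Zero-CpG windows enter
the likelihood only through the fixed component and carry posterior 0.

Numerical choices: initialization uses $\pi = 0.2$ and an NB regression on
the top count quartile of CpG-bearing windows for $\gamma$; densities are
combined on the log scale with log-sum-exp; degenerate $\pi$ (within
`1e-6` of 0 or 1) is flagged rather than an error. When the zero-CpG
counts show no real overdispersion the NB dispersion is unidentified; a
boundary likelihood-ratio test against a Poisson fit decides a flagged
Poisson fallback.

The **methylation score** of a sample is the sum of posterior
probabilities over the signature windows (range 0 to the number of
windows), so a fully methylated 77-window signature scores 77.

## Healthy-panel z-scores

Every genomic/fragmentomic metric is referenced to a panel of healthy
controls: per-feature mean and SD, with near-zero-SD features (SD
$< 10^{-8}$) excluded. Per-feature z-scores aggregate as
$\sum_i z_i / \sqrt{n}$ — signed and variance-normalized, so the aggregate
is unit-variance under the healthy null regardless of feature count — with
mean $|z|$ exposed as an alternate. A plain signed sum would scale with
the feature count and make panels of different sizes incomparable; because
published per-sample aggregates from the original analyses used an
unstated convention, their absolute values are not reproduced here.
Classification never depends on the convention: a sample is called
positive when its score strictly exceeds the healthy panel's own empirical
90th percentile (linear interpolation), computed on the same statistic.

**Fragment size**: distributions are converted to per-length proportions
(depth invariance) and z-scored per length over 90–150 bp, the
tumor-shifted band.

**Ratio profiles** (DELFI-adapted): short (90–150 bp) and long
(151–220 bp) fragments are counted in 100 kb bins (fragments assigned by
midpoint, so counting is a partition), GC-corrected by additive loess
(span 3/4; `corrected = raw − fitted + grand mean`, stable when fitted
values approach zero, unlike a ratio correction), summed into 5 Mb bins,
ratioed, and scaled to mean 0, unit SD. Targeted analyses (e.g. PRC1
binding sites, derepressed in aggressive uveal melanoma) restrict the
100 kb grid to bins overlapping at least one locus (any overlap counts)
and re-aggregate over that subset.

**Copy number**: 1 Mb binned counts are GC-corrected, depth-normalized to
the **median** bin (the median resists being dragged by large CNV events,
which would bias unaffected bins on small genomes), log2-ratioed against
the panel's per-bin median, and z-scored binwise on chromosomes 3, 6 and
8 — the uveal melanoma hallmark chromosomes. Each arm contributes
$|\sum z / \sqrt{n_a}|$ (absolute value, so chromosome 3 losses and 8q
gains both elevate the score) and arms combine with weights
$w_a = n_a / \sum n_a$. Upstream tumor-fraction estimation is treated as
an input; the positivity rule is strict: tumor fraction $> 0.03$.
Short-fragment mode (90–150 bp) refuses — an explicit status, not an
error — when post-pruning coverage is $\le 0.1\times$.

**Site-centered coverage**: composite depth at each offset within
±1000 bp of site centers (e.g. liver open-chromatin sites, liver being
the dominant relapse site), normalized so the outer flanks
(|offset| 750–1000 bp) average 1. The central coverage is the mean over
±30 bp; open chromatin in the contributing tissue depresses it, so lower
coverage gives negative z. GC re-weighting and mappability corrections
used by full nucleosome-profiling pipelines are deliberately out of
scope: the consumed quantity is the central-coverage z against a panel
built from the identical site list and flank, which cancels site-set
composition effects.

## The hypermethylation signature

Tumor-specific sites are selected from cohort-labelled methylation array
matrices. Betas are clipped to $[10^{-6}, 1-10^{-6}]$ and transformed to
M-values ($M = \log_2 \beta/(1-\beta)$), the scale on which array fold
changes are conventionally defined (the source analyses do not state the
scale; M is adopted). For each of the comparison cohorts, 50 samples per
cohort are subsampled (seeded, capped at cohort size) and a per-site
Welch t-test contrasts target vs comparison; Benjamini–Hochberg
adjustment is applied within each comparison. A site is *marked* in a
comparison when logFC $\ge 2$, adjusted $p < 0.05$, and the direction is
hyper-in-target; the signature keeps sites marked in **strictly more
than** 21 comparisons (exactly 21 is excluded). A moderated-t (limma)
variant would shrink per-site variances; at the effect sizes the
selection rule thresholds (2 M-units) the two agree, which the test suite
verifies by overlap against `limma::eBayes` — the vote rule, not the test
flavor, is the contribution. Selected sites map to the 300 bp window
containing their position; duplicate windows collapse.

## Integration

The six per-sample metrics are min-max scaled to [0, 1] over all rows and
fed to a logistic regression with a Gaussian random intercept per patient
(`lme4::glmer`, Laplace approximation). The source description
("logistic, Gaussian") is read as Bernoulli outcome + Gaussian random
effect; a fixed-effect logistic fit is the recorded fallback if the GLMM
fails. Labels follow the monitoring rule: baseline (tumor in place) and
timepoints at or after relapse are positive; everything else negative;
patients lost to follow-up are excluded from training but still receive
predictions. Cross-validation folds are assigned at the **patient** level
(never splitting a patient's timepoints across folds, which would leak
within-patient correlation); with 8 eligible patients the requested 10
folds cap at 8, with a warning. All predictions are population-level
(random effects zeroed) so held-out and never-seen patients are scored
identically. Integrated probabilities are reported relative to the cohort
baseline: the mean baseline probability is subtracted from every row, so
baseline rows average exactly 0 and trajectories read as change from
diagnosis; patients without a baseline draw simply do not contribute to
the baseline mean.

Per-metric performance uses the same single-metric mixed model with a
**likelihood-ratio** p-value against the intercept-plus-random-intercept
null, not a Wald statistic: on the separable trajectories this model is
designed to detect, Wald standard errors diverge (Hauck–Donner) and Wald
p-values approach 1 exactly when the signal is strongest.

## The synthetic cohort

The generators define the study conditions and carry their ground truth:

* **Clinical fixture**: an 11-patient table (6 relapsers; relapse at 3.1,
  6.0, 7.5, 12.3, 24.9 and 60.0 months; clinical copy-number calls per
  region) with a five-timepoint schedule (baseline, 2 weeks, 3, 6, 12
  months; calendar constants 0, 0.5, 3, 6, 12) and the documented
  collection exceptions, giving 46 collected samples. Shipped as
  version-controlled TSVs.
* **Fragment lengths**: a Gaussian mixture — analytically tractable, so
  the mixture CDF is a closed-form oracle for every distribution test.
  The healthy default (167 bp mono-nucleosome mode, SD 12, weight 0.92;
  120 bp sub-nucleosomal mode, SD 15, weight 0.08) yields a short-fragment
  proportion of ~0.15, matching healthy plasma; tumor-shifted samples
  raise the short-mode weight. Real spectra are not Gaussian (10 bp
  periodicity, di-nucleosome shoulder); nothing downstream depends on
  those features.
* **Genome model**: chromosome lengths, arm splits and blacklist are
  explicit; per-window GC and CpG tracks are deterministic functions of
  position (smooth sinusoid plus positional hash, zero-inflated CpG
  counts linked to GC), so windows at any width are reproducible without
  stored state, and the slow GC landscape shares its phase across
  chromosomes so no chromosome-level GC confound can masquerade as copy
  number.
* **CNV counts**: Poisson around `depth × (1 + tf × (multiplier − 1))`
  inside segments — the expected dilution of a clonal event at tumor
  fraction `tf` — with closed-form expectations as oracles.
* **cfMeDIP windows**: drawn from the caller's own generative model with
  known $(\pi, \beta, \gamma, \phi)$, CpG-zero windows forced
  unmethylated, so EM recovery is a parameter-recovery test, not a
  goodness-of-fit impression.
* **Methylation arrays**: site-level M means drawn once and shared across
  cohorts; planted sites shifted by the effect size (M-scale, because the
  selection rule thresholds M-scale logFC) in the target cohort only.
* **Metric trajectories**: latent ctDNA signal 1 at baseline, 0 after
  treatment for non-relapsers, and regrowing as
  $(t/t_\mathrm{relapse})^2$ toward relapse for relapsers (capped at 1);
  each metric is `baseline + slope × signal + patient intercept + noise`
  (defaults: slope 3, noise SD 0.5, intercept SD 0.3).

What passing tests on these data do **not** show: robustness to GC-bias
forms unlike the planted ones, to non-Gaussian fragment spectra, to
array probe artifacts, or to real inter-patient biology; the recovery
tests certify the statistical machinery, not clinical performance.

## Known limitations and problem sizes

* Timepoints immediately *before* relapse carry high latent signal but a
  negative label under the at-or-post-relapse rule; they are
  irreducibly ambiguous, which bounds cross-validated accuracy on
  simulated cohorts (typically 0.75–0.97 across seeds, ≥ 0.9 at the
  documented default conditions).
* With 8 eligible patients, patient-grouped CV means every fold's test
  set is one patient; fold-level variance is correspondingly high.
* The mixture caller assumes a single global $\pi$ per sample and NB
  dispersions per component; per-region mixing or covariate-dependent
  priors are out of scope.
* Test and demonstration problem sizes — 20,000 methylation windows,
  10,080 array sites across 34 cohorts of 50, 30-sample healthy panels,
  20-seed detection experiments, 60 Mb toy genomes with 1 Mb/100 kb/5 Mb
  grids — were chosen so closed-form and brute-force oracles are exact
  companions at cohort-realistic signal-to-noise; they are the package's
  documented defaults for reproducing its own results.
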