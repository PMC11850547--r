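---
title: "Reference microbiome profiles from paired body habitats: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference microbiome profiles from paired body habitats: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(microref)
library(dplyr)
```

## The problem

Clinical laboratory measurements are reported against reference intervals:
the central 95% of a healthy reference population. Microbiome sequencing
resists this framing for two reasons. First, 16S amplicon counts are
*compositional* — each sample's counts are scaled by an unknown per-sample
sampling fraction (library size, extraction efficiency), so raw abundances
are not comparable across samples or people. Second, between-person
variability of microbiome composition is large, so absolute abundances in
any single habitat make poor reference measures.

`microref` implements a reference framework built around a quantity that is
robust to both problems: the **within-subject log fold change (logFC)**
of each taxon's abundance between two body habitats (e.g. stool vs saliva)
sampled from the same person at the same time. Taking the difference within
a subject cancels the subject's own scale; correcting for the difference of
the two samples' sampling fractions makes the remainder comparable across
people. A healthy cohort then yields, per taxon, a reference range for this
logFC, and a new subject can be screened by asking which of their taxon
logFC values fall outside the healthy ranges.

## The paired differential-abundance model

For subject $i$, habitat $h \in \{A, B\}$ and taxon $t$, observed counts are
modeled as

$$ \log O_{iht} = \alpha_t \pm \gamma_t/2 + u_i + c_{ih} + \varepsilon_{iht}, $$

where $\alpha_t$ is the taxon's baseline log abundance, $\gamma_t$ the
habitat logFC of interest (natural-log scale throughout), $u_i$ a subject
effect, $c_{ih}$ the log sampling fraction of sample $(i,h)$ — the nuisance —
and $\varepsilon$ residual noise. `fit_paired_da()` estimates $\gamma_t$ as
follows:

1. $y_{iht} = \log(O_{iht} + 1)$ (pseudo-count 1, configurable);
2. within-subject differences over complete pairs,
   $d_{it} = y_{iAt} - y_{iBt}$, which cancel $\alpha_t$ and $u_i$;
3. the per-subject nuisance offset $\hat\delta_i = \mathrm{mean}_t\, d_{it}$,
   an estimate of $c_{iA}-c_{iB}$ *plus* the cross-taxon mean of $\gamma$;
   residuals $e_{it} = d_{it} - \hat\delta_i$;
4. raw per-taxon estimates $\tilde\beta_t = \mathrm{mean}_i\, e_{it}$. By
   construction $\sum_t \tilde\beta_t = 0$: the estimates are
   *grand-centered*, shifted by the (unknown) mean true fold change;
5. that shared shift is located by `estimate_bias_em()` (below) and
   subtracted: $\hat\beta_t = \tilde\beta_t - \hat b$;
6. $SE_t = \mathrm{sd}_i(e_{it})/\sqrt{n}$, two-sided normal p-values,
   Benjamini–Hochberg q-values, and 95% CIs
   $\hat\beta_t \pm 1.96\,SE_t$. Taxa with $q < 0.05$ are called
   differentially abundant (threshold configurable).

**Assumptions.** Counts enter through $\log(O+1)$, so the model is a
log-linear approximation that is accurate for taxa observed at moderate
counts and attenuated for taxa near the detection limit (the pseudo-count
perturbs $\log O$ by roughly $1/O$). Differential taxa must be a minority,
or their mass must roughly cancel, for the E-M step to identify the null
bulk. Standard errors ignore the (shared, $O(1/\sqrt{Tn})$) sampling error
of $\hat b$ itself.

### The E-M bias step

After grand-centering, the raw estimates of *non-differential* taxa cluster
at $-\overline{\gamma}$ rather than 0. `estimate_bias_em()` fits univariate
Gaussian mixtures with $K = 1, 2, 3$ components by expectation-maximization
(two deterministic quantile-based initializations per $K$, at most 500
iterations, log-likelihood tolerance $10^{-8}$, component-sd floor at
$10^{-3}\,\mathrm{sd}(x)$ to prevent single-point collapse), selects $K$ by
BIC, and returns the mean of the component with the largest total
membership. Ties break to the component whose mean is closest to the
overall median; with fewer than 10 inputs the median is returned and
flagged. The estimator is deterministic given its input. In the default
generator the planted fold changes alternate in sign, so the mixture the
E-M faces is asymmetric with a dominant null component — the regime the
selection rule is designed for.

### Per-subject profiles

For a *new* subject (not part of the reference fit), `per_subject_logfc()`
computes $d_t$ from the subject's pair and anchors it to the reference fit:
the subject's offset is $\hat\delta = \mathrm{median}_t(d_t - \hat\beta^{ref}_t)$
and the profile is $f_t = d_t - \hat\delta$. The median (not the mean) is
used deliberately: in a diseased subject, a subset of taxa is shifted, and a
mean offset would absorb part of that signal into the nuisance; the median
is robust as long as fewer than half the taxa are disease-shifted.

## Reference intervals and screening

`alpha_reference_interval()` implements the classical reference-interval
recipe for alpha-diversity indices: exclude outliers (Tukey 1.5 IQR fences
by default; `"3sd"` and `"none"` are available — the outlier rule is a
documented choice, not a canonical one), then take the 2.5th and 97.5th
percentiles with linear interpolation between order statistics
($h = (n-1)q + 1$, `quantile()` type 7). Intervals from fewer than 20
values are flagged.

`taxon_reference_ranges()` takes each taxon's screening range verbatim from
the reference cohort's 95% CI of the mean logFC, and `screen_cohort()`
flags a subject in-range when $f_t$ lies in the closed interval. Taxa
whose in-range proportion is 0 (no screened subject inside; threshold
configurable) form the selected profile.

**A statistical caveat that matters.** The CI of the *mean* logFC has
half-width $1.96\,\hat\sigma_t/\sqrt{n}$, while an individual subject's
$f_t$ fluctuates with sd $\approx \hat\sigma_t$. A healthy subject
therefore lands inside the range with probability
$\approx P(|Z| < 1.96/\sqrt{n})$ — about 0.17 at $n = 80$ — *regardless of
the noise scale*. Two consequences follow. Screening a disease cohort
against these narrow ranges is very sensitive: a planted disease effect
well above $\hat\sigma_t$ is detected in essentially every subject. But the
same arithmetic makes the rule anti-conservative on healthy cohorts: with
10 screened healthy subjects, each null taxon is selected with probability
$\approx 0.83^{10} \approx 0.15$, i.e. tens of false selections per 150
taxa. The package's calibration suite measures exactly this behaviour.
Because the CI-as-range rule is the published procedure, it is the default;
`taxon_reference_ranges(mode = "prediction")` provides a prediction-style
alternative, $\hat\beta_t \pm 1.96\,\hat\sigma_t\sqrt{1 + 1/n}$, which
targets the spread of an individual subject, keeps healthy cohorts almost
entirely in range, and is clearly labeled as a departure from the published
rule. Profile selection is monotone in the threshold, so tightening or
relaxing it never behaves erratically.

`pca_separation()` summarizes group structure on the selected taxa:
column-centered (unscaled) PCA by SVD, plus a separation score — the
distance between group centroids in the PC1–PC2 plane divided by the pooled
within-group sd of sample-to-centroid distances (denominator
$\sqrt{\sum d^2/(n - G)}$).

## Diversity and association statistics

Alpha diversity uses base-2 logarithms (bits) by default: Shannon
$H = -\sum p_t \log_2 p_t$, Simpson $D = 1 - \sum p_t^2$, Pielou
$J = H/\log_2 S$ ($J$ is undefined and reported missing when $S = 1$,
and such samples are excluded from reference-interval input). The base is
configurable (`base = exp(1)` for nats); base-2 Shannon over a few hundred
taxa spans the 5–8.2 range typical of published habitat intervals.
Rarefaction subsamples without replacement to a configurable depth
(default: the minimum sample total) and reports dropped samples rather than
silently keeping under-sampled ones.

Beta diversity (Bray–Curtis, unweighted UniFrac), PERMANOVA and the Mantel
test delegate to vegan/picante — the field-standard implementations —
behind small validating wrappers; unweighted UniFrac was verified against
an exhaustive branch-partition enumeration, which remains in the test
suite. Permutation p-values respect the $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$
floor and are seeded. The contingency test follows the standard
expected-count rule — Fisher's exact test when any expected cell is below
5, else Pearson chi-square without continuity correction (Yates toggleable);
this rule reproduces both published cohort-table p-values (0.048 for
alcohol, 0.339 for sex). The rank-sum test enumerates all
$\binom{n}{n_A}$ assignments on midranks when the pooled $n \le 20$ —
exact even under ties — and otherwise uses the tie-corrected normal
approximation.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts from the latent model above, with known
ground truth returned alongside the counts. Its defaults emulate the
motivating study design: 171 reference subjects and 10 disease (PD)
subjects across blood, saliva and stool, with the exact partial-pairing
structure (117/124/98 samples per habitat; 77, 65 and 72 complete pairs for
blood–saliva, saliva–stool and blood–stool), solved by inclusion–exclusion
(46 subjects carry all three habitats). Defaults for the signal follow the
calibration design used throughout the tests: 150 taxa, 10% differential at
$|\gamma| = 2$ with alternating signs, log-normal depths with
$\sigma = 0.5$, and a PD effect of magnitude 3 on 5 planted taxa.

Values the study does not report were fixed once at field-plausible levels
and not revisited:

| parameter | default | why |
|---|---|---|
| `baseline_log_mean`, `baseline_log_sd` | 0, 1.5 | log-normal baseline spanning ~3 orders of magnitude of relative abundance, typical of amplicon tables |
| `subject_sd` | 0.5 | moderate person-to-person scaling; cancels in pairs by design |
| `noise_sd` | 0.5 | residual per-sample, per-taxon biological/technical noise |
| `depth_log_mean` | log(30 000) | ~30k reads/sample, a routine MiSeq per-sample yield |
| depth floor | 100 reads | prevents degenerate near-empty samples |
| `pd_habitat` | saliva | the modeled disease is periodontal, i.e. oral; configurable |
| truncated normals | rejection sampling | simple and exact |

Counts are multinomial given the latent relative abundances, so the
generator is compositional by construction: expected relative abundances do
not depend on depth, and column sums equal realized depths exactly.
`redraw_counts()` re-draws any habitat's counts from the *stored* latent
composition at a rescaled depth, which is what makes clean
depth-invariance experiments possible.

**What the generator does not emulate:** taxon–taxon correlation
(interaction networks), zero inflation beyond multinomial undersampling,
overdispersion (e.g. Dirichlet-multinomial), taxonomy misclassification,
and sequence-level artifacts (chimeras, ASV inference error). Passing
calibration on these cohorts therefore demonstrates correctness of the
estimators under the stated model, not robustness to every property of
real amplicon data.

## Numerical choices and conventions

- Pseudo-count 1 before logs; natural-log fold changes everywhere.
- "Abundant" in calibration checks is judged on the log scale
  (geometric-mean count), because the estimator averages log counts and
  arithmetic means are dominated by a few deep samples; the
  depth-invariance check uses geometric-mean count ≥ 50, where the
  pseudo-count perturbation (≈ 0.9/count) is an order of magnitude below
  the 0.1 bound being verified.
- Closed screening intervals: boundary values count as within.
- Degenerate cases are flagged, not silently dropped: zero-width ranges,
  PERMANOVA on an all-zero distance matrix, E-M fallback below 10 inputs.
- All stochastic steps accept a seed; a fixed seed reproduces outputs
  byte-identically.
- Problem sizes in the calibration suite: 100 replicate cohorts of 80 pairs
  × 150 taxa for estimator recovery and null calibration, 200 replicates
  for permutation-test calibration, 50 replicates for screening recovery —
  sizes at which binomial noise on the measured rates is a few percent.

## Known limitations

- Standard errors omit the variance of the E-M bias term (small, shared
  across taxa).
- The log(O+1) transform attenuates fold changes of taxa observed at very
  low counts; published profiles carry the same caveat for low-abundance
  taxa.
- The CI-as-screening-range rule is anti-conservative on healthy cohorts
  (see above); the prediction-interval mode is the statistically
  conventional alternative but departs from the published procedure.
- Single-factor PERMANOVA only; no covariate-adjusted differential
  abundance; no weighted UniFrac.
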