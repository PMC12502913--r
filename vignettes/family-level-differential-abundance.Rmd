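---
title: "Family-level differential abundance of small non-coding RNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-level differential abundance of small non-coding RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncfam)
```

## The problem

Small non-coding RNA sequencing yields thousands of unique fragment
*species* — distinct sequences derived from longer parental RNAs such as
tRNAs, rRNAs and Y RNAs. Fragments of one parent (a *family*, e.g. all
pieces of genomic tRNA-Gly-GCC) tend to move together between biological
conditions, but each individual species is noisy and lowly expressed.
Summing reads per parent discards the per-species signal structure; testing
each species separately multiplies the testing burden and the noise.
`sncfam` aggregates statistically rather than arithmetically: all species
of a family contribute observations to a single family-level test.

## The multi-sample model

For a family with $n$ species and $m$ samples we stack the
log10-transformed RPM values species-major into a response
$E \in \mathbb{R}^{nm}$ and fit by ordinary least squares

$$E = \beta_0 + \beta_1 G + \beta_2 \mathrm{RNA}_2 + \dots +
      \beta_n \mathrm{RNA}_n + \varepsilon,$$

with $G$ the per-sample phenotype repeated per species block (binary 0/1 or
continuous) and $\mathrm{RNA}_i$ species indicators. The indicators absorb
each species' baseline abundance, so $\beta_1$ measures the shared
abundance shift of the family in log10-RPM units per phenotype unit. The
family call is the t-statistic of $\beta_1$ on $nm - (n + 1)$ residual
degrees of freedom and its two-sided Student-t p-value.

Assumptions worth stating plainly:

* *One direction of dysregulation per family.* The model pools species
  under a single $\beta_1$; a family whose members move in opposite
  directions will average toward zero.
* *Independent observations.* Species of a family are treated as
  independent given their own baselines; no within-species or
  within-sample correlation structure is modelled. The synthetic null
  simulations below show the resulting test is calibrated when species
  noise is independent; correlated species noise would make it liberal.
* *Additive effects on the log scale*, i.e. multiplicative fold changes on
  RPM.

With $n = 1$ (possible only when the two-species family constraint is
explicitly bypassed) the model collapses to the pooled-variance two-sample
t-test, which the test suite verifies against the closed form.

### Degenerate fits

A family whose log-abundances are constant within every species has zero
residual variance. Rather than reporting a 0/0 t-statistic, the fit
reports $t = 0, p = 1$ when the phenotype coefficient is numerically zero
and $t = \pm\infty, p = 0$ when a perfect nonzero fit occurs (detected at
relative tolerance $10^{-10}$ on the residual standard deviation).
Rank-deficient designs and insufficient degrees of freedom abort the
single-family fit; in cohort runs (`run_family_lm()`) such families become
`NA` rows with a reason code while the remaining families proceed, and the
Bonferroni multiplier conservatively counts every family attempted.

## The paired test

For one sample pair the family profile is compared by the Wilcoxon
signed-rank test over its species: $d_i = e_{i,s_1} - e_{i,s_2}$, zero
differences excluded, average ranks on $|d_i|$, and rank sums $W^+$ (over
$e_{i,s_1} > e_{i,s_2}$) and $W^-$. Direction is read off the rank sums
($W^+ > W^-$: up in $s_1$). The p-value is two-sided throughout; direction
is reported separately so a nondirectional p never hides the sign.

Numerical conventions, each of which the suite tests explicitly:

* **Zero differences** are excluded (Wilcoxon's convention); the effective
  family size `n_effective` is reported. `n_effective = 0` yields $p = 1$,
  direction `tie`.
* **Ties in $|d|$** get average (mid) ranks. $W^+ + W^- =
  n_e(n_e+1)/2$ holds exactly on every input.
* **Exact vs approximate p.** The exact null distribution of $W^+$ is
  computed by the subset-sum count recursion (equivalent to enumerating all
  $2^{n_e}$ sign assignments, which the tests do independently) whenever
  $n_e \le 25$ and the absolute differences are tie-free; the two-sided
  value doubles the smaller tail, capped at 1. Otherwise a normal
  approximation with tie-corrected variance and continuity correction is
  used. The 25-species threshold keeps the exact path cheap
  ($2^{25}$ assignments summarised by a vector of length 326) while the
  normal approximation is already excellent at that size; the cutoff is
  configurable and the method used is always reported per family.
* **Direction ties** ($W^+ = W^-$) are reported as `tie`, never assigned
  arbitrarily.

## Filtering and multiplicity

The pipeline applies, in order: species inclusion at mean RPM strictly
greater than 0.1 across the designated samples (cohort-wide by default; a
pair-scope option exists for standalone 1-on-1 runs); family membership
from parental annotations with multi-mapping species joining every family
they map to; families constrained to 2–1000 species, oversized families
truncated to the 1000 highest mean-RPM members (ties broken by species id
for determinism); Bonferroni correction with the number of families tested
as multiplier; significance at adjusted $p < 0.05$. An option restricts
the analysis to uniquely annotated species, after which the family-size
constraints are re-applied — stricter against multi-mapping artifacts, at
a cost in sensitivity for families rich in shared sequences.

RPM uses the per-sample column sums of the input table as denominators by
default, because the table is the only guaranteed input; externally
determined totals (e.g. total clean reads) can be supplied. The log
transform uses $\log_{10}(\mathrm{RPM} + \epsilon)$ with $\epsilon = 0.01$
— one decade below the inclusion cut, so the offset only shapes values
already near the detection floor. Because the inclusion filter guarantees
mean RPM > 0.1, the distortion of the linear model by the offset is
negligible for retained species; $\epsilon$ is nevertheless configurable
and documented because it is the one modelling constant the data do not
pin down.

## The synthetic cohort generator

`simulate_ms_cohort()` draws species baselines $\mu_i \sim
U(0.5, 2.5)$ in log10 RPM (roughly 3–300 RPM, comfortably above the
filter), adds the family's true shift $\gamma_f x_s$ for the non-reference
group and Gaussian noise $\sigma = 0.3$ log10 units, then quantises to
counts at a library size of $10^7$ reads (a typical small-RNA depth; the
returned RPM is recomputed from the rounded counts so the table is
internally exact, and the quantisation perturbs log abundances by well
under 0.01 at the default depth). Defaults — 5 species per family,
5 + 5 samples, effect size 0.5, 20% of families shifted — mirror the
validation conditions used throughout the tests.

`simulate_paired_cohort()` gives each member of a pair its own symmetric
noise around a shared species baseline: $s_1 = 10^{\mu_i + e_1}$,
$s_2 = 10^{\mu_i + \gamma_f + e_2}$ with independent $e_1, e_2 \sim
N(0, \sigma^2)$, the shift applying to the second condition (e.g. tumor).
Under $\gamma = 0$ the two profiles are exchangeable, so the paired
differences are symmetric about zero — exactly the null under which the
signed-rank test is valid. The asymmetric alternative (noise on one side
only) is *not* exchangeable: $|d|$ then correlates with the sign of $d$
and the "null" is not a null. We chose the exchangeable form deliberately
so that null calibration is a meaningful property to test. Paired
families default to 20 species because a signed-rank test on 5 species
cannot reach $p < 0.05$ two-sided at all ($\min p = 2/2^5 = 0.0625$).

What the generator does *not* emulate: correlated noise between species of
a family (an optional shared random effect would make the ms test liberal,
and real families likely sit between the two regimes), compositional
coupling between families competing for library mass, sequencing
zero-inflation at the detection floor, and annotation ambiguity patterns.
Passing calibration and recovery tests on these synthetic cohorts
therefore demonstrates correctness of the statistical machinery under the
model's own assumptions, not robustness to every feature of real data.

## Evaluation machinery

* `resample_robustness()` redraws $n$ samples per group without
  replacement (independently across rounds, 100 rounds by default),
  reruns the family model, and correlates each round's t-vector with the
  full-data one. Families failing in any round are dropped from the matrix
  rather than NA-imputed so correlations stay well defined. A fixed seed
  makes the report bit-reproducible.
* `tstat_concordance()` computes the Pearson correlation of family
  t-statistics between two cohorts and lists common hits (significant in
  both, same direction).
* `coverage_profile()` sums species RPM over their annotated
  $[\mathrm{start}, \mathrm{end}]$ intervals (1-based inclusive; strand
  ignored since parents are single-stranded references) per position, then
  averages across samples with SEM $= s/\sqrt{n}$ ($n - 1$ denominator;
  single-sample groups get SEM 0 with a warning). Coverage uses RPM, not
  raw counts, so profiles are comparable across samples. Total depth per
  sample equals $\sum_i \mathrm{rpm}_i \cdot \mathrm{span}_i$, a
  conservation law the tests check on random interval fixtures.
* `concordance_summary()` turns per-pair results into per-family fractions
  of patients significantly up, down, or not significant; the fractions
  are exact ratios of pair counts and sum to 1.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at the following
scales, chosen to make the binomial noise of the estimated rates small
relative to the acceptance bands: 2000 null families for the type-I rate
of the multi-sample model (binomial SE $\approx 0.005$ at a nominal 0.05)
and for the paired null; 200 families for effect recovery at
$\gamma = 0.5$; 500 families per effect size for the power comparison; 20
random small designs against the brute-force least-squares oracle; 100
random tie-free instances against full sign-assignment enumeration; 100
resampling rounds.

## Known limitations

* The linear model ignores within-family correlation of species noise;
  with strongly co-regulated fragments the type-I rate will exceed the
  nominal level. The unique-annotation option removes one source of such
  coupling (shared sequences) but not biological co-regulation.
* The paired test's exact path requires tie-free $|d|$; heavily quantised
  RPM values (shallow libraries) push families to the approximate path,
  which is reported per family.
* Family assignment is rule-based on annotation strings; the shipped rules
  cover the common tRNA/rRNA/yRNA/snRNA/snoRNA/miRNA naming conventions
  and anything else should be supplied as a custom rule set (regular
  expression → family template). Unmatched annotations are reported, not
  dropped, so rule gaps are visible.
* Bonferroni control is deliberately conservative, matching the
  family-level testing convention this package implements; no FDR option
  is exposed.
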