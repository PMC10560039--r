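---
title: "Two-sample MR screening, sensitivity analysis and mediation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening, sensitivity analysis and mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The problem

Observational associations between modifiable risk factors and disease are
confounded and subject to reverse causation. Two-sample Mendelian
randomization (MR) sidesteps both by using genetic variants as instrumental
variables: per-variant effects on an exposure (from one GWAS) are combined
with per-variant effects on an outcome (from another GWAS) into an estimate
of the causal effect of exposure on outcome. The design rests on three
assumptions: instruments are robustly associated with the exposure
(relevance), independent of confounders of the exposure–outcome relation
(independence), and affect the outcome only through the exposure (exclusion
restriction). The third is the fragile one — horizontal pleiotropy — and
most of this package is machinery for estimating the causal effect under
progressively weaker versions of it, and for diagnosing when it bites.

`mrscreen` implements the full workflow at summary-statistics level: a
multi-exposure screen across a discovery and a replication cohort, a
fixed-effect meta-analysis of the two, and a two-step mediation analysis
that decomposes an exposure's total effect into mediator-specific shares.
Because real GWAS inputs are large and external, the package ships a
synthetic summary-statistics generator with known ground truth; every
statistical claim in the test suite is checked against that truth or against
an independent closed-form oracle.

# Model and estimators

For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its estimated
effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its estimated
effect on the outcome, both per copy of the same effect allele. Under the IV
assumptions each variant yields a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard error
$\sigma_{Yj}/|\hat\gamma_j|$. The first-order SE deliberately ignores
$\sigma_{Xj}$: under that convention the inverse-variance-weighted (IVW)
combination of ratios is algebraically identical to a weighted regression of
$\hat\Gamma$ on $\hat\gamma$ through the origin with weights
$1/\sigma_{Yj}^2$, which is the form every other estimator builds on. A
second-order SE is available via `mr_wald_ratio(second_order = TRUE)`.

* **IVW** (`mr_ivw`): $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$,
  $w_j = 1/\mathrm{se}(\hat\beta_j)^2$. The default is a multiplicative
  random-effects model: the fixed-effect SE $1/\sqrt{\sum w_j}$ is scaled by
  $\sqrt{\max(Q/(L-1),\,1)}$ where $Q$ is Cochran's statistic over $L$
  instruments. The floor at 1 means under-dispersion never shrinks the SE
  below its fixed-effect value; consequently the fixed-effect variance never
  exceeds the random-effects variance, with equality exactly when
  $Q \le L-1$.
* **MR-Egger** (`mr_egger`): the same weighted regression *with* an
  intercept. The slope is consistent under the weaker InSIDE assumption
  (instrument strength independent of direct effects); the intercept
  estimates the average directional pleiotropic effect and is itself the
  pleiotropy test (`egger_intercept_test`). Because the model is not
  invariant to per-SNP allele reorientation, all exposure betas are made
  positive (flipping both axes SNP-wise) before fitting. SEs carry the same
  multiplicative scaling with $L-2$ degrees of freedom, and inference uses
  the $t_{L-2}$ distribution.
* **Weighted median** (`mr_weighted_median`): order the ratios, attach
  normalized weights $w'_j$, form $s_j = \sum_{k\le j} w'_k - w'_j/2$, and
  interpolate linearly where $s$ crosses $1/2$. Consistent when instruments
  carrying at least half the total weight are valid. With equal weights it
  reduces to the sample median. The SE comes from a parametric bootstrap —
  each ratio resampled as $N(\hat\beta_j, \mathrm{se}(\hat\beta_j))$ —
  with 1,000 seeded replicates by default.
* **Simple and weighted mode** (`mr_mode`): the mode of a Gaussian kernel
  density over the ratios (inverse-variance weights for the weighted
  variant), consistent when the largest group of instruments sharing one
  ratio value is valid. The bandwidth is
  $1.06 \cdot \min(\mathrm{SD}, \mathrm{MAD}/0.6745)\cdot L^{-1/5}$, a
  normal-reference rule with a robust spread so a single wild ratio cannot
  flood the bandwidth; `bandwidth_factor` rescales it. If all ratios
  coincide the common value is returned. SEs are bootstrapped as above.
* **Multivariable IVW** (`mr_mvmr_ivw`): weighted regression of outcome
  betas on a matrix of exposure betas through the origin, solved from the
  normal equations, giving one *conditional* estimate per exposure with the
  multiplicative scaling $\sqrt{\max(Q/(L-k),1)}$. Rank-deficient designs
  raise an error naming the collinear columns; a column of exact zeros is
  dropped from the fit (reported as not estimable) so the remaining
  estimates reduce exactly to the lower-dimensional model.

Minimum instrument counts are enforced throughout: 1 for the Wald ratio, 2
for IVW, 3 for Egger/median/modes, $k+2$ for MVMR with $k$ exposures.
`mr_all()` runs every applicable method and marks the rest not-applicable;
a single-instrument "IVW" request degrades to the Wald ratio, its exact
one-term special case.

P-values are two-sided normal everywhere except the Egger slope and
intercept ($t_{L-2}$); 95% CIs are $\pm 1.96\,\mathrm{se}$. These are
conventions, stated here because different MR implementations vary on them.

# Instrument selection and harmonization

`select_instruments()` keeps exposure variants with $p < 5\times10^{-8}$ and
prunes them by greedy LD clumping: sort by ascending p-value (ties broken
lexicographically by variant id, for determinism), keep the best remaining
variant, discard every remaining variant on the same chromosome within
5,000 kb whose $r^2$ with it is at least 0.01, repeat. The distance figure
is read as the window within which LD pruning applies — standard clumping
semantics. LD arrives as a plain pairwise $r^2$ table; absent pairs count as
$r^2 = 0$, and duplicate entries for a pair collapse to their maximum (the
conservative choice for pruning). On small instances the greedy result
provably equals exhaustive enumeration of maximal conflict-free sets chosen
in the same priority order; the test suite checks 500 random instances
against that oracle.

`harmonize()` aligns outcome records to the exposure's effect allele:
matching orientations copy, swapped alleles negate the outcome beta and
reflect its allele frequency (flagged `flipped`), and strand-complement
representations reconcile the same way. Palindromic variants (A/T, C/G)
cannot be oriented from labels; the default policy keeps them only when
both studies' effect-allele frequencies fall outside the ambiguous band
(0.42, 0.58) and then aligns by frequency, `drop` removes them all, and
`keep_all` trusts the labels. Anything irreconcilable is dropped with a
logged reason — never silently kept — and there is no proxy-variant search.
Harmonization is involutive: re-harmonizing an already-aligned set changes
nothing.

Instrument strength is summarized by the per-variant F statistic
$\hat\gamma_j^2/\sigma_{Xj}^2$ and by the variance explained
$2\,\mathrm{EAF}(1-\mathrm{EAF})\hat\gamma_j^2$ on the standardized scale
(the conventional formula; set-level $R^2$ is the sum over instruments). A
set-level mean F below 10 triggers the conventional weak-instrument warning.

# Sensitivity analyses

* **Cochran's Q** (`cochran_q`): $\sum w_j(\hat\beta_j - \hat\beta)^2$
  about the IVW estimate ($\chi^2_{L-1}$) or about the Egger fit
  ($\chi^2_{L-2}$). $Q = 0$ exactly when all ratios coincide. Both variants
  are always reported, since heterogeneity can implicate either model.
* **MR-PRESSO** (`mr_presso`): a parametric simulation framework around
  leave-one-out IVW fits. The observed residual sum of squares
  $\sum_j w_j(\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2$ is compared
  with `n_sim` simulated datasets drawn from
  $N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{Yj})$ (leave-one-out slopes
  recomputed per draw); the global p-value uses the add-one estimator
  $(1 + \#\{RSS^* \ge RSS\})/(n_\mathrm{sim}+1)$, so it is floored at
  $1/(n_\mathrm{sim}+1)$ and can never be zero. Per-variant residuals get
  the same treatment with Bonferroni adjustment across $L$; variants
  significant at 0.05 are removed automatically (with the removal list
  logged) and IVW re-estimated — reproducible automation of what is often
  done by hand. A distortion test compares the raw-vs-corrected shift with
  shifts from removing random subsets of the same size. Note a practical
  floor interaction: with $L$ instruments the Bonferroni-adjusted p cannot
  fall below $L/(n_\mathrm{sim}+1)$, so `n_sim` must exceed $L/\alpha$
  (e.g. 1,000 sims for 30 instruments at $\alpha = 0.05$); the function
  warns when it cannot.
* **Leave-one-out** (`leave_one_out`): IVW re-estimated omitting each
  variant; omissions flipping the sign or moving the estimate by more than
  one full-set SE are flagged. The fixed-effect LOO slopes satisfy an exact
  algebraic identity — averaged with weights
  $S_{xx} - w_j \hat\gamma_j^2$ they return the full-set slope — which the
  tests use as an internal consistency check.
* **Plot data** (`plot_data`): the scatter table (per-variant effects with
  SEs plus one fitted line per estimator) and funnel table (ratio against
  precision, IVW reference) as plain TSV-ready data frames. Rendering is a
  convenience left to the caller; the tables are the deliverable.

# Meta-analysis and mediation

`meta_fixed()` pools per-cohort estimates with inverse-variance weights:
$\hat\beta_\mathrm{meta} = \sum b_i/s_i^2 \big/ \sum 1/s_i^2$,
$\mathrm{se} = (\sum 1/s_i^2)^{-1/2}$, plus a cross-cohort Q. Precision
strictly increases with each added cohort, and pooling $k$ identical
$(b, s)$ inputs gives $(b, s/\sqrt k)$.

`mediate()` runs the two-step decomposition for one mediator:

1. $\beta_1$: exposure → mediator, univariable IVW over the exposure's
   instruments.
2. $\beta_2$: mediator → outcome *conditional on the exposure*, the
   mediator coefficient from multivariable IVW over the union of exposure
   and mediator instruments. A univariable fit cannot deliver the
   adjusted effect; MVMR can.
3. Total: exposure → outcome, univariable IVW.

The indirect effect is $\beta_1\beta_2$; the mediation proportion is
$\beta_1\beta_2/\mathrm{total}$, reported as a percentage truncated to
$[0, 100]$ with the untruncated value retained, and a flag raised when the
indirect and total effects disagree in sign (a share is then not
interpretable as a proportion). The CI comes from the delta method on the
three-way ratio with cross-fit covariances set to zero — the three fits
share instruments, so this is an approximation, which is why a parametric
bootstrap over $(\beta_1, \beta_2, \mathrm{total})$ is available behind
`ci_method = "bootstrap"`; output labels which method produced the
interval. Totals below `total_floor` (default $10^{-6}$) flag the
proportion undefined rather than dividing by nearly zero.
`rank_mediators()` sorts mediators by point-estimate share, ties broken by
name.

# The synthetic-data generator

`simulate_summary_stats()` emulates the statistical regime of a
biobank-scale two-sample MR study, not any particular dataset:

* Instrument effects $\gamma_j \sim \pm N(0.03, 0.01^2)$ with random
  reported-allele sign; with the default exposure GWAS size
  $n = 200{,}000$ this puts the median per-variant F near 50 and the bulk
  of instruments in the strong range typical of published exposure GWASs.
* Standard errors follow GWAS sampling theory for a standardized trait,
  $\mathrm{se} = 1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})\,n}$, with EAF
  uniform on $[0.05, 0.95]$; binary outcomes are treated on the log-odds
  scale with $n$ read as an effective sample size (defaults 300,000 and
  390,000 for the two outcome cohorts, the scale of large case-control
  biobank analyses).
* Outcome effects are $\beta\gamma_j + \alpha_j$ plus sampling noise.
  Direct effects $\alpha_j$ are zero (`none`), zero-mean (`balanced`), or
  mean-shifted (`directional`). Directional effects are specified in the
  exposure-increasing-allele frame and co-flip with the instrument's
  reported sign: without that coupling a nonzero mean would wash out under
  random allele orientation and "directional" pleiotropy would be
  indistinguishable from balanced.
* Null variants come in LD blocks (default 5 variants at pairwise
  $r^2 = 0.5$); their estimates are correlated within block with
  correlation $\sqrt{r^2}$, and LD is emitted as the pairwise $r^2$ table
  clumping consumes — no genotypes are simulated.
* Ten percent of variants get palindromic alleles and 30% of
  outcome/mediator records are reported on the opposite allele, so
  harmonization is exercised on every run.
* Mediator chains add a `mediator_spec` $(b_1, b_2, b_\mathrm{direct})$ and
  a second set of variants instrumenting the mediator directly; the truth
  records the generating share $b_1 b_2/(b_1 b_2 + b_\mathrm{direct})$.
* Identical configs (including seed) reproduce byte-identical tables, and
  the caller's RNG state is never disturbed.

What the generator does **not** emulate: individual genotypes,
case-control liability-scale subtleties, population stratification,
realistic LD beyond exchangeable blocks, winner's curse in instrument
discovery, or sample overlap between the two GWASs. Tests passing on this
generator therefore demonstrate the estimators' statistical correctness
under the stated model, not robustness to everything real data can do.

For mediation experiments the package's test conditions use moderate chain
magnitudes (e.g. $b_1 = -0.5$, $b_2 = 0.2$, $b_\mathrm{direct} = -0.3$ for
a 25% share) so the total effect is estimable with desk-scale replicate
counts; real binary-outcome studies often sit at far smaller per-unit
effects, where only the much larger instrument counts of real GWASs make
the denominator stable.

# Numerical and design choices

* Clump ties at equal p-value break lexicographically; duplicate LD pairs
  collapse to their maximum $r^2$ — both for determinism.
* The multiplicative random-effects floor at 1 makes IVW/Egger/MVMR SEs
  weakly conservative in under-dispersed sets; the Egger intercept test
  consequently runs a shade below nominal size when there is no excess
  dispersion at all and close to nominal under balanced pleiotropy.
* Bootstrap SEs (median, modes) and all simulation-based diagnostics take
  explicit seeds; the pipeline derives per-task seeds deterministically
  from one base seed, which is what makes whole screen runs byte-identical.
* Degenerate inputs have defined behavior: a zero exposure beta is an
  undefined Wald ratio (error); identical ratios give $Q = 0$, $p = 1$ and
  a zero-bandwidth mode returning the common value; an empty estimate list
  still yields scatter/funnel tables; a sub-minimum instrument count is an
  error for the core estimators but a logged not-applicable marker inside
  the pipeline and MR-PRESSO, so a screen never aborts on a 2-instrument
  exposure.
* Screens apply no multiple-testing correction by default — findings are
  flagged at raw $p \le 0.05$ per cohort and in the meta-analysis — since
  the screen is a triage step; Bonferroni/FDR can be applied to the output
  table.

# Known limitations

* The first-order Wald SE ignores exposure-side noise, so IVW inherits
  mild weak-instrument attenuation; at median F near 30–50 the bias is
  about $1/F$ of the effect (visible as ~0.195 recovered for a true 0.2 at
  $n = 100{,}000$), shrinking at larger F.
* The delta-method mediation CI assumes independent fits; with heavily
  overlapping instrument sets the bootstrap option is the safer choice.
* MR-PRESSO's corrected estimate is not guaranteed to beat the raw one in
  any single dataset: one ratio displaced by $10\,\mathrm{se}$ among 30
  clean instruments shifts IVW by only $10/\sqrt{30} \approx 1.8$ of its
  own SE, so removal improves the point estimate in roughly
  $\Phi(0.9) \approx 82\%$ of replicates — the correction's value
  concentrates in heavier contamination. `analysis/04_calibration.R`
  measures this directly.
* Palindromic frequency-based rescue assumes comparable allele frequencies
  between the two study populations; across diverged populations `drop` is
  the safer policy.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run all stochastic checks at
fixed seeds with desk-scale sizes chosen for tight Monte-Carlo error at
interactive runtimes: 2,000 replicates for test calibration (type-I error
bands), 1,000 for CI coverage, 200 for recovery/robustness/mediation
experiments, 500 exhaustive clumping instances, and MR-PRESSO at 1,000
simulation draws. The analysis drivers under `analysis/` use 400
replicates for the same quantities.
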