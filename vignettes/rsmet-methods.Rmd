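---
title: "Models and methods behind rsmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rsmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmet)
```

rsmet evaluates recurrent-selection programmes from plot-level records of
field trials grown under two moisture regimes — restricted irrigation (RI,
one life-saving irrigation; the non-stress level) and rainfed (RF, no
irrigation; the stress level) — over one or more years, with replicates
nested within each treatment-by-year combination. This vignette documents
the statistical models, the defaults and why they were chosen, the numerical
conventions, and what the synthetic-data tests do and do not establish.

## The three-way random model

The observational model for one trait is the fully crossed, balanced
genotype x treatment x year layout:

$$y_{ijkl} = \mu + G_i + T_j + Y_k + GT_{ij} + GY_{ik} + GTY_{ijk}
            + R_{l(jk)} + \varepsilon_{ijkl},$$

with all effects mutually independent and, in the generating model of the
simulator, Gaussian. `anova_three_way()` computes the nine-term
sums-of-squares partition (G, T, Y, GT, GY, TY, GTY, replicates within
treatment-by-year, residual) in closed form from marginal totals, so the
partition is exact: the component sums of squares add to the total sum of
squares to machine precision. This is the reference path because on
balanced data it is exactly testable against independent least-squares
fits; the package deliberately *refuses* unbalanced layouts (a distinct
"unbalanced" error naming the missing cells) rather than silently dropping
cells, because the moment equations below assume balance. For unbalanced
data the mixed-model route (`fit_blups()`, REML via lme4) is the supported
alternative.

`estimate_varcomps()` solves the expected-mean-squares equations of the
all-random model:

$$\hat\sigma^2_e = MS_e,\quad
  \hat\sigma^2_{GTY} = \frac{MS_{GTY} - MS_e}{r},\quad
  \hat\sigma^2_{GY} = \frac{MS_{GY} - MS_{GTY}}{rt},\quad
  \hat\sigma^2_{GT} = \frac{MS_{GT} - MS_{GTY}}{ry},$$
$$\hat\sigma^2_{G} = \frac{MS_G - MS_{GT} - MS_{GY} + MS_{GTY}}{rty}.$$

Method-of-moments estimates can be negative. They are *reported* as
estimated (and listed in the `negative` field) so that diagnostics are not
lost, but they are truncated to zero inside the heritability formula — this
keeps $H_{BS}$ in $[0, 100]$, as a percentage must be.

## Heritability, genetic advance, genetic gain

Broad-sense heritability on an entry-mean basis, in percent:

$$H_{BS} = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GT}/t +
  \sigma^2_{GY}/y + \sigma^2_{GTY}/(ty) + \sigma^2_e/(ryt)} \times 100.$$

The denominator is the variance of an entry mean taken over all $t y r$
plots, which is the basis on which entries are actually compared and
selected. Expected gain from one round of truncation selection follows the
breeder's equation $GA = K \, \sigma_P \, H_{BS}/100$, with $K = 2.06$
(the standardized selection differential when the top 5% of a normal
distribution is kept), and genetic gain percent is $GA/\bar{y} \times 100$.

**What $\sigma_P$ means here.** The phenotypic standard deviation is not
uniquely defined by the gain formula alone; rsmet uses the standard
deviation of entry means over all plots (`phenotypic_sd(..., basis =
"entry_mean")`), because selection operates among entries on their means.
A plot-basis switch exists for users who want the raw plot SD; the two can
differ substantially whenever non-genetic variance is large, so the choice
is stated prominently here and in the function documentation.

## Drought-tolerance indices

With $Yi_s$, $Yi_{ns}$ an entry's mean yield under stress and non-stress
and $Y_s$, $Y_{ns}$ the corresponding reference population means:

| index | formula | units | better is | ranked |
|---|---|---|---|---|
| TOL | $Yi_{ns} - Yi_s$ | g/plot | smaller (negative = yields more under stress) | ascending |
| MPI | $(Yi_{ns} + Yi_s)/2$ | g/plot | larger | descending |
| GMP | $\sqrt{Yi_s\,Yi_{ns}}$ | g/plot | larger | descending |
| MRP | $Yi_s/Y_s + Yi_{ns}/Y_{ns}$ | — | larger | descending |
| REI | $(Yi_s/Y_s)(Yi_{ns}/Y_{ns})$ | — | larger | descending |
| STI | $Yi_{ns} Yi_s / Y_{ns}^2$ | — | larger | descending |

Design decisions that were genuinely open:

* **Reference means.** Nothing in the index formulas dictates which
  population defines $Y_s, Y_{ns}$. rsmet requires the user to name a
  reference entry (or pass explicit means). For the bundled reference table
  the pooled half-sib population row is the only convention under which
  that row's own MRP equals 2 and REI equals 1 exactly, so the fixture and
  examples use it.
* **MPI** is the arithmetic mean of the two yields. The formula is
  sometimes typeset ambiguously as $Yi_{ns} + Yi_s/2$; the mean reading is
  the one consistent with published MPI values and with the index's name.
* **Tie policy.** Ranks use average ties by default (`ties =
  "competition"` gives min-rank "1224" ranking); field data rarely tie, but
  the policy must be deterministic and documented for reproducibility.
* **GMP caveat.** In the bundled reference table the printed GMP values for
  the ten family rows sit 0.4–2.6% *below* $\sqrt{Yi_s Yi_{ns}}$ applied to
  the printed yields, a pattern consistent with averaging per-replicate
  geometric means (Jensen's inequality); the plot-level data behind that
  table are unavailable, so rsmet implements the stated formula and
  documents the discrepancy rather than reverse-engineering it. Similarly
  the base row's printed MRP/REI/STI do not follow the stated formulas
  under any reference convention tried; they are treated as errata of that
  table, not targets.

`index_correlations()` reports Pearson correlations among the six indices
with two-sided p-values — the usual device for picking one index (a
productivity index positively correlated with all others) as the working
yardstick of drought tolerance.

## Population comparisons

* **t-tests** (`mean_shift_ttest()`): the experimental unit is the entry
  (line) mean, not the plot — families are populations of lines, and plot
  replicates of one line are pseudo-replicates for a population contrast.
  Welch's unequal-variance form is the default because family and base
  populations differ in size and spread; `var_equal = TRUE` restores the
  pooled test.
* **Dunnett many-to-one** (`dunnett_many_to_one()`): statistics use the
  variance pooled across all groups (error df $N - k - 1$) and the
  adjusted two-sided p-value for comparison $i$ is
  $1 - P(\max_j |T_j| \le |t_i|)$ under the multivariate-t distribution
  with correlation $\rho_{ij} = \lambda_i\lambda_j$,
  $\lambda_i = \sqrt{n_i/(n_i + n_0)}$. The integral has no closed form
  for general $n_i$, so it is evaluated by Genz–Bretz quasi-Monte-Carlo
  (mvtnorm) under a fixed seed with absolute tolerance $10^{-4}$; results
  are bit-for-bit reproducible for a given seed. An isotonic pass enforces
  monotonicity of adjusted p in $|t|$ (integration jitter could otherwise
  produce inversions of order $10^{-4}$), and adjusted p is floored at the
  unadjusted p.
* **Adjusted means** (`adjusted_means()`): least-squares entry means from
  the fixed model `trait ~ entry + env`, where `env` indexes each
  replicate within a treatment-by-year cell — a single blocking factor
  that absorbs treatment, year, their interaction and replicate effects
  without rank deficiency. On balanced data these equal arithmetic entry
  means exactly (orthogonality); with missing cells they solve the normal
  equations, averaged over all environment levels (emmeans).
* **BLUPs** (`fit_blups()`): the six-term all-random intercept model is
  fitted by REML through lme4 — the standard, heavily validated tool for
  this model class — and progeny effects are predicted by shrinkage.
  Random terms whose grouping factor has a single level in the data (e.g.
  year in a one-season trial) are dropped with a message rather than
  failing, since a one-level variance component is not identifiable.
  Boundary ("singular") fits are legitimate REML solutions — a zero
  progeny variance shrinks every BLUP to zero — and are returned as such.

## The synthetic-trial generator

`simulate_met()` draws every random effect independently Gaussian with the
stated variance on a fully balanced grid; the same seed reproduces the
dataset exactly, and seeds are explicit arguments everywhere (no global
RNG state is consumed: the caller's `.Random.seed` is saved and restored).

Defaults (`varcomp_spec()`): grand mean 600 g/plot; $\sigma^2_G = 1200$,
$\sigma^2_{GT} = \sigma^2_{GY} = 1200$, $\sigma^2_{GTY} = 800$,
$\sigma^2_e = 10000$ g². These give a plot-level coefficient of variation
near 20% — ordinary for stressed yield trials — and an entry-mean-basis
heritability of about 31% at $t = y = r = 2$, the magnitude reported for
grain yield under water limitation; the mean-to-SD ratio of 5 makes
negative simulated yields vanishingly rare, so the non-negativity
invariant of the yield trait is respected without truncating the normal
model.

`simulate_selection_response()` emulates one or more cycles of truncation
selection: entries are ranked on phenotype means over all plots, the top
fraction is kept (5% default, matching $K = 2.06$), and the offspring
genotypic mean shifts by the *realized* phenotypic differential times the
generating heritability — the breeder's equation with the realized rather
than the expected differential, so finite-sample selection intensity is
honoured automatically. Default population sizes (157 base lines, 75
selected progenies) mirror a realistic programme scale. The contrasting
drought response of the two populations is reproduced phenomenologically:
rainfed plot values are scaled multiplicatively so the base population's
RF:RI mean-yield ratio is 0.53 (yield collapse under stress) and the
selected population's is 1.09 (yield maintained); scaling is applied after
selection, so the realized genetic response is untouched. This is a
deliberate choice to reproduce the observed pattern without inventing a
physiological model.

**What passing tests do and do not show.** The generator is balanced,
Gaussian, additive and single-trait. Real trials are alpha-lattices with
spatial trend, occasional lost plots, non-Gaussian traits (HI is a bounded
fraction), multi-trait selection, and pedigree structure among half-sib
progenies — none of which is emulated. Parameter-recovery and calibration
tests therefore certify the *estimators and tests*, under the model they
assume, at realistic signal-to-noise; they do not certify robustness to
field artefacts. No marker/QTL or genotype-specific drought-response
simulation is attempted.

## Numerical conventions and test problem sizes

* Balance is checked cell-by-cell before any ANOVA; missing trait values
  propagate as reduced n in means but are an error in the ANOVA path.
* Negative variance components: retained in estimates, truncated in
  $H_{BS}$; an all-zero denominator returns 0 with a `degenerate` flag.
* Dunnett integration tolerance $10^{-4}$ on p; quantiles via `qmvt` with
  the same algorithm.
* Units are carried as supplied and never converted (biomass, in
  particular, is reported in the units of the source records without an
  area basis).
* Test problem sizes were chosen as the smallest that keep Monte-Carlo
  error well inside the asserted tolerances: 200 simulated trials of 100
  entries for variance-component recovery (mean estimates within 10% of
  truth, mean heritability within 5 points of the implied 53.33%), 500
  replicates for the selection-response calibration (mean response within
  10% of $K h^2 \sigma_P$), 1000 null replicates for t-test uniformity and
  2000 for Dunnett familywise error (binomial MC error 0.005 at
  $\alpha = 0.05$).

## Known limitations

* The expected-mean-squares path requires complete balance; there is no
  automatic fallback, by design — the user must opt into the REML route.
* Dunnett adjusted p-values inherit quasi-Monte-Carlo noise below the
  $10^{-4}$ tolerance; they are reproducible, not exact.
* `gain_table()` analyses each family on its own records; families with a
  single replicate or missing cells are reported with an error note rather
  than estimates.
* The published per-family heritabilities, gains and test p-values of the
  trial that motivated the bundled fixture depend on plot-level data that
  were never deposited; rsmet reproduces the index arithmetic and the
  population-level gain identities exactly, and everything else is
  validated by the property suites described above.
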