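---
title: "Classifying gene-environment interactions in daily life: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene-environment interactions in daily life: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Experience-sampling (ESM) protocols signal participants several times a day
and collect momentary self-reports: how stressful or positive the current
situation feels, and momentary symptom and affect levels on 1-7 scales.  A
person-level genetic sensitivity score — here a clumping-and-thresholding
polygenic score — may *moderate* how strongly the momentary context at one
signal predicts the person's state at the next signal.  Three classic
frameworks describe the possible shapes of such a cross-level interaction:

* **Differential susceptibility (DS)** — sensitive individuals do worse in
  adverse contexts *and* better in favourable ones ("for better and for
  worse"); the regression lines for different sensitivity levels cross
  inside the observed environment range.
* **Diathesis-stress** — sensitivity only amplifies harm; the lines meet at
  the favourable extreme of the environment.
* **Vantage sensitivity** — the mirror image; the lines meet at the
  unfavourable extreme.

`esmgxe` implements the full chain: polygenic scoring, time-lagged
multilevel screening models, and a competitive-confirmatory stage that fits
all six crossover models (three frameworks, each in a weak and a strong
variant) and classifies the interaction by AIC.

# The crossover model family

All six candidate models share one mean structure for the outcome at signal
$t+1$ given the context rating $E_t$ at signal $t$ and the person-level
sensitivity score $G_i$:

$$
y_{i,t+1} = b_0 + u_i + \sum_k \gamma_k \, \mathrm{cov}_{k,i}
          + (s_0 + s_1 G_i)\,(E_{t} - c) + \varepsilon_{i,t+1},
$$

with a random intercept $u_i \sim N(0, \sigma_u^2)$ for within-person
clustering and $\varepsilon \sim N(0, \sigma_e^2)$.  The parameters:

| parameter | meaning | units |
|---|---|---|
| $c$ | crossover point: the context value where lines for all $G$ intersect | units of $E$ (the 1-7 item scale) |
| $s_0$ | environmental slope for a person with $G = 0$ | outcome units per unit of $E$ |
| $s_1$ | sensitivity slope: extra environmental slope per unit of $G$ | outcome units per unit of $E$ per SD of $G$ |
| $b_0$ | expected outcome at $E = c$ for $G = 0$ | outcome units |

The frameworks differ only in what they do with $c$ and $s_0$:

* DS: $c$ **free** (estimated);
* diathesis-stress: $c$ fixed at the observed **maximum** of $E$;
* vantage sensitivity: $c$ fixed at the observed **minimum** of $E$;
* the **strong** variant of each constrains $s_0 = 0$ (all environmental
  reactivity runs through sensitivity), the **weak** variant leaves $s_0$
  free.

"Observable bounds" of the environment are taken as the per-dataset
observed minimum and maximum of $E$ at the lagged-pair level, not the
theoretical 1-7 scale: a crossover that the data never visited cannot be
certified as inside the data.

## Fitting

For fixed $c$ the model is linear in its coefficients, so it is fitted
directly by the random-intercept ML engine.  The two free-$c$ cases differ:

* **Weak, free $c$** is an exact reparameterization of the ordinary
  interaction model $\{1, G, E, G\!\times\!E\}$: expanding
  $(s_0 + s_1 G)(E - c)$ gives $\beta_G = -s_1 c$, $\beta_E = s_0$,
  $\beta_{G\times E} = s_1$, hence $\hat c = -\hat\beta_G /
  \hat\beta_{G\times E}$ with identical likelihood.  When
  $|\hat\beta_{G\times E}| < 10^{-10}$ the crossover is reported as
  non-identifiable rather than as a wild ratio.
* **Strong, free $c$** is genuinely nonlinear in $c$.  The profile
  likelihood over $c$ is maximized on a 61-point grid spanning the observed
  $E$ bounds extended by 50% of the range on each side (so an out-of-bounds
  optimum is representable — necessary for the bounds-check semantics),
  followed by golden-section refinement of the bracketing interval.

## Parameter counting and competition

All fits use **ML, not REML**, because the AIC competition spans models with
different fixed-effects structures.  `n_params` counts the fixed
coefficients, the two variance components, and the crossover point *when it
is free*; in the weak free-$c$ model the four coefficients of the
interaction parameterization are in one-to-one correspondence with
$(b_0, s_0, s_1, c)$, so no extra parameter is added there.  The winner is
the minimum-AIC model; exact ties break toward fewer parameters, then
toward fixed-$c$ specifications (parsimony).

A DS winner is only *labelled* DS after a bounds check: the 95% interval of
$\hat c$ must lie within the observed bounds of $E$.  The interval comes
from a **parametric bootstrap** (default $B = 500$): outcomes are
re-simulated from the fitted model (fresh random intercepts and residuals
around the fitted fixed-effect mean), the same free-$c$ specification is
refitted, and the 2.5/97.5 percentiles of $\hat c$ are taken.  Bootstrap
refits of the strong model use warm-started coordinate ascent (alternating
1-D searches over $c$ and over the variance ratio) from the parent
optimum, since each replicate only perturbs an already-located maximum.
Even under a perfectly strong truth, AIC selects the weak sibling whenever
adding $s_0$ gains more than one log-likelihood unit — about
$P(\chi^2_1 > 2) \approx 16\%$ of replicates — which is the inherent
ceiling of any "strong correctly labelled strong" rate.

# The mixed-model engine

The random-intercept Gaussian model has marginal covariance
$\sigma_e^2 (I + \lambda J)$ per subject, $\lambda = \sigma_u^2 /
\sigma_e^2$.  For fixed $\lambda$, GLS gives closed-form coefficients and a
profiled $\hat\sigma_e^2$, leaving a 1-D maximization over $\log\lambda$
(searched in $[10^{-8}, 10^8]$, with $\lambda = 0$ checked explicitly as a
boundary candidate).  Everything is computed from per-subject sufficient
statistics ($X'X$, group sums, cross-products), which makes the two hot
loops cheap: a bootstrap refit only updates the $y$-side statistics, and
the strong-model profile maps a fixed basis $[1, \mathrm{covs}, G, GE]$
through a small transformation matrix per candidate $c$.  The test suite
checks the engine against brute-force dense multivariate-normal
maximization on small instances and against `lme4` on a moderate one.

Inference on fixed effects is Wald with standard-normal reference — with
thousands of level-1 lagged pairs the difference from Satterthwaite-type
degrees of freedom is negligible.  Random intercepts only: the screening
and confirmatory models control for within-subject clustering and name no
random slopes.  The polygenic score is z-scored across subjects before
entering any model; other predictors stay on their raw scales.

# Screening, trimming, and FDR

For every outcome x context x threshold cell, the screening model is
`y ~ G + E + G:E + PC1 + PC2` on the within-day lagged pairs, where PC1/PC2
are the top two principal components of the column-standardized dosage
matrix (a desk-scale stand-in for the usual MDS ancestry axes — both
capture the same structure).  Benjamini-Hochberg correction is applied to
the four threshold-specific interaction p-values *within* each
outcome-context family; the confirmatory stage runs only on cells whose
FDR-adjusted p falls below $\alpha$, and ancestry covariates with
nonsignificant Wald tests are trimmed before the six-model competition.

Lagged pairs connect *consecutive issued signals within a day*: a pair
(beep $k$, beep $k{+}1$) enters an analysis only when the predictor (and
any beep-level covariates) are observed at $t$ and the outcome at $t+1$;
the last beep of a day is never paired with the next morning.  No
additional elapsed-time filter is applied — the design already caps gaps at
170 minutes.  An index is missing whenever any constituent item is missing
(strict policy; the permissive mean-of-available alternative is
deliberately not the default).

# The synthetic-data generator

No participant-level data are distributable, so the generator is the
package's study stand-in, and its defaults *are* the emulated design:

* 217 subjects, 7 days x 8 signals in a 10:00-22:00 window, consecutive
  gaps uniform on the integer minutes of [10, 170] (integer-minute gaps keep
  the bounds exact on the stored times), compliance $40.7/56 \approx 0.727$
  so the expected completed-beep count matches the observed 40.7.
* Genotypes from a latent-Gaussian threshold model: two independent gametes
  whose within-block allele indicators share an exchangeable latent
  correlation (default 0.7, 20 blocks x 10 SNPs); blocks sit 3 Mb apart so
  a 1000 kb clumping window never spans blocks.  This is deliberately not a
  chromosome-scale LD map.
* GWAS summary statistics: causal SNPs (probability 0.3) carry
  $N(0, 0.1^2)$ effects; every SNP's p-value is the normal tail of
  $\beta / \mathrm{se}$ with $\mathrm{se} = 1/\sqrt{n_{\mathrm{gwas}} \cdot
  2\,\mathrm{maf}(1-\mathrm{maf})}$, so p is monotone in the standardized
  effect and uniform under the null.
* Context appraisals from Beta-shaped latents rescaled to [1, 7] and
  rounded: a right-skewed "stress-like" preset (Beta(0.55, 2.33)) and a
  left-skewed "positive-like" preset (Beta(2.89, 1.09)), moment-matched so
  the rounded person-mean levels land near 2.15 and 5.35.  Only those first
  moments are calibrated; the true distributional form of daily-life
  appraisals is unknown, and the two context streams are generated
  independently (real stressful/positive ratings correlate negatively).
* Outcomes from the crossover model itself: the target outcome at beep
  $k{+}1$ is $b_0 + u_i + (s_0 + s_1 G_i)(E_k - c) + \varepsilon$ using the
  *stored* context value of the previous same-day beep; the first beep of a
  day has no lagged dependence, mirroring the analysis restriction.  All
  other outcomes are context-independent noise around their typical
  person-level values (symptom indices near the scale floor, positive
  affect near 4.7), which reproduces the floor effects real momentary
  symptom items show.  Items are the latent index plus $N(0, 0.3^2)$ noise,
  rounded and clipped to the 1-7 grid; a continuous test mode
  (`round_items = FALSE`, `item_noise_sd = 0`) disables this for exact
  oracle checks.  Missingness is Bernoulli compliance — completely at
  random; informative missingness is out of scope.

The default true regime is a modest weak-DS effect on paranoia via the
positive-context appraisal ($s_1 = -0.05$, $c = 4.5$), driven by the
z-scored PRS at the most inclusive threshold.

**What passing tests do and do not show.**  The generator produces
grid-valued, floor-affected, randomly missing data — but its lagged
dependence, Gaussian noise and MCAR missingness are exactly the assumptions
of the fitted models.  Operating characteristics measured on it (crossover
recovery within ~1% of the environment range, bootstrap coverage near 94%,
strong-DS selection near the theoretical AIC ceiling) certify the
*machinery*, not robustness to autocorrelated residuals, informative
missingness, or non-Gaussian outcomes in real ESM data.

One grid effect deserves mention because it is a real-data lesson too: if
the latent outcome sits off-center on the 1-7 scale, asymmetric truncation
at the scale ends induces a spurious baseline slope $s_0$, which inflates
weak-model selection under a strong truth.  The operating-characteristic
simulations therefore place the latent outcome mid-scale ($b_0 = 4$); with
symptom-like floored outcomes the weak/strong distinction should be read
cautiously.

# Numerical choices

* Variance-ratio profile: `optimize` on $\log\lambda$, tolerance $10^{-7}$
  ($10^{-4}$ inside crossover profiles, where the error is second-order);
  boundary $\lambda = 0$ always evaluated.
* Degenerate fits: residual variance is floored at the smallest positive
  double, so noiseless fixtures (used by the exact-interpolation tests)
  stay finite.
* Clumping visits SNPs in ascending p with ties broken by (chromosome,
  position, SNP id); thresholds are strict (`p < tau`); monomorphic SNPs
  have $r^2 = 0$ by convention (they tag nothing) with a warning.
* Allele alignment in scoring: opposite-allele codings are flipped
  (`2 - dosage`); palindromic A/T and C/G SNPs whose coded allele disagrees
  are dropped as strand-unresolvable; missing dosages are mean-imputed per
  SNP.
* AIC ties break toward fewer parameters, then fixed-$c$ models.
* All generator stages derive their own seeds from the config seed, so a
  config is one reproducible study.

# Problem sizes used by the shipped simulations

The packaged tests and the acceptance script size their simulations as:
full-design calibration at the default 217 subjects; crossover
recovery/coverage at 300 subjects with ~40 completed pairs each over 100
replicates ($B = 200$ bootstrap); strong-DS selection at 150 subjects over
100 replicates; the null false-discovery grid at 100 subjects over 40
seeds; and oracle equivalences on small instances (up to 8 subjects x 5
observations for the dense-likelihood check).  These sizes give
Monte-Carlo error comfortably below the margins being checked while
keeping a full run in the minutes range.

# Known limitations

* The LD reference for clumping is the analysis sample itself, not an
  external panel; with desk-scale synthetic genotypes that is the only
  consistent choice, and the clumping logic is unaffected.
* Reliability is reported as the classic two-level Cronbach decomposition
  (alpha over person means; alpha over person-mean-centered scores);
  multilevel SEM reliabilities (omega) are out of scope.
* No autoregressive residuals, random slopes, crossed random effects, or
  multiple-lag models.
* The bootstrap CI is percentile-based; profile-likelihood intervals for
  $c$ would be a reasonable alternative but are not implemented.
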