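---
title: "Models and methods: growth and survival genetics of village goat kids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: growth and survival genetics of village goat kids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`goatQG` estimates genetic parameters — heritability ($h^2$),
repeatability ($r$) and genetic correlations ($r_g$) — for the growth,
conformation and survival of goat kids recorded in smallholder village
herds.  The setting it is built around is a recording scheme in which
about 1,500 kids from roughly 650 dams and 100 bucks, spread over eight
village flocks in two provinces, are weighed and measured at birth and at
3, 6, 9 and 12 months (body weight BW in kg; chest girth CG, body length
BL and height at withers HW in cm), with survival followed to one year and
right-censored at 360 days.  Because no individual-level data set of this
kind is publicly deposited, the package pairs its estimation machinery
with a synthetic herd generator that emulates that recording structure, so
every stage of the pipeline can be exercised and validated end to end.

# The growth model

Repeated measurements of BW and one conformation trait are analysed with a
bivariate repeatability-maternal animal model.  For trait $t \in \{1,2\}$
and visit $j$ of kid $i$:

$$ y_{tij} = x_{ij}'b_t + a_{ti} + m_{t,\mathrm{dam}(i)} + p_{ti} +
c_{t,\mathrm{herd}(i)} + e_{tij} $$

* fixed effects: the full age class (5) x sex (2) x parity (3) x birth
  type (2) interaction, coded as cell means with unobserved cells dropped.
  Coding the complete cross-classification sidesteps the question of which
  interaction orders to keep; with about sixty possible cells it is well
  within the information in herd-scale data.
* $a$: additive genetic effects with $\mathrm{Var}(a_t) = \sigma^2_{a_t}
  A$, where $A$ is the pedigree additive relationship matrix, and additive
  covariance $g_{12}$ between the two traits;
* $m$: maternal effects, iid per dam (deliberately not pedigree-linked);
* $p$: permanent environmental effects, iid per kid, linking the repeated
  visits of one animal;
* $c$: common environmental effects, iid per herd (village flock);
* $e$: residuals, iid per visit with full 2x2 covariance $R_0$.

Every random term carries an unstructured 2x2 covariance matrix across
the two traits.  Derived parameters per trait are

$$ \sigma^2_{ph} = \sigma^2_a + \sigma^2_m + \sigma^2_p + \sigma^2_c +
\sigma^2_e, \qquad h^2 = \sigma^2_a / \sigma^2_{ph}, \qquad r =
(\sigma^2_a + \sigma^2_p)/\sigma^2_{ph}, $$

and $r_g = g_{12} / \sqrt{g_{11} g_{22}}$.  All derived quantities are
computed sample-wise along the chain and summarised afterwards (mean of
ratios, never ratio of summary means).  The reference table shipped as
`referenceParameters()` provides published posterior summaries for these
quantities in the study population; its component rows reproduce most of
its printed $h^2$ and $r$ values exactly under this arithmetic, with two
documented exceptions (the chest-girth $h^2$ printed as 0.16 versus 0.17
from the printed means, and the survival $h^2$ printed as 0.02 versus
0.026 from the printed means), presumably because the printed ratios were
summarised from the full posterior rather than recomputed from rounded
component summaries.

# The survival model

Survival to one year is analysed on the log-time scale with an
accelerated failure time animal model:

$$ \log ST_i = b_0 + b_1\,\mathrm{BW}^{(birth)}_i + a_i +
m_{\mathrm{dam}(i)} + c_{\mathrm{hys}(i)} + e_i, $$

where $c$ is a herd x birth-year x season cross-classified level and
kids alive at the horizon (360 days by default) are right-censored.
Day-of-birth deaths are floored at half a day before taking logs.  All
random terms are Gaussian on the log scale (a log-normal AFT).  An
exponential-error AFT is sometimes described for such data, but
exponential errors are incompatible with reporting heritability as a
ratio of variance components on the log scale, which is exactly what this
model is for; the `errorFamily` flag therefore admits only
`"lognormal"` and fails loudly otherwise.  The survival heritability uses
the four-component denominator $\sigma^2_a + \sigma^2_m + \sigma^2_c +
\sigma^2_e$ (no permanent-environment term: one survival outcome per kid).

# Bayesian estimation

Both models are fitted by Gibbs sampling with inverse-Wishart (matrix
terms) or inverse-gamma (scalar terms) priors, mirroring the estimation
protocol of the study the package emulates (100,000 iterations, 10,000
burn-in, thinning 10 at full scale; simulation experiments use shorter
chains).

Three implementation choices matter and are worth recording:

1. **Hybrid scan.**  The compiled kernel performs single-site updates
   (2x2 blocks per level; the additive and permanent-environment effects
   of a recorded animal are drawn as one 4-dimensional block because they
   compete for the same kid-level variance).  Every `blockEvery`
   iterations the R layer draws *all* location effects jointly from the
   sparse mixed-model equations with the $A^{-1} \otimes G_0^{-1}$
   penalty.  $A^{-1}$ is obtained once by dense inversion of $A$ (the
   analysis targets herd-scale pedigrees of a few thousand animals, where
   dense A is cheap) and stored row-sparse, since the inverse of a
   pedigree relationship matrix is structurally sparse.
2. **A marginal exchange move.**  At herd scale the likelihood is nearly
   flat along the ridge $G_0 + P_0 \approx$ constant: kid-level variance
   can sit in the additive or the permanent-environment term with almost
   identical fit, and sib covariances pin the split only weakly.  Plain
   Gibbs chains (whether single-site or blocked — an independent
   general-purpose MCMC implementation of the same model sticks in the
   same way) cross this ridge far too slowly and produce falsely tight
   intervals.  The sampler therefore adds a Metropolis move that proposes
   transferring covariance between $G_0$ and $P_0$ (direction
   $\tfrac12(G_0+P_0)$, which makes the proposal symmetric) and accepts
   against the *marginal* likelihood with all location effects integrated
   out via the sparse mixed-model-equation Cholesky.  With this move the
   20-replicate recovery experiment covers every body-weight component at
   or above its nominal 95% rate.
3. **Data-scaled priors.**  The default prior is inverse-Wishart with
   $\nu = 3$ (dimension + 1: heavy tails, uniform marginal correlation)
   and scale equal to 0.2 times the raw within-cell phenotypic variance
   of each trait.  A fixed small scale such as $0.1 I$ looks harmless but
   is sharply informative on the scale of cm^2-sized components: in the
   weakly identified decomposition above it drags the maternal, permanent
   and common components toward zero and piles their variance onto the
   additive term (whose conditional is dominated by the pedigree-augmented
   effects rather than the prior).  Fixed scales remain available through
   `priorSpec(nu=, scale=)` — the prior-predictive test uses one — and the
   scales actually used are recorded in the chain metadata.

Missing second-trait measurements are handled by data augmentation inside
the scan rather than row deletion, since attrition differs by trait
availability.  Right-censored log survival times are likewise augmented
from truncated normals above $\log(\mathrm{horizon})$.  All randomness
(compiled and R-level) flows from R's RNG, so a chain is exactly
reproducible from its seed; the chain metadata store seed, settings and
priors.

Convergence tooling is numeric rather than visual: effective sample sizes
from the initial-positive-sequence estimator of the integrated
autocorrelation time, and a Geweke-style z comparing the first 10% with
the last 50% of retained samples (window fractions configurable).

# The synthetic herd generator

`simulationConfig()` fixes the generator's defaults to the study
conditions: 1,538 kids from 645 dams and at most 106 sires in 8 herds
across 2016–2019; BW age-class means 2.1/6.4/9.0/11.4/13.6 kg with a
+0.58 kg male contrast and a −1.0 kg twin contrast; twin litter fraction
0.4 (mean litter size 1.4, litters trimmed so the kid count is exact);
true variance components equal to the reference posterior means;
censoring at 360 days; and per-age record retention calibrated so expected
counts fall like 1538/1270/992/787/705.  Conformation age means
(roughly 30→55 cm across traits) are plausible values for small East
African goats; nothing downstream depends on their exact levels.

Choices the recording scheme left open, and how they were made:

* **Survival calibration.**  The one-year mortality targets are 21.4% for
  singles and 39.2% for twins: these keep the published twin–single gap
  (17.8 points) while making the overall rate 31.6% at the generator's
  twin-kid share of 0.571 (the published per-stratum rates of 24.2%/42%
  imply a twin share lower than a 0.4 twin-litter fraction produces, so
  they cannot all three hold at once; the overall rate and the gap are the
  calibrated quantities).  The log-scale baseline and direct twin effect
  are then solved in closed form by probit inversion under the log-normal
  model, including the birth-weight slope's variance contribution.
* **Common-environment draws are centred** (herd effects for growth,
  herd-year-season effects for survival).  With eight herds the realised
  mean of uncentred draws would shift every fixed-effect mean by a random
  amount of SD $\sqrt{0.41/8} \approx 0.23$ kg, destroying the mean
  calibration the defaults promise; centring costs a $1/q$ deflation of
  the realised level variance, which is negligible against the posterior
  spread of these components.
* **Cross-trait coupling.**  Additive effects across traits share a
  standardised pedigree core so each BW-conformation pair has exactly the
  configured genetic correlation (0.79/0.65/0.74); the non-additive terms
  use within-term correlations 0.93/0.91/0.88, calibrated so pooled
  phenotypic correlations come out high with the CG > BL > HW ordering of
  the study.
* **Parity** is the dam's litter sequence number capped at 3; herds split
  evenly between the two provinces; years and seasons are assigned to
  litters uniformly.

What the generator does *not* emulate: growth variances are
age-homoscedastic (the repeatability model's own assumption), so the
simulated birth-weight SD is about 1.8 kg rather than the observed 0.5 kg
— and a homoscedastic Gaussian with mean 2.1 kg necessarily produces
occasional non-positive "weights".  These are kept (class validity checks
finiteness, not positivity) because truncating them would bias the
recovery experiments; real recording schemes obviously contain no such
values.  Trait trajectories have no kid-specific growth curves, disease
outbreaks or seasonal feed effects; passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions, not robustness to model misspecification.

# Validation experiments and problem sizes

The test suite validates the pipeline at sizes chosen to keep the whole
suite in the tens of minutes on one core:

* relationship matrices against an independent recursive kinship oracle
  (100 random pedigrees of up to 50 animals, tolerance 1e-12);
* generator moments at 20,000 kids: latent component variances within
  10–15%, and data-only method-of-moments checks (within-kid contrasts
  for $\sigma^2_e$; dam-mate, herd-mate and full-sib covariances via
  grouped sums).  With one record per kid $\sigma^2_p$ and $\sigma^2_e$
  are not separately identifiable from data alone, so the data-only
  oracle targets the component combinations the design identifies, at
  tolerances set from their a-priori sampling errors (e.g. 30% on the
  full-sib minus dam-mate contrast that isolates $\sigma^2_a/4$);
* growth-model recovery at 400 kids / 150 dams / 30 sires / 8 herds,
  chains of 20,000 (burn-in 2,000, thinning 10), 20 replicate seeds:
  95% HPD coverage of every body-weight component at 18/20 or better,
  and posterior mean $r_g$ in [0.5, 0.95] (truth 0.79);
* survival recovery at 1,000 kids with the reference survival pattern
  (dominant herd-year-season variance, $h^2 = 0.026$): posterior median
  $h^2 \le 0.10$ in at least 18/20 seeds;
* a degenerate-limit oracle: with unrelated kids, no censoring and no
  random-effect variance the AFT slope must match ordinary least squares
  within Monte-Carlo error;
* prior-predictive behaviour with a zero-row design against the
  closed-form marginal median of the fixed inverse-Wishart prior (the
  heavy-tailed prior has no stable sample mean, so the median is the
  honest check);
* generator calibration at the full default scale over 20 seeds (exact
  counts; mean litter size 1.4 ± 0.05; overall mortality within 3 points
  of 31.6%; twin mortality above single mortality in at least 18/20).

# Numerical notes and limitations

* Identifiability, not arithmetic, is the binding constraint at herd
  scale: the additive/permanent split and the maternal component are
  informed by a few hundred sib pairs, so their posteriors are wide, and
  honest width is exactly what the recovery experiments check.
* The inverse-Wishart draws are Bartlett-based, so every retained
  covariance sample is positive definite by construction; genetic
  correlations need no clipping.
* Degenerate inputs fail early with named errors: pedigree cycles list
  the animals involved, records of unknown animals name the identifier,
  all-censored survival data are rejected, empty record sets are
  rejected at design construction.
* `hpdInterval()` returns the shortest window containing
  `ceiling(prob * n)` sorted samples; for a constant sample it degenerates
  to a point interval.
* Identifier matching is exact string equality after whitespace trimming
  (ear-tag codes), never case-folded.  Unknown parents may be coded as
  empty, `0` or `NA` in files and are treated as unrelated, non-inbred
  founders.
* The pedigree machinery allows arbitrary depth, but the generator only
  produces two generations (founder parents and recorded kids), matching
  a recording scheme without grandparental identities.
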