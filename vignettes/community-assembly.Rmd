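---
title: "Methods: community assembly analysis of two-belt forest inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly analysis of two-belt forest inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestdiv)
library(dplyr)
```

`forestdiv` implements the standard analysis chain for stem-level tree
inventories from replicated plots in two altitudinal vegetation belts
(a birch belt and a pine-oak belt, each sampled as five stand types with
five 30 × 30 m plots): species importance values, Hill-number diversity with
rarefaction/extrapolation, species-abundance-distribution (SAD) model
selection, and assemblage structure via clustering and correspondence
analysis.  This vignette records the models, the conventions chosen where
the underlying field protocol leaves them open, and the numerical decisions.

## Data model and filtering

The unit record is a measured stem: plot, stand code, species binomial, and
DBH (diameter at breast height, 1.3 m) in cm.  The census includes every
stem with DBH ≥ 5 cm; `filter_dbh()` applies that threshold inclusively and
idempotently.  The ten stand codes map deterministically to their belt
(`stand_design()`), and per-hectare quantities are always scaled by the
plot area recorded in the plot table, never a hard-coded constant.

Higher-taxon summaries need a species → genus → family lookup, which field
protocols assume implicitly; we package one for the mid-altitude Qinling
tree flora (`reference_taxonomy()`).  Species missing from it are assigned
their binomial's genus and the family `"unknown"`, with a warning, so a
partially annotated inventory degrades visibly rather than silently.

Published stand tables report per-stand DBH minima around 13–22 cm, which is
impossible for stem-level extremes under a 5-cm census; they are read as
across-plot statistics of the plot-mean DBH.  `stand_summary()` therefore
reports both conventions (`dbh_min`/`dbh_max`/`dbh_mean` over plot means,
and `dbh_stem_min`/`dbh_stem_max` over stems).

## Importance values

For species $i$ with $n_i$ of $N$ stems, occupying fraction $F_i$ of
quadrats, with total basal area $d_i$ (basal area of a stem is
$\pi(\mathrm{DBH}/200)^2$ m²):

$$RD_i = 100\,\frac{n_i}{N},\qquad
  RF_i = 100\,\frac{F_i}{\sum_j F_j},\qquad
  Rd_i = 100\,\frac{d_i}{\sum_j d_j},\qquad
  IV_i = \frac{RD_i + RF_i + Rd_i}{3}.$$

Each relative column sums to 100, hence $\sum_i IV_i = 100$ — an invariant
the tests enforce on arbitrary inputs.  Some sources print a relative
frequency normalised by the *number of species* instead of total frequency;
that convention cannot produce percentage columns summing to 100 and
contradicts the column sums of published family/genus tables, so the
total-frequency form is the default and the per-species variant is kept
behind `rf_method = "per_species"` for comparability only.  At family or
genus level the overall relative importance is
$ORI = R.Ab + R.Fr$ (`ori_combine()`), the only combination consistent with
every published table row.  Values are carried at full precision and
rounded only for display.

## Hill-number rarefaction and extrapolation

Diversity of order $q$ is the effective species number
$^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}$: richness ($q=0$), exponential
Shannon entropy ($q=1$), inverse Simpson concentration ($q=2$).  Curves are
standardised either by sample size or by estimated sample coverage, for
abundance (individual-based) and incidence (plot-based) data.

Interpolation uses exact expectations under hypergeometric subsampling of
the reference sample: for $q=0$ the classical rarefaction formula, for
$q=1$ the entropy of the expected abundance-frequency counts
$E[f_k(m)]$, and for $q=2$ the unbiased estimator
$^2\hat D(m) = \big[\tfrac1m + (1-\tfrac1m)\sum_i
\tfrac{X_i(X_i-1)}{n(n-1)}\big]^{-1}$, which is valid at *any* size and so
covers extrapolation as well.  Extrapolated richness is anchored on the
Chao1 (abundance) or Chao2 (incidence) unseen-species estimate
$\hat f_0$, with the bias-corrected variant when doubletons are absent —
never a division by zero:
$$^0\hat D(n+m^*) = S_{obs} + \hat f_0\Big[1 - \Big(1 -
  \tfrac{f_1}{n\hat f_0 + f_1}\Big)^{m^*}\Big].$$
Extrapolated Shannon diversity uses a sample-size-weighted blend of the
observed entropy and an asymptotic (bias-corrected) entropy estimate,
$\hat H(n+m^*) = \tfrac{n}{n+m^*}\hat H_{obs} +
\tfrac{m^*}{n+m^*}\hat H_\infty$: it is continuous at the reference point,
nondecreasing, and approaches the estimated complete-assemblage entropy.
Continuity of the interpolated and extrapolated segments at the reference
sample, and monotonicity in both $q$ and $m$, are tested properties.
Extrapolation is intended for short range; when comparing assemblages the
endpoint is twice the smaller reference sample (`extrapolation_limit()`).

Sample coverage follows the Good–Turing construction: at the reference
size
$\hat C = 1 - \tfrac{f_1}{n}\tfrac{(n-1)f_1}{(n-1)f_1+2f_2}$, below it the
exact hypergeometric expectation (validated against exhaustive subsample
enumeration on a 12-individual toy), above it the geometric extension, with
sizes beyond $2n$ rejected.

Confidence bands are normal approximations, `estimate ± z · SD`, with the
SD taken over bootstrap replicates (default 200, the protocol's setting)
drawn from an estimated assemblage that augments the observed species (with
coverage-adjusted probabilities) by $\hat f_0$ unseen species sharing the
coverage deficit; incidence data use independent Bernoulli draws per
sampling unit.  All bootstrap paths require a seed for reproducibility.
The percentile alternative was not used; the cited framework's default is
the normal approximation, and a simulation in the test suite checks that
nominal 95% bands cover the true Shannon diversity at the reference size at
close to nominal rate (200 simulated communities, S = 15, N = 400).

## SAD models and selection

Six rank-abundance models are fitted to the descending abundances
$a_1 \ge \dots \ge a_S$: broken-stick ($k=0$ free parameters),
niche preemption ($k=1$), log-normal ($k=2$), Zipf ($k=1$ by default, with
$\hat p_1$ tied to the observed rank-1 proportion; $k=2$ when freed),
Zipf–Mandelbrot ($k=3$), and the dispersal-limited neutral model
($k=2$: $\theta$, $m$, with local community size $J$ fixed at $N$).
The log-normal's quantile argument, unspecified in many sources, is the
standard normal quantile at the mid-rank plotting position $(S-r+0.5)/S$,
so the median rank sits at abundance $\mu$.

All six models share one objective — the Poisson likelihood of the observed
abundance at each rank given the model's expectation — which is the
convention of standard rank-abundance fitters and makes
$\mathrm{AIC} = -2\log L + 2k$ comparable across models (the parametric
fits agree to numerical precision with `vegan::radfit`'s corresponding
models, used in the tests as an independent cross-check).  Agreement of
observed and fitted SADs is additionally summarised by a two-sample
Kolmogorov–Smirnov statistic on the abundance values; abundances are
discrete and tied, so the asymptotic p-value is a rough guide, not an exact
test — model ranking rests on AIC.

The neutral expectation is the abundance spectrum
$\phi_n$ (expected species with $n$ individuals) of the sampling formula
with $\gamma = m(J-1)/(1-m)$, evaluated in the log-Gamma domain by adaptive
quadrature (guarding the integrable endpoint singularity; agreement with a
fine-grid trapezoid rule to four significant figures is a tested property,
as is the conservation identity $\sum_n n\,\phi_n \approx J$ and the Ewens
metacommunity limit as $m \to 1$).  To place the neutral model in the same
rank-based objective, expected rank abundances are obtained by inverting
the cumulative expected species count $G(a) = \sum_{n \ge a}\phi_n$ at
$r - \tfrac12$; the spectrum is computed exactly for $n \le 30$ and on a
geometric grid above, log-interpolated.  Ranks beyond the expected species
count receive an expected abundance of 0.5, penalising over-rich fits
smoothly.  Fitting is a nested search — a log-spaced $\theta$ grid with 1-D
optimisation of $m$, refined by Nelder–Mead on $(\log\theta,
\mathrm{logit}\,m)$ with relative tolerance $10^{-8}$.  Non-convergence or
an inadmissible profile (e.g. a nondecreasing Zipf–Mandelbrot) yields a
flagged failure row, listed last in `compare_sad_models()`, not an error —
mirroring how a "failed to fit" outcome is reported in practice.

## Assemblage structure

Stand × species matrices are compared by Bray–Curtis dissimilarity on raw
abundances (the protocol does not state a metric; Bray–Curtis is the
community-ecology default and a chi-square option is provided for
consistency with correspondence analysis; no abundance transformation is
applied by default for the same reason).  Group-average (UPGMA)
agglomeration is delegated to `stats::hclust` and validated against a
brute-force agglomerator on small leaf sets; merge heights are
nondecreasing and ties resolve deterministically for a fixed input order.
The two-group cut labels each stand.

Correspondence analysis is computed directly as the SVD of the chi-square
standardised matrix $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$; the squared
singular values are the axis inertias and their sum equals the Pearson
$\chi^2/N$ of the table (tested against an independent $\chi^2$
computation, and against `vegan::cca` eigenvalues).  Scores are reported in
symmetric scaling so stands and species share one ordination diagram; rows
of reciprocal-averaging identity link the two score sets.  Degenerate
(rank-deficient) tables yield fewer axes rather than an error.

## The synthetic survey generator

`gen_survey()` exists so that every stage is testable with known ground
truth.  It emulates the reference design: 2 belts × 5 stands × 5 plots of
900 m², stems drawn per plot (Poisson counts around 117 and 110 stems per
plot, giving belt totals near 2,930 and 2,750), species pools of 43 and 41
with 34 shared (50 overall), truncated log-normal DBH ≥ 5 cm with
belt-specific scale, and simple allometric height/crown columns.  Belt
dominance structures were chosen once to match the published contrasts: a
flat log-normal SAD for the birch belt ($\sigma = e$, top species ≈ 13% of
stems, observed richness ≈ 43) and a concentrated Zipf SAD for the pine-oak
belt ($\gamma = -1.5$, top three species ≈ 63% of stems).  A geometric
(niche-preemption) pine-oak pool was considered and rejected: its tail
decays so fast that ranks beyond ~20 are never sampled at this effort,
contradicting the ~41 observed species it must emulate.  The neutral
community option uses the sequential urn in which the $j$-th individual is
an immigrant with probability $I/(I+j-1)$, $I = m(J-1)/(1-m)$, drawn from
a metacommunity Ewens urn with parameter $\theta$ — the construction whose
expected spectrum is exactly the fitted $\phi_n$ (verified by Monte-Carlo
in development).

What the generator does *not* emulate: spatial stem placement and
within-stand autocorrelation, environmental covariates, observational
error in species identification, and any systematic stand-to-stand
compositional gradient within a belt (stands of a belt share one SAD).
Passing tests therefore demonstrate correctness of the estimators and the
pipeline under idealised multinomial sampling, not robustness to the messy
structure of real survey data.

## Problem sizes and numerical choices

The test suite and examples run at deliberately moderate sizes chosen for
tight feedback loops: toy communities of ≤ 12 individuals for exhaustive
enumeration oracles; 200 simulated communities (S = 15, N = 400) for
confidence-band calibration; 50 seeded replicates at S = 40, N = 3000
(broken-stick) and J = 1000 ($\theta = 30$, $m = 0.2$; neutral) for
model-recovery rates; 100 seeded reduced surveys (~30 stems per plot) for
belt-recovery rates.  Bootstrap defaults stay at the protocol's 200
replications, while fast integration tests lower them explicitly.

Other numerical decisions: `lchoose`-based hypergeometric terms (exact
zeros outside support); the asymptotic entropy tail series computed in the
log domain to avoid overflow at large $n$; expected abundances floored at
$10^{-12}$ inside Poisson log-likelihoods; optimisation tolerances
$10^{-8}$ (Nelder–Mead relative, Brent/`optimize`); CA singular values
below $10^{-10}$ treated as null axes.

## Limitations

Incidence-based extrapolation of Shannon/Simpson diversity uses the same
weighted-blend construction as the abundance case with a
bootstrap-assemblage asymptote; it is a short-range device, not an
asymptotic estimator.  The neutral fit maximises an expectation-based
(Volkov-type) likelihood, not the exact sampling likelihood of the full
abundance configuration (Etienne's formula); the approximation is
documented and switchable in principle, and the model-recovery tests bound
its practical cost.  K-S p-values ignore discreteness.  The Zipf $k=1$
convention (rank-1 proportion fixed) follows the packaged default and can
be freed per fit.
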