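# forestdiv

Community assembly and diversity analysis for stem-level forest
inventories.

`forestdiv` implements the analysis chain used to compare tree communities
of two altitudinal vegetation belts (a birch belt and a pine-oak belt, each
sampled as five secondary-forest stand types with five 30 × 30 m plots,
every stem with DBH ≥ 5 cm recorded):

* **Importance values** — per species, the mean of relative density,
  relative frequency and relative dominance (basal-area share):
  `IV = (RD + RF + Rd) / 3`, with `Σ IV = 100`; per family/genus, the
  overall relative importance `ORI = R.Ab + R.Fr`.
* **Hill-number diversity** — effective species numbers of order
  `q = 0, 1, 2` (richness, exponential Shannon entropy, inverse Simpson),
  with size- and coverage-based rarefaction and short-range extrapolation
  curves (Chao1/Chao2-anchored, extended to twice the smaller reference
  sample) and 200-replicate bootstrap confidence bands, for both
  individual-based (abundance) and plot-based (incidence) data.
* **SAD model selection** — broken-stick, niche-preemption, log-normal,
  Zipf, Zipf–Mandelbrot and the dispersal-limited neutral sampling formula
  (`φ_n` via log-Gamma quadrature), all fitted by one Poisson
  rank-abundance likelihood and ranked by `AIC = −2 log L + 2k`, with
  Kolmogorov–Smirnov agreement statistics.
* **Assemblage structure** — Bray–Curtis distances, group-average (UPGMA)
  clustering with a two-group cut, and correspondence analysis (chi-square
  SVD; total inertia = χ²/N), with Newick export and ggplot2 `autoplot()`
  methods throughout.
* **A synthetic survey generator** — `gen_survey()` draws a full two-belt
  stem table with known ground truth (configurable SAD per belt, shared
  species fraction, seeded and byte-reproducible), so the whole pipeline is
  testable without field data.

Functions take data frames first and return tibbles, so stages chain with
the pipe; fitted objects have broom-style `tidy()`/`glance()` methods.
See `vignette("community-assembly")` for the models, conventions and
numerical choices.

## Worked example

```r
library(forestdiv)
library(dplyr)

survey <- gen_survey(seed = 1)          # synthetic two-belt survey
stems  <- filter_dbh(survey$stems, 5)   # census threshold, inclusive

species_importance(filter(stems, belt == "pine-oak")) |> head(5)
#>   species                            n_i    RD   F_i    RF   d_i    Rd    IV
#> 1 Quercus aliena var. acutiserrata  1168 43.1      1  5.01 34.7  44.2  30.8
#> 2 Pinus tabuliformis                 414 15.3      1  5.01 11.5  14.7  11.7
#> 3 Pinus armandii                     240  8.86     1  5.01  7.13  9.09  7.65
#> 4 Toxicodendron vernicifluum         144  5.31     1  5.01  3.82  4.88  5.07
#> 5 Carpinus turczaninowii              99  3.65     1  5.01  2.81  3.58  4.08
```

The pine-oak belt is dominated by oak and pines (top importance value
30.8%, i.e. that species carries ~31% of the combined density, frequency
and basal-area shares); the IV column always sums to 100.

```r
birch <- pooled_abundance(filter(stems, belt == "birch"))
po    <- pooled_abundance(filter(stems, belt == "pine-oak"))
hill_number(birch$n_i)   # q0 = 43,  q1 = 27.08, q2 = 18.72
hill_number(po$n_i)      # q0 = 41,  q1 =  9.30, q2 =  4.45
extrapolation_limit(attr(birch, "N"), attr(po, "N"))  # 5420

hill_curve(birch$n_i, q = 1, knots = 10, reps = 50, seed = 1) |> tail(3)
#>        basis q    m coverage estimate ci_low ci_high         kind
#>  9 abundance 1 4446        1   27.149 26.211  28.087 extrapolated
#> 10 abundance 1 5081        1   27.165 26.226  28.104 extrapolated
#> 11 abundance 1 5716        1   27.178 26.238  28.117 extrapolated
```

Both belts hold ~40+ species, but the birch belt's effective diversity
(q = 1, 2) is several times the pine-oak belt's — the flat versus
concentrated dominance contrast the generator emulates.  The extrapolated
Shannon diversity flattens near its asymptote with a ±0.94 normal
bootstrap band.

```r
compare_sad_models(po$n_i)
#>             model k    logL    AIC ks_stat converged
#> 1            zipf 1  -102.2  206.3   0.171      TRUE
#> 2 zipf-mandelbrot 3  -101.3  208.6   0.171      TRUE
#> 3       lognormal 2  -151.1  306.3   0.268      TRUE
#> 4         neutral 2  -322.4  648.8   0.366      TRUE
#> 5      preemption 1  -712.3 1426.6   0.415      TRUE
#> 6    broken-stick 0 -1418.4 2836.7   0.415      TRUE

mat <- stand_species_matrix(stems)
cluster_stands(stand_distance(mat))$groups
#> group 1: AFBA BA CTBA PABA TCBA   (birch stands)
#> group 2: PA PAQA PT PTQA QA       (pine-oak stands)
correspondence_analysis(mat)
#> total inertia 0.4795, axis 1 = 86.6% of inertia
```

The AIC ranking recovers the generating model (this belt was simulated
from a Zipf SAD), the two-group UPGMA cut separates the belts exactly, and
the first correspondence-analysis axis carries the belt contrast.
`run_pipeline(run_config(...))` executes all stages and writes the tables,
a Newick dendrogram, and a JSON manifest (seed, parameters, checksums) to
an output directory.

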