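---
title: "Presence-background suitability modeling with suitcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-background suitability modeling with suitcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suitcast)
```

## The modeling problem

`suitcast` implements an end-to-end ecological niche modeling (ENM)
workflow for presence-only species occurrence data: given curated
occurrence records and a stack of gridded climate layers, it estimates a
climatic suitability surface with a maximum-entropy (MaxEnt)
presence-background model, tunes the model's regularization and feature
classes by AICc, evaluates it with a multi-metric panel on held-out
presences and 50%-prevalence pseudo-absences, and projects it onto
perturbed future climate stacks from an ensemble of global climate
models (GCMs), with binary change maps and latitude-weighted area
accounting. The motivating use case is mapping invasion risk for a
rapidly spreading agricultural pest (the tomato leaf miner is the
canonical example), but every stage is generic.

## The MaxEnt model

Let $x$ be a grid cell with covariate vector $v(x)$, and let
$f(x) \in [0,1]^J$ be the feature expansion of $v(x)$: linear (L),
quadratic (Q), pairwise product (P), forward hinge (H), and threshold
(T) features, each scaled to $[0,1]$ over the background sample. The
model is the Gibbs distribution over the $m$ background cells

$$ p_\lambda(x) = \frac{e^{\eta(x)}}{Z}, \qquad
   \eta(x) = \lambda^\top f(x), \qquad
   Z = \sum_{b=1}^{m} e^{\eta(b)}, $$

fitted by maximizing the L1-penalized presence log-likelihood

$$ \frac{1}{n}\sum_{i=1}^{n} \eta(x_i) \;-\; \log Z
   \;-\; \sum_j \beta_j |\lambda_j|, \qquad
   \beta_j = \mathrm{rm} \cdot \beta_{\text{class}(j)}(n) \cdot
             \frac{s_j}{\sqrt{n}}, $$

where $s_j$ is the feature's standard deviation over the presences and
$\beta_{\text{class}}(n)$ is the per-class default schedule interpolated
on presence count (linear/quadratic/product share one schedule falling
from 1 to 0.05; hinge is constant 0.5; threshold falls from 2 to 1).
The regularization multiplier `rm` scales all of them, so `rm = 1`
reproduces the defaults. Optimization is cyclic coordinate-wise proximal
Newton: each coordinate takes a Newton step on the smooth part (gradient
$\bar f_j^{\text{pres}} - E_p[f_j]$, curvature $\mathrm{Var}_p(f_j)$),
soft-thresholds at $\beta_j$, and backtracks on the true objective;
sweeps stop when the objective changes by less than `tol` (default
`1e-7`). Penalty-dominated fits shrink every coefficient to exactly
zero, and at `rm = 0` the fitted expectation of every active feature
matches its presence-sample mean — both limits are asserted in the test
suite.

Three output scales are provided. `raw` is $p_\lambda$ normalized over
the training background. `cumulative` is the percentage of raw mass at
or below a cell's raw value. `cloglog` is
$1 - \exp(-e^{H} \cdot \mathrm{raw})$, with $H$ the entropy of the raw
background distribution; for the uniform model this is exactly
$1 - e^{-1} \approx 0.632$ everywhere.

Projection onto new layers clamps covariates to the training background
range before feature construction, so extrapolated cells saturate
rather than explode. Hinge and threshold knots are placed at interior
background quantiles rather than fixed value ladders: quantiles are
scale-stable under monotone transformations of a covariate, which
matters when future stacks shift the covariate range. This is a
deliberate divergence from implementations that use evenly spaced value
thresholds.

## Occurrence curation

Occurrence records carry provenance flags. The temporal partition puts
natural (unflagged) records from 1981–2010 in the *basic* dataset — the
fixed-niche snapshot matching the climatology window — and natural
records from 2011–2024 in the *expanded* dataset; records flagged as
greenhouse or summer-only populations are *excluded* from modeling at
any date, because they persist outside the open-air climate envelope
and would inflate the apparent niche. Records without a usable year are
excluded with a warning.

Deduplication keeps one record per grid cell (earliest year, then input
order), so each environmental cell contributes a single presence.
Spatial thinning then removes records until the occurrence set is no
longer strongly autocorrelated: global Moran's I with inverse
great-circle-distance weights is computed on each screened
environmental variable at the occurrence cells, and while the maximum
across variables is at or above the target (default 0.2) the closest
pair of points is found and the member whose removal lowers that
maximum most is dropped (ties: the later-year record). The procedure is
deterministic, strictly shrinking, and fails loudly with diagnostics if
the target is unreachable before a floor count (default 30). Because no
single canonical variable exists for a multivariate thinning criterion,
the max-over-screened-variables rule is used; it is conservative in the
sense that every screened variable ends below the target.

## Predictor screening

Candidate covariates are screened on the background sample (the model's
domain): while any pair has $|r| \ge 0.8$ or any variable has
$\mathrm{VIF} \ge 10$, the violating variable with the lowest MaxEnt
percent contribution is dropped and everything is recomputed, refitting
the contribution model on the survivors each round. Contribution is
permutation importance: the drop in training AUC when a variable is
permuted across the combined presence and background rows, rescaled to
sum to 100. Ties break toward dropping the higher-VIF variable, then
lexicographically, making the audit trail replayable.

## Tuning and model selection

The candidate space is the Cartesian product of a regularization-
multiplier ladder (default 0.1 to 5.0 in steps of 0.1 — the ladder
starts at 0.1 because a fully unpenalized fit is degenerate for
hinge/threshold-rich designs) with the 31 non-empty subsets of
{L, Q, H, P, T}: 1550 candidates. Each candidate is fitted on a 75%
training share and scored by:

* `aicc` — $2k - 2\log L + 2k(k{+}1)/(n{-}k{-}1)$, where $k$ counts
  *nonzero* coefficients and the likelihood renormalizes the raw
  prediction over the full projection grid (a background-only
  normalization is available when no grid is supplied);
* `or_mtp`, `or_10` — test-presence omission below the training minimum
  and the nearest-rank 10th training percentile;
* `proc_ratio`, `proc_p` — the partial-ROC AUC ratio at tolerated
  omission $E = 0.05$, bootstrap-resampled (500 half-samples), with
  the p-value the fraction of resamples at or below ratio 1.

Champion selection filters to partial-ROC-significant candidates
(p < 0.05), then to `or_10` at most 0.1 — each filter is relaxed with a
warning if it would empty the pool — and takes the lowest AICc, with
ties going to fewer parameters and then smaller rm.

## Evaluation panel

All metrics are computed on the held-out 25% test share only. Exactly
as many pseudo-absences as test presences are drawn uniformly from
unmasked non-presence cells (prevalence 0.5). The max-TSS threshold is
found by exhaustive scan over all unique predicted values plus a 0.001
ladder; at that threshold the confusion table yields TSS, Cohen's
Kappa, Jaccard and Sorensen. Two algebraic identities are worth noting:
Sorensen $= 2J/(1+J)$ always, and at exactly 50% prevalence with a
shared threshold Kappa equals TSS. Published panels sometimes report
Kappa visibly below TSS under a stated 50%-prevalence design; that is
only possible if the two metrics were computed at different thresholds
or point sets, so `suitcast` reports both at the single max-TSS
threshold where they coincide by construction. Threshold-free metrics
complete the panel: rank-based AUC (ties counted half) and the
continuous Boyce index — predicted-to-expected presence ratios in 101
moving windows of width one tenth of the prediction range, Spearman-
correlated against the window midpoints, following the continuous-Boyce
literature's standard parameterization.

## Projection, ensembles, change maps

Suitability surfaces binarize at the near-current max-TSS threshold
(future periods are not re-thresholded). Areas are latitude-weighted on
the authalic sphere: a cell spanning $\Delta\lambda$ by
$[\phi_b, \phi_t]$ has area
$R^2 \, \Delta\lambda (\sin\phi_t - \sin\phi_b)$ with $R = 6371.0088$
km. Replicate variability is summarized by a per-cell SD map and a
consistency map (cells where at least 95% of replicates agree on the
binary class). The five-GCM ensemble is combined two ways — per-cell
mean suitability and per-cell fraction of GCMs voting suitable — since
both conventions are in active use; the change map classifies cells as
unchanged-suitable / unchanged-unsuitable / gained / lost and its area
totals satisfy the accounting identities exactly
(unchanged-suitable + lost = current suitable area, and analogously for
the future map).

## The synthetic world

Because real climatologies and compiled occurrence databases are
download-scale inputs, the package carries a generator that emulates
their statistical structure at desk scale:

* **Layers** — smoothed Gaussian white-noise fields (separable kernel,
  SD 6 cells by default) that are empirically orthogonalized and then
  mixed through the matrix square root of a target correlation matrix,
  plus a shared latitudinal gradient (weight 0.2). The
  orthogonalize-then-mix construction makes the realized correlations
  match the target to well within 0.1 even though spatially
  autocorrelated fields have few effective degrees of freedom. The
  default seven-layer panel uses a climate-like target: moderately
  correlated precipitation indices with one deliberately collinear pair
  (r = 0.85) for the screen to break up, weakly coupled temperature
  indices.
* **Truth** — a logistic transform of a standardized linear-plus-
  quadratic predictor (default: dominated by the February-temperature
  analog `tas2`, with a negative quadratic term giving the unimodal
  thermal response typical of ectotherm pests).
* **Occurrences** — 1000 records drawn cell-wise with probability
  proportional to truth (with replacement, so deduplication has work to
  do), dated to the 1981–2010 or 2011–2024 window; a 10% contaminant
  fraction is flagged greenhouse/summer-only and placed where truth
  < 0.05, mirroring protected-cultivation records that survive outside
  the climate envelope.
* **Futures** — five stacks whose temperature-like layers shift by an
  amount proportional to each GCM's relative warming magnitude
  (defaults 5.4, 4.6, 3.1, 3.0, 2.7 — the equilibrium-climate-
  sensitivity spread of a standard five-model CMIP6 ensemble) plus
  smooth anomalies, and whose precipitation-like layers rescale
  multiplicatively; zero magnitudes reproduce the input bit-for-bit.

What the generator does *not* emulate: realistic marginal distributions
of specific climate variables, coastline/elevation masks, observation
effort gradients, or spatially biased sampling. Passing tests therefore
demonstrate correctness of the machinery and recoverability under known
truth, not real-world predictive skill.

## Numerical choices and problem sizes

* All floating point is double precision; ASCII grids are written with
  17 significant digits so read/write round trips are bit-exact.
* The coordinate-descent tolerance is `1e-7` on the penalized
  objective; presence-feature SDs in the penalty are floored at `1e-3`
  so invariant-over-presences features stay penalized.
* Background defaults: 10,000 cells within a 500 km buffer of the
  presences. On the synthetic world the whole domain is the projection
  target, so study-scale analyses use a buffer covering the grid —
  background coverage of the scoring domain measurably improves rank
  recovery of the truth (the package's recovery check runs at Spearman
  about 0.95 with a full-domain background of 10,000 cells).
* Ties in `max_tss_threshold` break toward the lowest threshold;
  `select_champion` is a pure function of its input table.
* The bundled checks run the full workflow at deliberately modest sizes
  (a 100 x 100-cell world with 1000 presences for recovery and
  screening; a 40 x 40 world for pipeline smoke tests; tuning grids of
  a few rm values by a few feature-class sets) — large enough for the
  statistical contracts to hold, small enough to run routinely.

## Known limitations

* Categorical covariates and MESS-style extrapolation maps are not
  implemented; projection clamping is the only extrapolation control.
* The likelihood normalization for AICc uses the full projection grid
  by default; numbers are not comparable across different scoring
  domains.
* Moran's-I thinning recomputes the statistic after every removal; for
  occurrence sets much beyond ~2000 deduplicated records the O(n^2)
  weight matrix becomes the dominant cost.
* The pipeline assumes all layers share one grid; reprojection and
  resampling beyond integer block aggregation are out of scope.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(
  recipe = world_recipe(n_rows = 40, n_cols = 40, n_presences = 150,
                        layer_names = c("tas2", "bio15", "prec2"),
                        truth_coefficients = list(
                          linear = c(tas2 = 2, bio15 = 1),
                          quadratic = c(tas2 = -1)),
                        seed = 7),
  rm_values = c(1, 2), fc_values = c("L", "LQ"),
  background_size = 600, buffer_km = 3000, n_reps = 5,
  thinning_floor = 20, master_seed = 11)
run <- run_pipeline(cfg, out_dir = "run_artifacts")
print(run)
```

The printed report shows the record counts surviving each curation
stage, the retained variable panel, the tuning champion, the averaged
evaluation panel, and the area/change budgets; `run_artifacts/`
receives the suitability, SD, binary and change maps as `.asc`, the
candidate and evaluation tables as CSV, and a manifest with stage
hashes that replays bit-identically under the same master seed.
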