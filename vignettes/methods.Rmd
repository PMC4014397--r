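---
title: "Methods: superposition analysis of promoter activity dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: superposition analysis of promoter activity dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsup)
```

## The measurement and the model

`dynsup` works on batch-culture reporter experiments: each well of a
96-well plate carries a strain with GFP under a promoter of interest, and a
plate reader samples optical density and fluorescence every ~8 minutes from
inoculation until stationary phase. Promoter activity is the rate of GFP
accumulation per unit of cell mass,

$$P(t) = \frac{1}{\mathrm{OD}(t)}\,\frac{dG}{dt},$$

a proxy for the transcription rate. The analysis asks how $P$ in a medium
with several supplements relates to $P$ in media with each supplement
alone, and rests on two empirical regularities it also provides the tools
to test:

1. **Low-rank dynamics.** For a given promoter, the activity curves across
   all measured conditions lie close to a one- or two-dimensional space of
   *shape curves* (principal component curves of the conditions ×
   generations matrix).
2. **Linear superposition.** The curve in a combined condition is close to
   a *weighted average* of the single-condition curves, with non-negative
   weights summing to one. The sum-to-one constraint is what makes
   higher-order combinations predictable from pairs.

Fitting is exposed as one function, `superpose(target, singles, model)`,
returning a classed fit with `coef`, `fitted`, `residuals`, `predict`,
`plot`, `print`, and `summary` methods. Three model variants are fit:

* `superposition` — least squares under $w_i \ge 0$, $\sum w_i = 1$. For
  $\le 4$ singles the solver enumerates all supports and solves each
  equality-constrained subproblem by its KKT system; this is exact (no
  iterative tolerance) and deterministic.
* `unconstrained` — an error-in-variables (total least squares) linear
  combination. All curves, singles included, are treated as equally noisy;
  the solution is the right singular vector of the smallest singular value
  of $[P_1 \cdots P_N \,|\, P_{\rm target}]$, rescaled so the target
  coefficient is $-1$. If that coefficient vanishes (a degenerate
  direction) the fit falls back to ordinary least squares and says so in
  its `notes`.
* `multiplicative` — the competing hypothesis that conditions combine
  multiplicatively: $\ln P_{\rm target}$ is fit as a simplex combination of
  $\ln P_i$, i.e. the target is modeled as a weighted geometric mean.
  Because the exact published form of this alternative is not available,
  the weighted geometric mean is this package's declared reading; its fit
  error is reported in the linear domain so the three models are
  comparable.

Model comparison uses $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ — a
Gaussian likelihood with unknown common variance, the package's declared
choice — with $k$ the number of free weights ($N-1$ on the simplex, $N$
unconstrained). The relative fit error is
$\|\hat P - P\|_2 / \|P\|_2$ by default (`error_norm = "mae"` gives a
mean-absolute alternative; outputs state which was used).

## From raw traces to comparable curves

**Background.** Fluorescence of a promoterless-vector control well (same
condition, same day) is subtracted point-wise, with linear interpolation if
the control sits on a shifted time grid. Negative values are kept by
default so the derivative sees unbiased noise (`clip = TRUE` floors at
zero). OD is not blank-corrected by default; the assay this emulates does
not document OD blanking, and a constant blank can be handled upstream.

**Derivative.** The slope of a sliding window of `window = 17` samples of
fluorescence versus time (ordinary least squares, centered, stride 1),
divided by the mean OD over the window. One value per window center;
endpoints without a full window are dropped. Seventeen 8-minute samples
(~2.3 h) suppress measurement noise well; window sizes from 5 to 30 change
smoothness, not conclusions, and `window` is a parameter everywhere.

*Estimator bias.* The windowed slope-over-mean-OD estimator has a
curvature bias of order $(r\,\Delta t\, h)^2$ (growth rate $r$, sampling
step $\Delta t$, half-window $h$): during exponential growth the window
mean of OD exceeds the center OD, and at the fastest simulated condition a
17-sample window spans ~2 generations, smearing sharp features. The bias is
a few percent and — importantly for mixture fitting — differs between
conditions with different growth rates. For this reason the package's
*noiseless* validation of end-to-end weight recovery runs at `window = 5`,
where the bias is negligible; noise-bearing analyses use the default 17.

**Generation axis.** Conditions with different growth rates are aligned by
cumulative doublings $g(t) = \log_2(\mathrm{OD}(t)/\mathrm{OD}_{\rm ref})$.
OD is smoothed in the log domain (window mean of $\ln$ OD — the local
linear fit at the window center, exact under exponential growth), and a
cumulative maximum enforces monotonicity under noise. The reference is the
smoothed OD extrapolated to the *first raw time point* (`origin =
"culture_start"`): wells are inoculated from a common dilution, so this
anchors all conditions to a shared axis. Anchoring instead at the first
window center (`origin = "first_window"`) is available but shifts
fast-growing conditions by up to ~0.6 generations relative to slow ones,
which misaligns the curves that the mixture model compares; that is why it
is not the default. Points with non-positive OD become missing and are
dropped before interpolation.

**Common grid.** Curves are linearly interpolated onto `n_points = 100`
uniform generations spanning the *intersection* of their ranges — never the
union, so no curve is extrapolated. Ties on the flat stationary-phase axis
are averaged.

## Principal component curves

Per promoter, replicate days are averaged arithmetically and the
conditions × grid matrix is decomposed by SVD *without centering*
(`center = TRUE` is available for comparison): each condition's curve is
modeled as a plain linear combination of the component curves with no mean
term, so a promoter whose dynamics changes only in amplitude is exactly
rank one. Variance fractions are $\sigma_i^2/\sum_j \sigma_j^2$. The
randomized null permutes entries within each grid column across conditions
(preserving each time point's marginal) and recomputes the 2-PC fraction;
it is seeded and deterministic. The correlation of the first component with
the instantaneous growth rate ($d\ln \mathrm{OD}/dt$, windowed slope of log
OD) is reported as a squared Pearson correlation.

## Weights, identifiability, and conditioning

Mixture weights are well determined only when the single-condition curves
are sufficiently independent. With replicate noise of relative size
$\varepsilon$, weights are unidentifiable once the singles' condition
number $\kappa$ exceeds roughly $1/\varepsilon$; at the default 14%
day-to-day noise averaged over 4 replicates, $\varepsilon \approx 0.07$ and
the package marks fits with $\kappa > 15$ (`kappa_max`) with a collinearity
note. Such fits still report an excellent *curve* fit — the mixture is
nearly one-dimensional — but their *weights* carry little information, and
summaries that compare weights to ground truth exclude them.

Two further consequences of noise that is (multiplicatively) common to a
whole curve, as day-to-day factors are:

* The simplex constraint cannot absorb the target's amplitude factor and
  projects it onto the weights, amplified along the ill-conditioned
  direction. The error-in-variables fit absorbs it in the weight *sum*
  instead; normalizing EIV weights by their sum is therefore the package's
  estimator when recovered weights are compared to simplex ground truth.
* The EIV estimate itself is heavy-tailed on nearly collinear singles
  (weight sums can reach tens in magnitude), so `weight_sum_statistics()`
  reports the median alongside the mean and SD; the median is the stable
  summary of where weight sums concentrate.
* With $n = 100$ grid points, AIC rewards the unconstrained model whenever
  its extra amplitude degree of freedom lowers RSS by more than
  $e^{2/n} \approx 2\%$ — which per-curve amplitude noise essentially
  guarantees. Superposition is AIC-preferred when the discrepancy between
  target and mixture is exchangeable across grid points rather than a
  common scale factor; the model-selection property test is constructed
  accordingly.

## Predicting cocktails from pairs

Writing $w_i^{(\neq j)}$ for the weight of single $i$ within the cocktail
missing supplement $j$, self-consistency of all $N$ decompositions of an
$N$-cocktail yields

$$w_i = \frac{N-2}{\sum_{j\neq i} 1/w_i^{(\neq j)} - 1},$$

which returns the exact simplex point whenever the lower-order weights are
its renormalized restrictions $w^*_i/(1 - w^*_j)$ — the property the
implementation is validated against (direct algebra: the sum telescopes to
$(N-2)/w^*_i$). Non-positive lower-order weights propagate to a zero
prediction for that supplement; the raw vector is then clipped to $[0,1]$
and renormalized. With pair data only the formula is applied level by
level: pairs → triplets → quadruplet. Inputs are the simplex-constrained
fits by default; unconstrained fits can be fed in after clipping.

Prediction quality is judged against two anchors: the day-to-day replicate
error (the symmetrized mean of pairwise relative errors — the L2 ratio is
asymmetric in its denominator, so both orders are averaged), and a
deterministic exemplar baseline that "predicts" a condition's curve by each
of the promoter's other measured curves and averages the errors (the
exhaustive mean a random-exemplar scheme converges to).

Violations of superposition — promoters regulated *sequentially* by two
conditions, the diauxic-shift phenomenology — are flagged when the best
linear-combination error (the smaller of the superposition and EIV errors)
exceeds `violation_threshold = 0.2` in any combined condition.

## The synthetic plate generator

The simulator provides ground truth with the statistical structure the
analysis assumes, under the study conditions it emulates:

| parameter | default | meaning |
|---|---|---|
| labels | A, B, C, D | supplements; 15 combinations |
| `n_days` | 4 | replicate days |
| `day_sigma` | 0.14 | log-normal day factor per (promoter, condition, day) |
| `od0`, `od_max` | 0.15/2⁶, 0.15 | inoculation and carrying-capacity OD (~6 doublings) |
| `dt_min` | 8 | sampling interval (min) |
| `rates` | 0.0115, 0.0052, 0.0088, 0.0070 /min | single-condition logistic rates |
| `od_sigma`, `fluo_sigma` | 3·10⁻⁴, 5 | per-time-point measurement noise |
| `background_fluo` | 100 | constant background level |
| `frac_single_shape` | 1/3 | amplitude-dominated promoters |
| `n_violators` | 1 | diauxie-like promoters |

Latent shape 1 is proportional to the instantaneous growth rate on the
generation axis ($1 - 2^{g - G}$ for a logistic culture $G$ doublings below
capacity — the same shape in every condition up to scale), so the first
principal component is growth-coupled by construction. Shape 2 is a
Gaussian bump in generations with a random center. "One-shape" promoters
carry a small residual second loading (5–25 vs 50–200 activity units)
because real promoters are never exactly rank one — their best
one-component description leaves a few percent unexplained — and an exactly
rank-one basis would make mixture weights unidentifiable by any method.

Each promoter draws one flat-simplex point over the four labels; every
condition subset's true weights are its renormalized restriction, so the
self-consistent weight hierarchy that the prediction formula presumes holds
by construction. Mixing happens at the *activity level on the generation
axis* — the model's own domain — and is then pushed through logistic
growth, trapezoidal GFP integration, background addition, day factors, and
measurement noise into plate-reader wells (96-well layout, one promoterless
control per condition/day group). Measured values are quantized to
instrument-like precision (OD 10⁻⁶, fluorescence 10⁻³) so written CSV
tables round-trip exactly. Growth rates were fixed so saturation spans
roughly 12.6–22 h inside the assay's 8–22 h envelope, at the slower end to
keep the window-curvature bias of the derivative estimator small relative
to the signal.

What the generator does *not* emulate: lag phases, GFP maturation kinetics,
plate-position effects, OD detection floors, shape (as opposed to
amplitude) components of day-to-day error, or mechanistic transcription
models. Passing recovery tests therefore demonstrates the estimation
chain's correctness under the declared noise model, not robustness to every
artifact of real plate data.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: per-window
regression by brute force, variance fractions against an eigendecomposition
of the Gram matrix, simplex fits against a 0.001-step grid search, EIV fits
against the smallest eigenvector of the cross-product matrix, the
prediction formula against 1000 random simplex points per cocktail size,
and end-to-end weight recovery against the generator's truth (50 noiseless
promoters at window 5; 200 noisy promoters at window 17, EIV-normalized,
well-conditioned fits; medians reported). Violation detection is checked
over 20 simulation seeds of the default 20-promoter experiment. These sizes
are the package's chosen balance between statistical resolution and a test
suite that runs in well under a minute per property.

`scripts/acceptance.R --seed S --out f.json` recomputes the headline
quantities (replicate error, per-day and day-averaged fit errors,
prediction medians by cocktail size, exemplar baseline, weight-sum
statistics, 2-PC fractions, PC1–growth correlations, recovery errors, the
formula's worst-case error) from freshly simulated data; every number it
writes is produced by running the pipeline at run time.

Fit error is reported in two poolings, because the choice is genuinely
open: *per-day* (each day's combined curve against the same day's singles,
the error a single experiment would see) and *day-averaged* (fits to
4-day-mean curves, the error the final weight table is built from). The
per-day figure is the one comparable to a replicate-noise floor.

## Known limitations

* Weights of nearly proportional singles are reported but weakly
  identified; consult the fit's `notes` and `kappa_max` before interpreting
  them.
* The generation axis assumes a shared inoculation density; wells seeded at
  very different densities would need explicit re-anchoring.
* The multiplicative model is one declared reading (weighted geometric
  mean) of a family of multiplicative alternatives.
* Un-centered PCA and arithmetic replicate averaging are declared choices
  (`center_pca` switches the former); results metadata state which was
  used.
* The pipeline does not segment lag or stationary phases; the intersection
  grid simply excludes generations not covered by all curves.
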