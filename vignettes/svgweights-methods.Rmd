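---
title: "Precision-weighted detection of spatially variable genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-weighted detection of spatially variable genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Spatially resolved transcriptomics (SRT) platforms such as 10x Visium
measure UMI counts $r_{gi}$ for genes $g = 1,\dots,G$ at spatial locations
(spots) $s_i$, $i = 1,\dots,n$. A routine analysis task is to rank genes by
the strength of their spatial expression structure — spatially variable
gene (SVG) detection. Most detectors operate on log-normalized expression,
and log transformation of counts is known to induce a *mean–variance
relationship*: high-count observations have small log-scale variance and
low-count observations large log-scale variance. Because SVG statistics are
variance decompositions, this technical coupling leaks into the ranking —
highly expressed genes are systematically prioritized — and the effect is
an artifact of normalization, not biology. `svgweights` estimates
observation- and gene-level precision weights from the empirical
mean–variance trend and feeds them back into the detector so that the
ranking is (approximately) freed of this bias.

## The detection model

Per gene, expression on the logCPM scale,

$$y_{gi} = \log_2\!\left(\frac{r_{gi} + 0.5}{R_i + 1}\times 10^6\right),
\qquad R_i = \sum_g r_{gi},$$

is modeled as a Gaussian process regression

$$\mathbf{y} \sim N(\mathbf{X}\beta,\; \sigma^2 K(l) + \tau^2 I),
\qquad K_{ij}(l) = \exp(-\lVert s_i - s_j\rVert / l),$$

with $\mathbf{X} = \mathbf{1}$ by default. The exponential kernel is the
Matérn covariance with smoothness $1/2$; $\sigma^2$ is the spatial
variance, $\tau^2$ the nugget, and $l$ the lengthscale. The pseudocounts
$0.5$ and $1$ keep the CPM argument in $(0, 10^6)$, so all $y_{gi}$ are
finite even for empty spots (which are retained with a warning; the
formula stays proper and dropping data silently seemed worse).

Each gene is scored by the likelihood-ratio statistic against the
non-spatial linear model ($\sigma^2 = 0$, iid noise with ML variance),
referred to a $\chi^2_2$ distribution ($\sigma^2$ and $l$ both vanish
under the null). Since the null value $\sigma^2 = 0$ sits on the boundary
of the parameter space, the $\chi^2_2$ reference is conservative; the test
is used for *ranking* (largest statistic = rank 1, ties broken by first
occurrence) and for threshold sweeps in the evaluation module, not as a
calibrated test. The effect size reported alongside is the proportion of
spatial variance $\hat\sigma^2/(\hat\sigma^2 + \hat\tau^2)$. A Moran's I
baseline ranking (row-normalized inverse-distance weights) is also
provided.

### Likelihood evaluation: exact and Vecchia

For $n$ up to a configurable dense limit (default 2000) the likelihood is
evaluated with a dense Cholesky factorization. Above that, a
nearest-neighbor (Vecchia) factorization is used: spots are ordered by the
sum of their scaled coordinates and each spot conditions only on its $m$
nearest already-ordered neighbors ($m = 15$ by default, standard NNGP
practice). For $m \ge n-1$ the factorization is exact, which the test
suite asserts to $10^{-8}$; at $m = 15$ the log-likelihood error is below
1% on the grid sizes used here. Distances that recur on lattice-like
coordinates are exponentiated once per evaluation through a distinct-value
table, which is an exact optimization (no rounding) and matters because
per-gene fitting evaluates the likelihood hundreds of times.

### Optimization

Maximum likelihood is computed with L-BFGS-B on log-transformed
parameters with three lengthscale multi-starts (scaled lengthscales 0.05,
0.2, 0.5) to guard against the well-known multimodality of GP likelihoods.
Coordinates are internally rescaled so the longer axis spans $[0,1]$;
scaled-lengthscale bounds are $[10^{-3}, 2]$ and fitted lengthscales are
reported in both original and scaled units ("scaled lengthscale 0.15" =
15% of the tissue's maximum extent). One deliberate design choice: the
overall variance scale has a closed-form ML solution given the
nugget-to-spatial ratio $\delta = \tau^2/\sigma^2$ and $l$, so the
optimizer works over $(\log\delta, \log l)$ only and the scale is
profiled out analytically. This halves the number of likelihood
evaluations relative to optimizing all three parameters and removes the
need for data-dependent variance bounds; the maximizer is the same. A
nugget floor of $10^{-8}\,\mathrm{var}(y)$ prevents singular
factorizations; constant genes short-circuit to a null fit (LR = 0) rather
than crashing; genes whose optimizer fails to converge keep their
best-found statistic (flagged `converged = FALSE`) so the ranking always
covers all genes.

## Precision weights

The weight pipeline mirrors the voom idea, with the GP replacing the
linear model so that spatial correlation is accounted for when residual
variability is measured:

1. **Residual SD per gene.** From the intercept-only GP fit,
   $s_g = \sqrt{\sum_i (y_{gi} - \hat\mu_{gi})^2 / (n-1)}$ with
   $\hat\mu_{gi} = x_i^\top\hat\beta_g$. The trend is fitted on
   $\sqrt{s_g}$, which is roughly symmetrically distributed.
2. **Count-scale abscissa.** The per-gene mean logCPM $\bar y_g$ is mapped
   back to the count-log2 axis with the geometric mean library size:
   $\tilde r_g = \bar y_g + \log_2\tilde R - \log_2 10^6$, where
   $\tilde R = \exp(\tfrac1n\sum_i \log R_i)$, computed in log space. (A
   sum of raw logs without the $1/n$ is *not* a geometric mean and would
   overflow — the very thing the construction avoids; we implement the
   true geometric mean. Zero library sizes fall back to $R_i + 1$ with a
   warning.)
3. **Trend.** A cubic smoothing spline (`stats::smooth.spline`, GCV
   smoothness) of $\sqrt{s_g}$ on $\tilde r_g$, requiring $G \ge 10$.
   Monotonicity and positivity are *not* enforced; the curve is whatever
   the data supports.
4. **Per-observation prediction.** Each fitted mean is mapped to a
   predicted count value $\hat\lambda_{gi} = \hat\mu_{gi} +
   \log_2(R_i + 1) - \log_2 10^6$. With an intercept-only design
   $\hat\mu_{gi}$ is constant in $i$, but $\hat\lambda_{gi}$ still varies
   through $R_i$ — this is what makes the weights observation-level.
5. **Weights.** $w_{gi} = \mathrm{spl}(\hat\lambda_{gi})^{-4}$: the spline
   predicts the square *root* of the residual SD, so the fourth power is
   the predicted variance, and the weight is its inverse. Values of
   $\hat\lambda_{gi}$ outside the spline's training range are clamped to
   the boundary (no extrapolation); the package clamps to the range of
   $\tilde r$ by default, since $\hat\lambda$ and $\tilde r$ live on the
   same axis, with `clamp = "ybar"` available for the alternative reading
   that clamps on the mean-logCPM range. Spline excursions at or below
   zero are floored at $10^{-4}$ before inversion (with a warning), since
   an unconstrained spline can cross zero.

## Weighted detection (Delta-method rescaling)

With $W = \mathrm{diag}(w_{gi})$ for one gene,
$W\mathbf{y} \sim N(W\mathbf{X}\beta,\; W\Sigma W)$ and
$W\Sigma W = W C W + \tau^2 W^2$, which is again "kernel plus nugget" in
form. So the weighted fit runs the unmodified GP detector on
$(W\mathbf{y}, W\mathbf{X})$, where $\mathbf{X}$ carries an explicit ones
column and the fit adds *no* intercept of its own — the weighted ones
column replaces it (an unweighted intercept would be wrong, and silently
absorbing one is the classic implementation error here). The LR null model
is the *weighted* linear model ($W\mathbf{y}$ on $W\mathbf{X}$), so the
test compares like with like. By default the data are multiplied by $w$
itself, following the construction above literally;
`weight_scale = "sqrt"` is available because inverse-variance weighting
conventions elsewhere multiply by $\sqrt{w}$, and which of the two a given
downstream tool expects is worth checking. With all weights equal to 1 the
weighted path reproduces the unweighted path bit for bit (asserted in the
tests).

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws, per gene, a mean log-rate
$\beta \sim U[\ln 0.5, \ln 1]$ and, for non-null genes, a spatial variance
$\sigma^2 \sim U[0.2, 1]$ — independently of $\beta$, so spatial signal
occurs at all expression levels and any mean-rank association in the
output is attributable to the detector, not the truth. The log-rate is
$\beta + \eta$ with $\eta \sim N(0, \sigma^2 K_0)$, a single fixed
lengthscale for all genes, and counts are Poisson:
$c_i \sim \mathrm{Poisson}(e^{\beta + \eta_i})$. Coordinates form a
Visium-like hexagonal lattice; the default 31×32 grid at spacing 100
(992 spots) approximates the ~968-spot subset used in the source study, so
lengthscales 50/60/100/500 are directly meaningful (100 ≈ 2% of the
tissue extent).

Choices worth stating:

* **Null genes.** FDR/TNR/TPR need ground-truth negatives, so a
  `null_fraction` (default 0.5 for evaluation runs) of genes get
  $\sigma^2 = 0$.
* **Kernel.** The generator's default is the squared-exponential
  $\exp(-d^2/2l^2)$; the description it implements ("Matérn kernel with
  squared exponential distance") is ambiguous, an `exponential` option is
  one flag away, and the mismatch with the detector's exponential kernel
  is kept deliberately — detectors never see their own generative kernel
  in real data.
* **Jitter.** $10^{-8}$ on the diagonal if the kernel Cholesky fails
  (routine for the squared-exponential).

What the simulator does **not** emulate: segmentation/tissue artifacts,
spot-level quality variation, zero inflation beyond Poisson sampling, and
— importantly — any *additional* mean–variance bias mechanism beyond what
Poisson sampling plus log transformation induces. A green bias-removal
test therefore establishes that the weights counteract the
normalization-induced bias in this generative world, not that they fix
every dataset-specific artifact.

## Evaluation machinery

* **Decile diagnostic.** Genes are binned into deciles of mean logcounts
  (ties go to the lower decile via first-occurrence ranking, so decile
  sizes differ by at most one — quantile binning would not guarantee
  that). "Signal" is the top `floor(G/10)` ranks; an unbiased method
  spreads signal evenly across deciles.
* **Bias metric.** Spearman correlation between mean logcounts and rank,
  over true SVGs when truth is available. 0 = unbiased; negative = high
  expression buys better ranks.
* **Error curves.** Raw p-value thresholds are swept over 200 log-spaced
  points in $[10^{-4}, 0.5]$; at each threshold FDR, TPR, TNR come from
  the confusion matrix (FDR = FP/max(1, FP+TP); no multiplicity
  adjustment — the sweep is over the Type I error level itself). Curves
  from multiple seeds are averaged pointwise. TPR comparisons "at matched
  achieved FDR" take, for each FDR level, the best TPR attained at or
  below it.

## Numerical and degenerate-input policy

* Exact/Vecchia agreement is asserted at $10^{-8}$; the dense path
  refuses $n$ above its limit rather than silently thrashing.
* Duplicate spots are fine whenever $\tau^2 > 0$ (the nugget
  regularizes).
* Weights must be strictly positive and finite everywhere — a zero weight
  is a validation error, not a soft warning, because it silently deletes
  an observation.
* All randomness flows from explicit seeds; reruns of the CLI with the
  same configuration are byte-identical, and each output carries a JSON
  sidecar with version, seed, and parameters.

## Known limitations

* Weighted and unweighted rankings differ only modestly when library
  sizes are nearly uniform, because intercept-only fitted means make the
  within-gene weight profile depend on $R_i$ alone; the bias reduction is
  correspondingly modest in the simulated world (and is tested as a
  strict, if small, improvement).
* The $\chi^2_2$ reference is conservative (boundary null); calibrated
  significance would need a mixture reference or permutation.
* Only the exponential kernel is fitted (Matérn $\nu = 1/2$); a general
  smoothness parameter is out of scope.
* The GP mean is intercept-only unless the caller supplies covariates;
  rich designs are untested territory.
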