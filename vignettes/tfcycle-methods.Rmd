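---
title: "Inferring periodic transcription factor activities over the yeast metabolic cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring periodic transcription factor activities over the yeast metabolic cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcycle)
```

## The problem

Continuously cultured, nutrient-limited budding yeast settles into a
self-sustaining metabolic cycle with a period of roughly 300 minutes. Each
cycle passes through three phases, visible directly in dissolved oxygen:
a short oxidative burst (Ox, oxygen drops sharply), a reductive/building
phase (R/B, oxygen rises, cells enter the cell cycle), and a long
reductive/charging phase (R/C, oxygen roughly constant). Over half of
yeast genes oscillate with this cycle. The question the package addresses
is which transcription factors drive these genome-wide oscillations, and
how the factors influence one another over time.

Direct measurements of factor activity over time are not available; what
is available is (a) a gene-by-time-point expression matrix and (b) a
gene-by-factor promoter-binding matrix from genome-wide ChIP. The package
combines the two to reconstruct per-time-point factor activities and then
analyses those activities as time series.

## The activity model

The core assumption is multiplicative: relative expression of gene $i$ is
proportional to a product of contributions from the factors bound at its
promoter,

$$R_i = c \prod_{j=1}^{N} b_{ij}^{\alpha_j},$$

where $b_{ij} > 0$ is the binding coefficient of factor $j$ at gene $i$
and $\alpha_j$ is the activity of factor $j$. Taking logarithms gives a
linear model per time point,

$$\log R_i = c + \sum_j \alpha_j \log b_{ij},$$

which is fit by robust multiple regression across genes, independently at
each time point. Non-targets sit at the neutral baseline $b = 1$
($\log b = 0$), so they contribute nothing — the only convention under
which absence of binding is truly neutral in the product model. Genes with
a missing (or non-positive, hence log-undefined) expression value at a
given time point are excluded from that time point's regression only; rows
are never dropped globally.

### Robust fit

The regression is iteratively reweighted least squares with Tukey
bisquare weights and tuning constant 4.685 (95% Gaussian efficiency), an
intercept always included. Iteration stops when the largest relative
coefficient change falls below $10^{-8}$; the default cap is 100
iterations, which covers the slow tail observed when binding columns are
strongly correlated. On noiseless data every weight is 1 and the robust
fit coincides with ordinary least squares — a property the test suite
asserts.

Residual scale is estimated in three steps: $\sigma_{OLS}$ is the RMSE of
the unweighted fit; $\sigma_{robust} = \mathrm{MAD}/0.6745$ of the
converged residuals about their median (unbiased for Gaussian noise); and
the final scale is
$\sigma = \max\{\sigma_{robust},\; w\,\sigma_{OLS} + (1-w)\,\sigma_{robust}\}$.
The blending weight $w$ is not pinned down by any published account of
this estimator family, so it is exposed as an option with default
$w = 0.5$. Standard errors come from
$\sigma^2 (X^\top W X)^{-1}$ and p-values from a two-sided $t$ test with
$n_{\mathrm{genes}} - n_{\mathrm{factors}} - 1$ degrees of freedom; the
published method reports standard errors without stating the reference
distribution, and the $t$ form is the standard choice for a
regression-scale statistic.

### Iterative selection

Most of the ~200 candidate factors have no resolvable activity. Each
selection iteration counts, per factor, the time points with $p < 0.1$
and simultaneously drops every factor with fewer than 9 of 36; survivors
are refit and the loop repeats to a fixed point. Simultaneous (rather
than one-at-a-time) elimination matches a batch "recalculate the
survivors" reading of the procedure and makes the retained sets nested by
construction. On the published data this funnel goes 203 → 20 factors.

## Periodicity

Each activity profile is scored by the raw, unscaled autocorrelation at
the one-period lag, normalized by the zero-lag value:

$$s = \frac{\sum_{t} x_t x_{t+P}}{\sum_t x_t^2}, \qquad P = 12 \text{ samples}.$$

No mean-centering is applied by default. This has a consequence worth
stating plainly: for $n = 3P$ observed samples the score of any exactly
period-$P$ signal — including a constant — is exactly $(n-P)/n = 2/3$,
which is also the attainable maximum. That the top published score (0.631)
sits just below 2/3 is consistent with this non-centered convention;
centering is available behind a flag for sensitivity analysis. The lag is
rounded from period/sampling-interval with a warning when the ratio is not
integral (the real grid's 24.7-min interval rounds 12.15 to 12).

Significance is assessed by permuting the time order ($N = 1000$ by
default, seeded). Two references are supported: the conventional
permutation p-value compares permuted scores to the observed score and is
approximately uniform for noise profiles (a property tested by
Kolmogorov–Smirnov at 200 replicates); passing a fixed threshold instead
asks how often random orderings clear the retention cut (0.44), the
convention behind the published pooled exceedance rate, which
`score_periodicity()` also reports. Factors scoring at or above 0.44 are
retained — the boundary is inclusive, since the published rule discards
scores *below* the threshold. On the real data this step goes 20 → 13
factors.

## Phases and amplitudes

Because all candidate model patterns share the cycle period, the phase
decomposition collapses to fitting the single best sinusoid
$A \sin(2\pi t/P + \phi) + m$. The phase is searched on a 1° grid
(matching the integer-degree resolution of published phase tables), with
the amplitude and offset set by exact least squares at each candidate
phase; over whole cycles the optimal phase does not depend on the trial
amplitude, so this sequential search equals joint minimization, and the
test suite checks it against the closed-form sin/cos-regression fit. An
explicit offset $m$ is included because activity profiles are not
zero-mean. The time origin is $t = 0$ at the first sample; amplitude is
reported non-negative (negative amplitude ≡ 180° phase shift).

Peak phases are computed separately: the 36-point profile is averaged
over its three cycles to 12 points, the maximum located (ties broken by
the earliest position, flagged), and the position mapped to degrees
(position $k \mapsto 30k°$). Angles map to cycle phases through the fixed
partition Ox = [285°, 345°), R/B = [165°, 285°), R/C = the remaining
180° wrapped arc — R/C is correctly the longest phase. Independently,
time points are labelled from the oxygen trace by the sign of its
finite-difference slope with a dead band of half the slope standard
deviation: steep drop → Ox, rise → R/B, else R/C.

The angular registration between sine-fit phases and absolute experiment
time is fixed by the conventions above rather than inferred from
published polar figures, whose registration is not fully specified; the
conventions are documented so results are comparable run to run.

## Dynamics and the regulatory network

Activities (with the oxygen trace z-scored and rescaled to the median
per-factor activity standard deviation, appended as an extra "factor")
are modelled as a linear time-translation system
$\alpha_{t+1} = T\,\alpha_t$. With columns as time points, $A$ = all but
the last column and $B$ = all but the first, the unconstrained estimate
minimizes $\lVert B - TA\rVert_F$ and is computed via the pseudoinverse —
identical to the normal-equations solution at full rank, minimum-norm
(with a warning) otherwise. The orientation contract, not any transpose
convention, is normative: $T$ applied to the activity vector at $t$
approximates the vector at $t+1$, verified by recovery tests on noiseless
trajectories. A non-negative variant fits each row of $T$ by
Lawson–Hanson NNLS. Because the unconstrained feasible set is larger, its
fit residual can never exceed the constrained one — an inequality the
tests assert on every seeded dataset, and the package's reason (matching
the published conclusion) for extracting the network from the
unconstrained matrix: with sign-flipped activity pairs in the data, large
negative couplings are as meaningful as positive ones.

Model adequacy is reported per time point in two conventions: the
mean-over-factors difference between observed and simulated activities
(the published convention), and the per-time-point RMSE as a stricter
diagnostic. Eigen-decomposition of $T$ yields asymptotic modes: modulus =
per-step decay/growth, and $2\pi/|\arg\lambda|$ = oscillation period in
samples for complex pairs.

Entries with $|T_{kj}|$ at or above 0.5 become directed edges
$j \to k$. The comparator is inclusive by default (published wording is
ambiguous between "greater than 0.5" and "threshold of 0.5"; both are
exposed). When a pair is significant in both directions only the
larger-magnitude direction is kept (exact ties keep both, flagged);
self-loops are recorded in $T$ outputs but excluded from graph exports.

## Clustering

Profiles are clustered hierarchically on $|\alpha|$ — activators and
repressors acting in the same regulatory group show mirror-image curves,
and the absolute value makes such pairs coincide. The external tool used
originally does not document its algorithm, so the defaults here are
Euclidean distance with average linkage, both configurable; the
two-cluster separation test runs under the defaults.

## The synthetic-data generator

Real inputs require external downloads, so the package generates datasets
with the statistical structure the analysis assumes, plus full ground
truth. The default spec mirrors the study conditions: 36 time points at
25-minute spacing (three 12-sample cycles), 13 active factors among 37
decoys, and two activity shape families — five smooth sinusoids
(amplitudes 0.50–0.70, phases 200°–255°, echoing the similar amplitudes
and clustered phases of the published smooth group) and four sign-flipped
spike pairs (a 0.35-amplitude baseline sine plus a ±1.2 Gaussian pulse of
width 0.8 samples repeated each cycle, mimicking the sharp per-cycle
spikes seen in the oxidative phase). Binding assigns each factor 30
target genes out of 200 with log-strengths from a positive-truncated
N(1, 0.3); expression follows the multiplicative model with log-noise sd
0.15 and 2% missing cells; oxygen is a sawtooth (2-sample drop, 4-sample
rise, 6-sample plateau) whose construction labels are recovered exactly
by the slope classifier. Dimensions keep the genes ≫ factors regime the
regression needs while the whole pipeline runs in seconds; all generators
are deterministic given the seed.

What the generator does *not* emulate: microarray hybridization physics,
correlated (non-i.i.d.) measurement noise, condition-dependent binding
(the ChIP matrix is treated as static, as the model assumes), and any
metabolite beyond oxygen. Passing tests therefore demonstrate that the
pipeline recovers the truth of its own generative model at realistic
noise, not that the model is a complete account of real chemostat data.

## Numerical choices and degenerate inputs

- Natural log throughout; activities are log-base invariant (only the
  intercept shifts), asserted as an equivariance test.
- Zero-energy profiles make the periodicity score undefined (error);
  zero-variance profiles yield amplitude 0 with an indeterminate-phase
  flag; constant oxygen traces label everything R/C with a warning.
- Binding values are clipped below at a 1e-4 floor; missing binding
  entries become the neutral 1.
- Underdetermined regressions (usable genes ≤ factors + 1) error per time
  point and propagate as flagged all-missing columns, not as a global
  failure.
- Permutation p-values use the add-one estimator, so they are never
  exactly zero at finite $N$.
- TSV outputs are written at full double precision (17 significant
  digits) so write/read round-trips are exact.

## Problem sizes used in the test suite

Unit tests run on 36-point grids with 60–300 genes and up to 55 factors;
the end-to-end acceptance checks use the default 200 × 50 × 36 synthetic
study, 1000-permutation nulls, and 200-replicate uniformity checks. The
full suite completes in well under a minute on a single core.

## Known limitations

- The binding matrix is static; activities absorb all temporal variation.
- The linear time-translation model is first-order and time-invariant;
  with 13–14 factors and 35 transitions the data-to-parameter ratio is
  modest, and the model is a descriptive summary rather than a validated
  causal graph.
- The non-centered periodicity score rewards any exactly periodic signal
  including constants; it is used downstream of selection, where flat
  profiles have already been eliminated, and a centering flag exists.
- Sine-fit phases can disagree with peak phases for strongly non-sinusoidal
  (spike) profiles; both are reported.
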