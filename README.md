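# tfcycle

Infer time-dependent transcription factor activities over the yeast
metabolic cycle, score them for periodicity, place them on the cycle, and
extract a dynamical regulatory network.

## The problem

Nutrient-limited continuous yeast cultures oscillate with a ~300-minute
metabolic cycle — a sharp oxidative burst (Ox), a reductive/building phase
(R/B) in which cells divide, and a long reductive/charging phase (R/C) —
and most of the transcriptome oscillates with it. Factor activities cannot
be measured directly, but they can be reconstructed from two genome-wide
datasets: a gene × time-point expression matrix and a gene × factor
promoter-binding matrix. `tfcycle` is for computational biologists who
want that reconstruction, and the downstream periodicity, phase, and
network analysis, as a tested, scriptable R pipeline.

## The model

Expression is assumed multiplicative in the bound factors,

$$R_i = c \prod_j b_{ij}^{\alpha_j} \quad\Longrightarrow\quad
\log R_i = c + \sum_j \alpha_j \log b_{ij},$$

so each time point is a robust (bisquare IRLS) multiple regression of log
expression on log binding across genes, yielding per-factor activities
α_j(t) with standard errors. The pipeline then:

1. **selects** factors with ≥ 9 of 36 time points at p < 0.1, refitting
   survivors iteratively to a fixed point;
2. **scores periodicity** as the raw autocorrelation at the one-period lag
   (P = 12 samples) over the zero-lag value — maximum 2/3 for three
   observed cycles — with a seeded permutation null, retaining scores
   ≥ 0.44;
3. **fits a single sinusoid** A·sin(2πt/P + φ) + m per factor (1° phase
   grid) and computes cycle-averaged peak phases, mapped to
   Ox/R-B/R-C arcs; labels time points from the oxygen-trace slope;
4. **clusters** profiles on |α| (sign-flipped activator/repressor pairs
   coincide);
5. **fits the time-translation model** α(t+1) = T·α(t) by least squares
   (and row-wise NNLS for a non-negative variant), with normalized
   dissolved oxygen included as an extra factor, and
6. **extracts the network**: entries |T_kj| ≥ 0.5 become directed edges,
   keeping the stronger direction of any bidirectional pair.

A fully specified synthetic-data generator (`synthetic_spec()`,
`generate_dataset()`) emulates all inputs with ground truth, so every
stage is testable end to end without downloads.

## Worked example

```r
library(tfcycle)

ds  <- generate_dataset(synthetic_spec(rng_seed = 42))
ds
#> <synthetic_dataset> 200 genes x 36 time points; 50 factors (13 active, 37 decoys)

res <- run_pipeline(ds$expression, ds$binding, ds$oxygen$trace,
                    tfa_config(n_permutations = 200, rng_seed = 42))
res
#> <tfa_pipeline>
#>   candidates: 50 -> selected: 13 -> periodic: 13
#>   network edges: 78
```

The funnel mirrors the published analysis shape (203 → 20 → 13 on the
real data): of 50 candidate factors, iterative selection keeps the 13
with reproducible activity, and all 13 clear the periodicity threshold.
Their scores sit just under the 3-cycle maximum of 2/3:

```r
head(res$periodicity, 5)
#>   tf    score   lag p_value n_perm  seed
#> 1 SIN1  0.661    12 0.00498    200    42
#> 2 SIN2  0.667    12 0.00498    200    42
#> 3 SIN3  0.649    12 0.00498    200    42
#> 4 SIN4  0.657    12 0.00498    200    42
#> 5 SIN5  0.667    12 0.00498    200    42

head(res$sine_fits[, 1:5], 5)
#>   tf    phase_deg amplitude   offset    rss
#> 1 SIN1        200     0.494  0.0145  0.0379
#> 2 SIN2        214     0.545 -0.00775 0.0142
#> 3 SIN3        225     0.598  0.00531 0.0416
#> 4 SIN4        240     0.652  0.00753 0.0353
#> 5 SIN5        255     0.705  0.00482 0.0348
```

The recovered phases and amplitudes match the generator's truth (200°/0.50,
215°/0.55, 225°/0.60, 240°/0.65, 255°/0.70) to within the 1° grid and a
few percent. `tidy()`/`glance()` methods give tibble views of every fitted
object, and `autoplot()` / `plot_phase_polar()` / `plot_cycle_phases()`
draw the standard displays:

```r
glance(res$transition_unconstrained)
#>   n_factors constrained frobenius_rss mean_abs_residual mean_rmse
#> 1        14 FALSE                9.80            0.0153     0.183
autoplot(res$network)
```

A thin command-line wrapper is installed at
`inst/scripts/tfcycle` (`tfcycle synth`, `tfcycle run`).

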