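# lipidremodel

Inference of phospholipid acyl-chain remodeling networks and kinetics
from pulse-chase lipidomic time courses.

## What it is for

Membrane glycerophospholipids are continuously rewritten by the Lands
cycle: phospholipases remove the acyl chain at the sn1 or sn2 position of
the glycerol backbone and acyltransferases/transacylases install a new
one through a transient lyso-intermediate. Pulse-chase experiments —
loading cells briefly with an isotope-labeled precursor species and
following the labeled pool by mass spectrometry over ~24 h — expose these
kinetics, but extracting reaction networks and rate constants from such
time courses is non-trivial.

`lipidremodel` is for lipidomics and systems-biology researchers with
per-species pulse-chase time courses (species label, time, replicate,
intensity). It implements a two-step inference:

1. **Correlation-network inference** — prunes the combinatorially full
   single-position reaction network down to the reactions with visible
   flux, using per-time-point significance tests for declining sources
   and windowed inverse-correlation scores for source → target edges.
2. **Rate fitting by B-spline collocation** — represents each species
   trajectory as a cubic B-spline and minimizes

   `E_total = E_obs + lambda * E_ode`,

   the squared misfit to the observed replicate means plus the squared
   residual of the linear mass-action system `x' = M(theta) x` at
   collocation points, by alternating exact SVD-based linear
   least-squares solves for the rates `theta` and the spline coefficients.

Fitted conversion rates `k(i -> j)` are then decomposed under a
steady-state treatment of the lyso pool, where they take the rank-1 form
`k(i -> j) = d_i * a_j / sum(a)`: **row ratios give relative deacylation
rates `d_i`, column ratios give relative reacylation rates `a_j`** per
chain and sn position.

The package also ships a pulse-chase simulator with known ground truth
(`simulate_pulse_chase()`, including a rank-1 mode), label-permutation
and parameter-perturbation negative controls, a transcription of the
primary conversion rates from six independent BHK21 PE pulse-chase
experiments (`inst/extdata/pe_remodeling_rates_bhk21.tsv`), and a
command-line interface (`inst/cli/lipidremodel.R`) with subcommands
`simulate`, `infer-network`, `fit`, `decompose`, `permute`, `run`.

## Worked example

Relative rates from the packaged BHK21 conversion-rate table:

```r
library(lipidremodel)
tab <- read_rate_table(system.file("extdata", "pe_remodeling_rates_bhk21.tsv",
                                   package = "lipidremodel"))

pairwise_rate_ratio(tab, "sn1", "14:0", "18:1", "18:0", digits = 2)
#> [1] 5.36
```

The 14:0 sn1 chain converts to 18:1 5.36× faster than to 18:0 — a
reacylation preference, since both conversions start from the same
deacylation.

```r
suppressWarnings(relative_deacylation(tab, "sn1", ref = "14:0"))
#> <relative deacylation rates> sn1, reference 14:0
#>   chain    ratio n_pairs
#> 1  14:1 6.582071       2
#> 2  18:3 2.994839       3
#> 3  14:0 1.000000       3
#> 4  18:0 0.772216       2
#> 5  18:1 0.195160       2
```

Pooling row ratios over all shared columns ranks sn1 deacylation
14:1 > 18:3 > 14:0 > 18:0 > 18:1 (6.58 : 3 : 1 : 0.77 : 0.20):
unsaturated chains are cleaved from sn1 fastest, and 18:1 — the dominant
reacylated chain — is removed an order of magnitude more slowly than
14:0, which is why saturated/monounsaturated chains accumulate at sn1.

A full round trip on simulated data — simulate a 3-species conversion
cascade with 10% measurement noise, infer the network, fit the rates:

```r
path <- c("18:3-18:3", "18:1-18:3", "18:1-18:1")
ed <- data.frame(source = head(path, -1), target = tail(path, -1))
ed$position <- mapply(differs_at_one_position, ed$source, ed$target)
ed$score <- NA_real_; ed$window_start <- NA_integer_; ed$window_end <- NA_integer_
spec <- simulation_spec(remodeling_network(path, ed), c(0.25, 0.05),
                        x0 = c("18:3-18:3" = 100), noise_cv = 0.10, seed = 1)
sim <- simulate_pulse_chase(spec)

net <- bidirectionalize(infer_network(sim$tc))
net
#> <remodeling network> 3 species, 4 directed edges
#>      source    target position     score window_start window_end
#> 1 18:3-18:3 18:1-18:3      sn1 0.8193357            1          6
#> 2 18:1-18:3 18:1-18:1      sn2 1.0000000            5          6
#> 3 18:1-18:3 18:3-18:3      sn1 0.0000000            1          6
#> 4 18:1-18:1 18:1-18:3      sn2 0.0000000            5          6

fit_dynamics(sim$tc, build_ode(net))
#> <remodeling fit> 4 rates, 41 iterations (converged), E_total = 14.92
#> 18:3-18:3 -> 18:1-18:3 18:1-18:3 -> 18:1-18:1 18:1-18:3 -> 18:3-18:3
#>                 0.2629                 0.0515                 0.0009
#> 18:1-18:1 -> 18:1-18:3
#>                 0.0030
```

The true path is recovered exactly (the two score-0 edges are the added
reverse reactions), and the true rates (0.25, 0.05 h⁻¹) come back as
0.2629 and 0.0515 despite the noise, with near-zero reverse flux.

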