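# retinamosaic

Simulation and inference for fly retinal color mosaics — from the fully
random *Drosophila* eye to the striped eyes of long-legged flies
(Dolichopodidae, "Doli"), and everything in between.

## The problem

Fly ommatidia (unit eyes) come in two color classes. In *Drosophila* the
classes are scattered randomly with a 35:65 pale:yellow bias; in some
dolichopodid genera they form strictly alternating red/green columns; and
intermediate genera such as *Chrysosoma* show partially ordered mosaics.
Because the retina is specified column by column behind the
morphogenetic furrow, and because patterning errors in wild-caught
animals propagate anteriorly from the column where they arise, a single
local patterning rule with species-specific interaction strengths can
generate all three pattern classes. This package is for quantitative
biologists who want to simulate that rule, measure mosaics, and ask which
parameters most likely generated an observed pattern.

## The model

A retina is an `n x m` binary matrix `a_ij` (1 = green/yellow,
0 = red/pale), generated in furrow order. Three pieces:

1. **Threshold relay** (structured component). Column `j` has default
   green probability `p_j = P0` if `X_j <= X0`, else `1 - P0`; the relay
   `X_{j+1} = gamma - beta p_j` feeds the decision forward. For
   `beta = 8, gamma = 10, X0 = 5, P0 = 1e-4` the relay oscillates
   (`p = 0.9999 -> X = 2.0008 -> p = 1e-4 -> ...`): alternating stripes.
   Other parameter regions give uniform retinas (`classify_regime()`).
2. **Mistake propagation.** Minority elements of a realized column bias
   nearby sites of the next column toward the opposite color:
   `l_ij = eps * sum_{i'} exp(-(i-i')^2 / k) ((1 - a_{i',j-1}) - p_j)`,
   summed over the previous column's mistakes.
3. **Mixture.** The full site probability interpolates between the
   corrected structured component and a stochastic component:
   `P_ij = alpha * clip(p_j + l_ij) + (1 - alpha) * (1 - P0_droso)`.
   `alpha = 1` is pure Doli (or, for `beta < 0`, the uniform fly at
   green probability 0.99); `alpha = 0` is pure *Drosophila*.

Inference replaces `(beta, gamma)` by a discrete mode
`m ∈ {fr, fg, ar, ag}` (fixed point vs alternation × initial green
probability low vs high) and maximizes the exact column-factorized
likelihood over reference discrete grids by exhaustive search.

## Worked example

```r
library(retinamosaic)

# a slightly disordered Doli eye: 90% structured, strong error propagation
p <- retina_params(alpha = 0.9, epsilon = 0.5, P0_droso = 0.4)
sim <- simulate_retina(p, n_rows = 30, n_cols = 50, seed = 1)
pattern_stats(sim$pattern)
#> <correlation_stats>
#>   R_h: -0.6906   R_v: 0.5321   green fraction: 0.5133
#>   total mistakes: 246 (0 ambiguous columns)

# recover its parameters on the reference grid
infer_pattern(sim$pattern, parameter_grid("simulated"))
#> <inference_result>
#>   ML estimate: mode = ag, alpha = 0.89, epsilon = 0.4, P0 = 0, k = 1
#>   log-likelihood: -519.2633  (3636 grid points, 1 tied)
```

The horizontal correlation `R_h = -0.69` sits between the perfect-stripe
anchor (-1) and the random anchor (0): columns still alternate, but the
246 mistakes (cells disagreeing with their column majority) blur the
stripes. The grid search recovers the generating parameters to within one
or two grid steps — mode `ag` (alternating, starting green), mixing
weight 0.89 vs the true 0.9, speckle coefficient 0.4 vs the true 0.5.

Other entry points: `run_perturbation_experiment()` (error propagation
from a perturbed column), `phase_diagram()` (mean `R_h` over the mixture
plane), `recovery_experiment()` (systematic parameter recovery),
`spearman_permutation()` (rank correlations with permutation p-values),
`read_pattern()`/`write_pattern()`/`render_pattern()` (CSV and PNG I/O).
A thin command-line wrapper with `simulate | perturb | stats |
phase-diagram | infer | recover | render` subcommands is installed at
`inst/cli/retinamosaic.R`.

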