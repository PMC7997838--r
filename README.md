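# aromkin

Kinetic modeling of the anaerobic co-metabolism of plant-derived aromatic
mixtures in batch culture.

When bacteria such as *Rhodopseudomonas palustris* grow anaerobically on
lignocellulosic hydrolysates, they face a mixture of lignin-derived
aromatic monomers — p-hydroxyphenyl (H), guaiacyl (G) and syringyl (S)
types — many of which are degraded only by co-metabolism, with a few acids
accumulating extracellularly. `aromkin` is for researchers who want to pose
alternative degradation-pathway hypotheses for such mixtures as kinetic
network models, simulate them against batch time-series data, and rank
them by goodness of fit.

## The model

Each compound's concentration S (µmol l⁻¹) follows

    dS/dt = r_p X − r_s X

with biomass X(t) (mg l⁻¹) an exogenous Gompertz forcing,
X(t) = A·exp(−exp((µe/A)(λ − t) + 1)). Reactions are 1:1 molar
substrate→product steps with one of two specific rate laws:

* first order: r = k S (k in l mg⁻¹ h⁻¹)
* inhibited: r = k · k_i/(k_i + S_i) · S, covering competitive inhibition
  by a second substrate (S_i ≠ S) and substrate self-inhibition (S_i = S),
  with inhibition factor k_i in µmol l⁻¹

The ODEs are integrated by fixed-step explicit Euler (compiled core;
negative overshoot clipped to zero), and free parameters are estimated by
minimizing the total residual sum of squares (RSS) over all measurable
compounds jointly, using multi-start Nelder–Mead in log-parameter space.
Five shipped network hypotheses (`case_network(1:5)`) form a nested ladder
over the H+G pathways — substrate channeling past the aldehydes, competitive
inhibition of G steps by H analogs, self-inhibition — plus a syringyl chain
and two small side models. A synthetic-data generator with documented
ground truth emulates a ~192 h batch run (hydrolysate initial
concentrations, Gompertz growth, 5% proportional measurement noise) so
identifiability, parameter recovery and case discrimination are testable
end to end.

## Worked example

Generate a synthetic experiment under the hybrid-inhibition truth (Case
5), fit the biomass forcing from the OD series, and compare hypotheses:

```r
library(aromkin)

spec <- synthetic_spec(synthetic_truth_network(5), noise_cv = 0.05, seed = 42)
ds   <- generate_dataset(spec)

bm <- fit_biomass(ds$biomass_obs)
#> <biomass_model> Gompertz: A = 498.9 mg/l, mu = 7.892 mg/l/h, lag = 23.42 h (OD600 x 500)

cmp <- compare_cases(ds$observations, bm, cases = 2:5, seed = 42,
                     restarts = 3, dt = 0.25, cycles = 4)
tibble::as_tibble(cmp)[, c("case", "feruloyl amide", "vanillic acid", "total")]
#> # A tibble: 4 × 4
#>   case  `feruloyl amide` `vanillic acid`   total
#>   <chr>            <dbl>           <dbl>   <dbl>
#> 1 case2           28638.            233. 275219.
#> 2 case3           22638.            262. 267244.
#> 3 case4           23505.            207. 158091.
#> 4 case5           23586.            209. 157201.
```

The fitted Gompertz parameters land within ~2% of the generating truth
(A = 500, µ = 8, λ = 24). The RSS table (µmol² l⁻²; full table has one
column per measurable compound) recovers the expected ranking: the cases
without self-inhibition of the abundant H compounds (2, 3) fit far worse,
and the generating structure (Case 5) fits best. `parameter_table(cmp)`
lists the per-case estimates, with rate constants at the positivity floor
displayed as 0 (no degradation); `autoplot(attr(cmp, "fits")$case5)`
overlays observations on the fitted trajectories.

See the vignette (`vignettes/kinetic-modeling.Rmd`) for the model,
numerical choices, and what the synthetic generator does and does not
emulate.

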