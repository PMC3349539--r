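# fflscape

Function landscape, plasticity and evolvability of feed-forward loop
(FFL) motifs.

## The problem

The feed-forward loop — a signal protein X regulating a target gene Z
both directly and via an intermediate Y — comes in eight sign topologies
(coherent C1–C4, incoherent I1–I4), and their frequencies in real
transcription networks are strongly biased towards C1 and I1. A single
topology does not determine a single function: depending on its kinetic
parameters, the same wiring can behave as a *grader* (monotone shift of
Z to a new level) or a *pulser* (transient overshoot/undershoot), in six
qualitative classes overall. `fflscape` is for systems biologists who
want to work with this structure-to-function *distribution* view: it
simulates the two-equation gene-circuit model

    dY/dt = γ_Y (1 + α^x ω_yx X^n) / (1 + ω_yx X^n) − δ_y Y
    dZ/dt = γ_Z (1 + β^x ω_zx X^n + β^y ω_zy Y^m + β^xy ω_zxy X^n Y^m) /
                (1 + ω_zx X^n + ω_zy Y^m + ω_zxy X^n Y^m) − δ_z Z

classifies responses into the six classes, estimates the per-motif
function-probability table P(class | motif) by Monte-Carlo parameter
sampling, and derives the statistics that connect distribution shape to
abundance:

* **kurtosis** K of the six class probabilities (bias-corrected sample
  estimator; one-hot rows give 6, the uniform limit is −10/3),
* **plasticity** ψ = |K| − K₀ with K₀ = 4/3 the midpoint of the two
  extremes (low ψ = balanced specialization/flexibility),
* **predicted abundance** ρᵢ = ψᵢ⁻¹ / Σⱼ ψⱼ⁻¹,
* **Shannon entropy** in bits as the complementary shape measure,
* **robustness** (diagonal mass of a mutation class-transition matrix)
  and **evolvability** E = 1 − R_accumulated / R_single from an
  in-silico single-parameter mutation protocol.

The published probability table and the single-/accumulated-mutation
transition matrices ship as plain-text fixtures
(`inst/extdata/`), so the whole chain — probabilities → K → ψ → ρ, and
transition matrices → robustness → E → correlation of E with ψ — is
reproducible offline.

## Worked example

```r
library(fflscape)

scores <- score_table(ffl_reference_table2())
head(scores, 3)
#>   motif kurtosis entropy_bits       psi        rho
#> 1    C1 1.630533     1.874767 0.2971996 0.34245321
#> 2    C2 4.141801     1.890748 2.8084673 0.03623932
#> 3    C3 3.042781     1.803093 1.7094473 0.05953793

single <- suppressWarnings(ffl_reference_transitions("single"))
acc    <- ffl_reference_transitions("accumulated")
E <- mapply(evolvability, single, acc)
round(E, 3)
#>    C1    C2    C3    C4    I1    I2    I3    I4
#> 0.315 0.050 0.255 0.073 0.413 0.275 0.280 0.240

compare_report(scores, E)
#> FFL correlation report
#>   Pearson r (evolvability vs psi): -0.917
#>   most evolvable motifs: I1, C1
#>   correlations with abundance sources:
#>                  source r_rho  r_psi r_evolvability
#>  ecoli_approx_synthetic 0.946 -0.657          0.606
#>  yeast_approx_synthetic 0.950 -0.690          0.619
```

Read: C1's class distribution has intermediate peakedness (K ≈ 1.63),
hence the smallest plasticity distance ψ and the largest predicted
abundance ρ ≈ 0.34; I1 is second (ρ ≈ 0.26). The two motifs that
dominate real transcription networks are also the two most evolvable
(E = 0.41 and 0.32), and evolvability anticorrelates with ψ at
r ≈ −0.92. The abundance fixture used above is an approximate synthetic
stand-in shipped for ranking checks only; supply your own
`motif,abundance,source` CSV for quantitative comparisons.

Simulation side, the same objects come out of the model rather than the
fixtures:

```r
p <- sample_parameters("C1", 1, seed = 1)[[1]]   # random C1 circuit
classify_trajectory(ffl_integrate(p))            # "P+T-"
estimate_landscape(200, seed = 1)                # Monte-Carlo P(class|motif)
transition_matrices("C1", mutation_config(60, 25, seed = 1))
```

The numbered scripts in `analysis/` run the full workflow — landscape
estimation, plasticity scoring, robustness/evolvability, correlation
report — and write their tables to `results/`:

```sh
Rscript analysis/01_landscape.R
Rscript analysis/02_plasticity.R
Rscript analysis/03_evolvability.R
Rscript analysis/04_compare.R
```

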