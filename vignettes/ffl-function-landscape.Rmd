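---
title: "The FFL motif-function landscape: model, statistics and mutation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FFL motif-function landscape: model, statistics and mutation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflscape)
```

## The question

Feed-forward loops (FFLs) — three-gene motifs in which a signal protein X
regulates a target Z both directly and through an intermediate Y — occur in
transcription networks with a strongly biased frequency pattern: two of the
eight sign topologies (C1 and I1) dominate. `fflscape` implements an
analysis of why: instead of assigning each topology a single function, it
treats the topology as inducing a *probability distribution* over
qualitative dynamical responses, scores the shape of that distribution
(plasticity), and connects the score to mutational robustness and
evolvability. The package provides the dynamical model, the response
classifier, the Monte-Carlo landscape estimator, the distribution-shape
statistics, the mutation protocol, and the published reference tables as
plain-text fixtures.

## The dynamical model

Each circuit is described by two rate equations for the intermediate Y and
output Z. Production is basal transcription modulated by thermodynamic
promoter occupancy:

$$\dot Y = \gamma_Y\,
  \frac{1 + \alpha^x \omega_{yx} X^n}{1 + \omega_{yx} X^n} - \delta_y Y,
\qquad
\dot Z = \gamma_Z\,
  \frac{1 + \beta^x \omega_{zx} X^n + \beta^y \omega_{zy} Y^m
        + \beta^{xy} \omega_{zxy} X^n Y^m}
       {1 + \omega_{zx} X^n + \omega_{zy} Y^m + \omega_{zxy} X^n Y^m}
  - \delta_z Z.$$

The $\gamma_i$ are basal production rates (concentration/time), the
$\omega_{ij}$ binding-equilibrium constants, the $\delta_i$ first-order
degradation rates (1/time), and $n, m$ multimerization degrees of the
regulators. The regulation factors $\alpha^x$ (X on gene Y) and
$\beta^x, \beta^y, \beta^{xy}$ (X, Y and joint binding on gene Z) are
fold-changes relative to basal expression: $>1$ is activation, $<1$
inhibition. The eight topologies are exactly the eight assignments of
activation/inhibition to the three edges; a parameter set realizes a
topology when each factor lies on the matching side of 1.

**Input model.** X is an external step, not a dynamical variable: zero
before $t = 0$ and constant at `x_active` afterwards. The model contains
no equation for X, and treating it as a controlled input keeps the
pre-/post-input steady states well defined.

**Steady states.** The circuit is strictly feed-forward — Y depends only
on X, and Z on X and Y — so for any constant input the fixed point is
unique and available in closed form (Y\* from the occupancy expression
over $\delta_y$, then Z\* with $Y = Y^*$). `ffl_steady_state()` evaluates
this closed form and checks the residual; `ffl_integrate()` independently
verifies that forward integration relaxes onto it. No multistability is
possible in this model, which also means the response to a given input is
a deterministic function of the parameter set.

**Joint regulation.** The model leaves the sampling rule for
$\beta^{xy}$ open. We constrain it to the product of the X→Z and Y→Z
edge signs (joint binding is coherent with the individual bindings), so
no fourth independent edge sign is introduced. This is a package
convention, made explicit so it can be varied.

## Response classes and classification

After input onset, Z(t) is classified into six qualitative classes:
graders `G+`/`G-` (monotone approach to the new level) and pulsers
`P+T+`, `P+T-`, `P-T-`, `P-T+` (overshoot/undershoot, annotated by the
sign of the initial slope and of the final level relative to the
pre-input level). All decisions use a relative dead band `rel_tol * z0`
(default `rel_tol = 0.01`):

* *no-response* — the final level and the whole trajectory stay inside
  the band;
* *monotone* — the excursion beyond the envelope
  $[\min(z_0, z_\infty), \max(z_0, z_\infty)]$ is at most
  `rel_tol * |z_inf - z0|` (this tolerance absorbs solver ripple without
  misreading it as a pulse);
* *perfect adaptation* — a pulser whose final level falls back inside the
  band takes its target sign from the strict side of $z_0$ on which
  $z_\infty$ lies; an exact tie is reported as `"ambiguous"`.

`no-response` and `ambiguous` outcomes are *excluded* from probability
counts and logged, never binned into a seventh class: the reference
probability table normalizes over the six classes only, and we follow
that convention. Classification reads trajectories on a dense grid
(default 2001 points over 20 relaxation times) so extremum detection is
grid-limited well below the dead band.

## The landscape estimator and its priors

`estimate_landscape()` draws sign-consistent parameter sets per motif,
simulates, classifies, and normalizes class counts over classified
samples, giving a row-stochastic table of P(class | motif). The original
quantification behind the packaged reference table used a symbolic
nullcline-geometry formalism with unpublished parameter ranges, so exact
numerical reproduction from sampling is not attainable; the estimator is
a reproduction apparatus with qualitative expectations (e.g. C1's modal
class is `G+`), and the packaged table is the authoritative input for all
downstream statistics.

Default prior (all log-uniform): rates and binding constants on
$[0.01, 100]$, fold-changes on $[1, 50]$ or its reciprocal interval,
input strength on $[0.1, 10]$, multimerization degrees uniform on
$\{1,\dots,4\}$. Wide log-uniform ranges are the standard uninformative
choice for positive kinetic constants spanning several decades; the
bounds are configurable through `ffl_prior()`. One master seed derives a
deterministic child seed per motif, so any subset of motifs reproduces
the same rows.

## Distribution-shape statistics

For each motif's 6-vector of class probabilities:

* **Sample kurtosis** (`sample_kurtosis()`): the bias-corrected estimator
  with $n = 6$ and the sample standard deviation. Its extremes anchor the
  scale: a one-hot distribution gives exactly 6; the uniform distribution
  is a removable 0/0 singularity whose symmetric-perturbation limit is
  $-2(n-1)/(n-3) = -10/3$. (The reduced closed forms sometimes quoted for
  these extremes are inconsistent as printed; the package derives both
  from the estimator itself.) `sample_kurtosis()` returns the limit value
  when the standard deviation falls below $10^{-12}$. The flexible
  extreme is stored exactly as $-10/3$, not as the rounded $-3.33$.
* **Shannon entropy** (`shannon_entropy()`), in bits, with
  $0 \log 0 = 0$: ranges from 0 (one-hot) to $\log_2 6$ (uniform) and
  orders the extremes oppositely to kurtosis.
* **Plasticity** $\psi = |K| - K_0$ (`psi_score()`), with $K_0 = 4/3$ the
  midpoint of $(-10/3, 6)$: small $\psi$ means the motif balances
  specialization and flexibility. The score is not clamped; it would be
  negative for $|K| < K_0$.
* **Predicted abundance** $\rho_i = \psi_i^{-1} / \sum_j \psi_j^{-1}$
  (`rho_score()`): normalized inverse plasticity, defined only for
  positive $\psi$, scale-free in $\psi$.

`score_table()` applied to the packaged probability table reproduces the
packaged reference scores (kurtosis, $\psi$, $\rho$ for all eight motifs)
within $\pm 0.005$ — the print precision of the source, and the tolerance
used by the acceptance tests. The worst deviation ($\psi$ of I4,
$\approx 0.003$) reflects rounding in the published values, not a
different formula.

## Mutation protocol, robustness and evolvability

`mutate_params()` changes exactly one of the 14 circuit parameters
(`x_active`, being the external input, is not mutable). Continuous
parameters are multiplied by $e^\varepsilon$,
$\varepsilon \sim U[-\ln 10, \ln 10]$, so mutations can be numerically
small or large; regulation factors are resampled until they stay
strictly on their side of 1, preserving the topology; $n, m$ step by
one within $\{1,\dots,4\}$, and only when the kernel width is positive
(so a zero-width kernel freezes the whole genotype).

`transition_matrices()` runs two regimes over a cohort of classified
circuits: *single* (mutate the original, classify, bin the class pair,
revert — independent single-mutation trials) and *accumulated*
(mutations persist; unclassifiable mutants are rejected and logged).
Counts are normalized by total binned events, so each 6×6 matrix of
joint frequencies sums to 1 and its diagonal mass is the robustness.
Iteration stops when every cumulative bin frequency changes by less than
$10^{-3}$ over a 500-round window, or at the round cap. Defaults (1000
circuits per motif, up to 10,000 rounds) match the study conditions;
tests and the analysis scripts use reduced cohorts (tens of circuits,
tens of rounds), which is sufficient for the structural properties they
assert.

Evolvability is $E = 1 - R_{\text{acc}} / R_{\text{single}}$
(`evolvability()`). From the packaged reference matrices, E ranges from
0.05 (C2) to 0.41 (I1), the two most abundant motifs C1 and I1 carry the
two largest values, and E correlates with plasticity at
$r \approx -0.92$.

**A caveat we consider a finding.** The reference matrices were derived
by mutating entries of a symbolic qualitative-condition representation,
not raw parameters. Our parameter-level protocol cannot distinguish
mutations invisible to that representation from visible-but-neutral
ones, so simulated matrices are not numerically comparable to the
packaged ones — and indeed, under parameter-level mutation the
accumulated regime tends to drift circuits into *more* class-stable
parameter regions, so simulated E for C1 sits near or slightly below
zero at desk scale. The packaged tables therefore remain the
quantitative source for E throughout, and simulated matrices are used
only for structural properties (seed determinism, normalization,
diagonal dominance, kernel→0 ⇒ E→0).

## Abundance comparisons

The natural FFL abundances used in the original comparison are not
printed anywhere we can transcribe them from; the packaged
`abundance_approx_synthetic.csv` is explicitly synthetic (figure-derived
by eye) and is used only for ranking checks (C1 and I1 dominate).
Quantitative correlation claims are instead validated constructively:
`abundance_with_correlation()` builds nonnegative, normalized abundance
vectors whose in-sample Pearson correlation with a score vector is
*exact* (residualized noise mixing followed by affine rescaling), and
the compare stage must recover the target. Users with real abundance
data can supply a `motif,abundance,source` CSV to `compare_report()`.

## What the synthetic generators do and do not emulate

`toy_trajectory()` produces piecewise-smooth curves whose class is known
by construction — it exercises every branch of the classifier but not
solver noise or stiffness; `ffl_integrate()` outputs cover those.
`random_probability_table()` spans the flexible-to-specialized range of
row shapes via a symmetric Dirichlet but has no motif structure. Neither
generator emulates real expression noise, embedding of motifs in larger
networks, or X-dynamics — all outside the model.

## Numerical choices

* Steady-state residual tolerance $10^{-9}$ (relative); solver
  tolerances rtol $10^{-8}$ / atol $10^{-10}$ (`lsoda`, compiled
  right-hand side).
* Horizon 20 × the slowest relaxation time
  $\max(1/\delta_y, 1/\delta_z)$: residual class-relevant transients are
  $O(e^{-20})$, far below the 1% dead band.
* Classification grid ≥ 2000 points; `rel_tol = 0.01`.
* Problem sizes in the test suite: landscape convergence is checked at
  250/500/1000 samples per motif (total-variation distance must shrink
  as n doubles), classifier–oracle agreement at 10,000 synthetic
  trajectories, mutation-protocol properties at cohorts of 8–60
  circuits.
* Integer seeds everywhere; per-motif child seeds are derived from the
  master seed by a fixed affine map mod $2^{31} - 1$.

## Known limitations

* The Monte-Carlo landscape depends on the prior; only qualitative
  features of the reference table are reproducible from sampling.
* Simulated transition matrices use a different mutation substrate than
  the packaged ones (see above).
* The C3 single-mutation reference block totals 1.106 rather than ≈1 as
  transcribed from its source; it is kept verbatim and the loader warns.
  Robustness and evolvability read only the diagonal entries as printed,
  so they are insensitive to however the normalization slipped.
* Single, isolated motifs only: no embedding in larger networks, no
  stochastic gene expression.

## Worked example

```{r example, eval = FALSE}
scores <- score_table(ffl_reference_table2())
single <- suppressWarnings(ffl_reference_transitions("single"))
acc <- ffl_reference_transitions("accumulated")
E <- mapply(evolvability, single, acc)
compare_report(scores, E)
```

The numbered scripts under `analysis/` run the four stages (landscape
estimation, plasticity scoring, robustness/evolvability, correlation
report) and write their tables under `results/`.
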