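---
title: "Model-based synergy analysis of drug-combination checkerboards"
author: "CombiSurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based synergy analysis of drug-combination checkerboards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CombiSurf)
```

## The problem

A checkerboard combination assay exposes cells to all pairwise
concentrations of two drugs and reads out viability as a percentage of the
untreated control: 100 means no effect, 0 complete kill. The scientific
question is whether the combination does more (synergy) or less
(antagonism) than two *non-interacting* drugs would — and "non-interacting"
is not one thing. CombiSurf implements the classical surface approach: the
two single-agent dose–response curves are extracted from the zero-dose row
and column of the matrix, fitted with a Hill model, and used to construct a
reference response surface under a chosen non-interaction model. The
difference between that reference and the observed surface is the synergy
distribution over concentration space; scalar metrics summarize it for
ranking across a screen.

Because the reference is model-generated, every result is conditional on
the chosen model, and the package always carries the model id through
surfaces, distributions, metrics and file outputs.

## The dose–response model

Single agents follow a three-parameter Hill curve

$$E(c) \;=\; E_0 + \frac{E_{\inf} - E_0}{1 + (EC_{50}/c)^h},
  \qquad E_0 = 100,$$

with `eInf` the response at infinite dose (% control), `ec50` the
half-effect concentration (same units as the dose grid — units are the
user's, only consistency matters), and `h` the unitless Hill slope. The
baseline is pinned at 100 rather than fitted: the data are already
normalized to the untreated control, so the control *defines* the baseline,
and freeing it would let fit error leak into every reference surface.

`fitHill()` minimizes unweighted squared error over all replicate points
(not replicate means), with box constraints
$E_{\inf} \in [-20, 100]$, $EC_{50} \in$ [min positive dose/100, max
dose × 100], $h \in [0.1, 10]$. The optimization is parameterized in
$(E_{\inf}, \log EC_{50}, h)$ and run from a deterministic multi-start grid
— five $EC_{50}$ starts log-spaced over the tested dose range crossed with
slope starts $\{0.5, 1, 3\}$ — followed by a Levenberg–Marquardt polish of
the best start. There is no random number used anywhere in fitting, so a
fit is a pure function of the data; on noise-free model-generated data the
polish converges to the generating parameters at close to machine
precision, which is what lets the pipeline's null calibration be asserted
at the 1e-5 level rather than at "fit noise" level.

An agent is flagged **inactive** when the fitted curve is essentially flat
(|100 − eInf| < 5 % points) or explains almost no variance (R² < 0.3).
Inverse dose–response is undefined for a flat curve, and real screens
contain inactive compounds, so downstream models must not silently
extrapolate them.

## Reference surfaces

All three models agree with the fitted single-agent curves on the two axes
by construction; they differ only in the interior.

**Bliss independence** treats the two surviving fractions as independent
probabilities: $E_{AB} = E_A E_B / 100$. This is only meaningful for
fractions in [0, 1], so curve predictions outside [0, 100] (possible when
`eInf < 0`, i.e. readouts dipping below zero) are clamped before the
product and the cell flagged `clamped`.

**HSA** (highest single agent) takes the stronger single-agent effect,
$\min(E_A(a), E_B(b))$ on the % control scale.

**Loewe additivity** is dose equivalence: the reference effect $E^*$ at
dose pair $(a, b)$ solves

$$\frac{a}{A(E^*)} + \frac{b}{B(E^*)} = 1,$$

where $A(E)$, $B(E)$ are the inverse Hill curves. The left-hand side (the
combination index) is strictly increasing in $E$ on
$(\max(E_{\inf,A}, E_{\inf,B}),\, 100)$, so each interior cell is solved by
bisection on the effect, iterated until the bracket is narrower than
1e-10 % points (the combination-index residual alone is a poor stopping
rule where the index is flat in $E$, so the bracket is always narrowed).
The solver is vectorized across all interior cells, so an 8×8 grid solves
in milliseconds. Its correctness is cross-checked in the test suite against
an independent brute-force scan of the effect axis (`loeweGridScan()`,
staged uniform grid with final step 1e-6).

Two partial-definition cases are handled explicitly rather than by
extrapolating a Hill curve beyond its asymptote:

* **Unreachable effects.** When a cell demands an effect deeper than the
  weaker agent's asymptote, the index equation has no root in the bracket;
  in that limit the weaker agent's term vanishes and the equation
  degenerates to the stronger agent acting alone. The cell is therefore
  capped at $\min(\max(E_{\inf,A}, E_{\inf,B}),\, E_A(a),\, E_B(b))$ (plus
  the solver tolerance as a margin) and flagged `capped`. Capping at the
  bare boundary asymptote alone would place these cells *above* the axis
  values wherever the stronger agent alone reaches deeper — breaking the
  monotonicity of the surface and the property that a Loewe reference never
  predicts less effect than the better single agent.
* **Inactive agents.** If either agent is inactive the reference falls back
  to the active agent's own curve, flagged `fallback_single_agent` (a drug
  combined with nothing should predict the drug alone). Both inactive:
  flat 100.

Flags are kept per cell and written with the surfaces so users can see
where the Loewe model is only partially defined for their compounds.

## The synergy distribution and its metrics

The synergy distribution is `reference − mean(observed)` per cell, in %
points: observed response *below* the reference (more kill than predicted)
scores positive. The literature is split on this sign, so
`synergyDistribution(..., direction =)` can flip it; the default is stated
on every plot scale. Since the definition is linear, computing on the
replicate mean equals averaging per-replicate differences — one reason this
simple difference was chosen. With ≥ 2 replicates the per-cell replicate SD
is carried along; with ≥ 3, `synergySignificance()` offers a
Bonferroni-corrected one-sample t-test per interior cell as an explicitly
labeled extension, off by default.

Cells on the zero-dose axes measure single-agent *fit residual*, not
interaction, and are excluded from metrics. Over the interior cells,
`computeMetrics()` reports: the extreme values (`max_synergy`,
`max_antagonism`); the means of the positive and negative parts and their
sum (`integrated_total`); an effect-weighted mean with weights
$w = (100 - \bar E)/100$ clamped to [0, 1], which emphasizes synergy where
the combination actually does something (a 10-point synergy at doses that
barely affect the cells is rarely actionable); and the dose pair of peak
synergy density. Integrated metrics are means rather than sums so that
screens mixing 6×6 and 8×8 grids remain comparable. The peak is the argmax
after 3×3 uniform smoothing (kernel truncated at borders) so a lone noisy
cell cannot define it, with ties resolved to the lexicographically lowest
(dose A, dose B) pair — deterministic, and conservative in preferring lower
concentrations. If no cell shows any observed effect, the weighted mean
falls back to the unweighted one rather than dividing by zero.

## Synthetic data: what it emulates and what it does not

`simulateExperiment()` generates replicate matrices as
`reference(model, true curves) − synergyField + N(0, noiseSD²)` per cell —
every cell, the untreated control included. The defaults are the study
conditions used throughout the tests: 8 doses per drug (zero plus 7
log-spaced concentrations over three decades), 3 replicates, 3 % points of
Gaussian noise, and screen-level ground-truth curves with
$E_{\inf} \sim U(0, 40)$, $EC_{50}$ log-uniform over the positive dose
range and $h \sim U(0.5, 4)$ — a realistically active oncology screen.
`simulateScreen()` writes such experiments through the package's own CSV
writer so the parser is exercised by every batch test.

The generator is deliberately idealized: noise is homoscedastic Gaussian on
the % scale, wells are independent, and the truth really is a Hill surface
plus an additive interaction field. Real plates add edge effects, drift,
heteroscedastic and occasionally heavy-tailed noise, and single-agent
behavior that is not Hill-shaped (biphasic curves). Passing the suite
therefore demonstrates that the *mathematics* of the pipeline is correct
and calibrated — zero planted synergy in, zero scored synergy out, at
1e-5 — not that any particular real assay meets the model's assumptions.

## Problem sizes and numerical choices at a glance

| Choice | Value | Why |
|---|---|---|
| Hill baseline $E_0$ | fixed 100 | control defines the baseline |
| Fit bounds | $E_{\inf} \in [-20,100]$, $h \in [0.1,10]$ | stimulation/noise margin; implausible slopes excluded |
| Loewe bracket stop | effect interval < 1e-10 | residual is flat in shallow regions |
| Loewe cap | min(boundary, single agents) + tol | keeps surface monotone, never above HSA |
| Peak smoothing | 3×3 truncated mean | robustness to single noisy cells |
| Peak ties | lowest (dose A, dose B) | deterministic, prefers low doses |
| Metrics | interior cells only | axes are fit residual |
| Test/validation sizes | 8×8 grids; 20–100 random curves/pairs; 20-experiment screens | spans the design space while keeping the suite fast |

## A worked example

```{r example, eval = FALSE}
ce <- simulateExperiment(
  HillCurve(eInf = 5, ec50 = 0.8, h = 1.3),
  HillCurve(eInf = 25, ec50 = 2.5, h = 2.1),
  model = "BLISS", noiseSD = 3, nReplicates = 3, seed = 42
)
res <- analyzeExperiment(ce, models = c("LOEWE", "BLISS", "HSA"))
res$metrics[, c("model", "max_synergy", "integrated_total", "peak_dose_a")]
renderPlots(ce, res$curves, res$references, res$distributions,
  outDir = "figures"
)
```

## Known limitations

* Bliss is computed on clamped fractions when a fitted curve leaves
  [0, 100]; strong growth stimulation is outside the model's sound domain.
* The Loewe reference is undefined (and capped, with flags) wherever the
  demanded effect is beyond an asymptote; combinations of very unequal
  maximal-effect drugs will show capped regions that should be read as
  "Loewe not defined here", not as evidence of interaction.
* Metrics definitions (means, weighting, smoothing) are this package's
  documented choices; other tools implementing the same named metric
  families may scale them differently, so compare rankings, not raw
  numbers, across tools.
* Plate-layout deconvolution, LIMS connectivity and mechanistic PK/PD
  simulation are out of scope.
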