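---
title: "Kinetic modelling of DUSP-regulated HER2/MAPK signalling under Herceptin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of DUSP-regulated HER2/MAPK signalling under Herceptin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duspkin)
```

## The model

HER2-positive breast cancer is driven by the receptor tyrosine kinase
HER2, whose downstream MAP kinases — ERK1/2, JNK1/2 and p38 — control
proliferation. Herceptin (trastuzumab) down-regulates HER2, but
resistance frequently develops; dual-specificity phosphatases (DUSPs),
which dephosphorylate MAP kinases on both threonine and tyrosine, sit at
the centre of this circuitry, and DUSP8/16 are overexpressed in
resistant cells. `duspkin` implements a small mass-action kinetic model
of this pathway to ask a focused question: does inhibiting the DUSP
re-sensitise resistant cells to the drug?

Each of the five proteins (HER2, ERK1/2, JNK1/2, p38, DUSP8/16 — the
latter a single joint node, `DUSP`) is represented by an active/inactive
pair under first-order mass action, so each pair conserves its total
exactly. Herceptin is a constant input $H$ (not a state variable)
driving HER2 inactivation. Writing $X_a$/$X_i$ for active/inactive
pools:

$$
\begin{aligned}
\dot{HER2}_a &= k_1\,HER2_i - d_1\,HER2_a\,H \\
\dot{ERK12}_a &= k_2\,ERK12_i\,HER2_a - d_2\,ERK12_a \\
\dot{JNK12}_a &= k_3\,JNK12_i\,HER2_a - d_3\,JNK12_a\,DUSP_a \\
\dot{P38}_a &= k_4\,P38_i\,HER2_a - d_4\,P38_a\,DUSP_a \\
\dot{DUSP}_a &= k_5\,DUSP_i\,\iota - d_5\,DUSP_a \\
\dot{S} &= s_1\,ERK12_a - s_2\,(JNK12_a \cdot P38_a)^{0.6}
\end{aligned}
$$

with each inactive pool obeying the negated equation. $S$ is an abstract
survival score standing in for cell count: ERK promotes it, the
cooperative JNK1/2–p38 combination opposes it through a Hill-type term
with exponent 0.6. The inducer factor $\iota$ encodes the three
topologies: $\iota = 1$ (constitutive DUSP activation, the baseline
DUSP16 model), $\iota = ERK12_a$, or $\iota = JNK12_a$ (the two
candidate induction mechanisms for DUSP8). The induced variants are the
simplest mass-action reading of "inducible by": the activation flux is
multiplied by the inducer's active amount, in both equations of the
DUSP pair, so conservation is untouched.

$d_5$, the DUSP inactivation rate, is the inhibition knob: raising it
emulates pharmacological inhibition or shRNA silencing of the
phosphatase.

## Parameters and their defaults

| parameter | meaning | default |
|---|---|---|
| `k1`–`k5` | activation rate constants (per time, per amount where a second species enters) | 1 |
| `d1`–`d5` | inactivation rate constants | 1 |
| `s1`, `s2` | survival gain/loss weights | 1 |
| `hill` | exponent on the JNK12·p38 product (dimensionless) | 0.6 |
| `herceptin` | constant drug level (amount units) | 100 |
| `totals` | conserved per-protein amounts | 100 each |

Only the Hill exponent (0.6), the Herceptin level (100) and the initial
amounts are fixed by the study design; the remaining rate constants are
a reference reconstruction. Setting every unprinted constant to 1 is the
least-informative choice that reproduces the full qualitative pattern,
verified here by the closed-form survival-slope oracle: on the scan grid
$d_5 \in \{1,10,20,50,100,500\}$ the baseline topology has positive
asymptotic slope through $d_5 = 20$ and negative slope from $d_5 = 50$,
while both induced topologies keep a positive slope everywhere on the
grid.

"Initial amounts" are read as *active*-form amounts (HER2, ERK1/2, DUSP
= 100; JNK1/2, p38 = 0), and each inactive pool completes its protein to
the configured total of 100. This gives JNK1/2 and p38 a working
inactive reservoir to activate from, and makes conservation uniform
across proteins. The survival score starts at 0 and is interpreted only
through its shape; it is not clamped below (the governing equation has
no floor), so sustained JNK/p38 activity drives it negative.

The mapping between the experimental 50 µM Herceptin dose and the
model's level of 100 is not mechanistic; the drug enters only as a
constant multiplicative pressure on HER2.

## Steady states and the survival-slope oracle

Because HER2's pair is autonomous, and ERK depends only on HER2, the
protein fixed point is available in closed form
(`steady_state()`). The DUSP level is linear in the constitutive
($D^* = k_5 T_D/(k_5+d_5)$) and ERK12-induced topologies, and the
positive root of a quadratic when JNK1/2 induces DUSP (the inducer is
itself dephosphorylated by DUSP, coupling the two pairs). The *eventual
survival slope* $s_1 E^* - s_2 (J^* P^*)^{0.6}$ predicts the sign of
the trajectory tail and serves as an independent cross-check on every
simulated regime label: the two routes (algebra vs. integration) are
compared in the test suite at every grid point.

```{r steady}
steady_state(dusp_model("constitutive", dusp_params(d5 = 50)))
```

## Simulation and regime classification

`simulate_trajectory()` integrates with the stiff-capable `lsoda`
switching solver (the $H \cdot HER2_a$ term creates rates of order
$10^4$, so the first transient is stiff). Defaults: horizon $t \in
[0, 10]$ model-time units with 1001 output points — the slowest
relaxation modes have time constants $\lesssim 1$, so the asymptotic
slope dominates well before $t = 10$ — and tolerances rtol $10^{-8}$ /
atol $10^{-10}$, at which the integrated DUSP trajectory matches its
exponential closed form to better than $10^{-6}$ relative and
per-protein conservation holds to the same tolerance. All metrics are
computed on the discrete output grid with no interpolation:
reproducibility is preferred over spurious precision.

Survival trajectories are classified from grid metrics alone
(`classify_regime()`), a shape-only rule invariant to affine rescaling:

* **increasing** — the maximum is effectively terminal
  ($s_{max} - s_{end} \le \varepsilon \cdot \mathrm{range}$; flat counts
  as increasing);
* **inflected** — the trajectory falls at the end but first rose
  substantially ($s_{max} - s_0 > \delta \cdot \mathrm{range}$);
* **decreasing** — it falls after at most a brief transient.

The thresholds $\varepsilon = 0.01$ and $\delta = 0.05$ reconstruct a
distinction the source figures make only visually: at $d_5 = 50$ the
survival curve climbs for a substantial fraction of its range before
turning over (inflected), while at $d_5 \ge 100$ the rise is a brief
transient (decreasing). `decrease_threshold()` reports the smallest
scanned $d_5$ whose trajectory *eventually decreases*
($s_{max} - s_{end} > \varepsilon \cdot \mathrm{range}$) — the model's
operational definition of inhibition reversing proliferation.

```{r scan, eval = FALSE}
scan <- inhibition_scan(dusp_model("constitutive"))
summary(scan)
decrease_threshold(scan)
```

## What the synthetic data emulate — and what they do not

The study's wet-lab readouts have no deposited data, so the package
generates seeded synthetic stand-ins with the same structure:

* **Noisy trajectories** (`noisy_trajectories()`): replicate
  observations of chosen state variables with multiplicative lognormal
  noise. Lognormal (rather than additive Gaussian) noise keeps positive
  amounts positive and scales errors with magnitude, the usual behaviour
  of abundance measurements.
* **72-h cell counts** (`synth_cell_counts()`): relative cell numbers
  for sensitive/resistant × {NT, shDUSP8, shDUSP16} × ±Herceptin with
  two replicates per condition, mirroring the assay's two independent
  experiments. The default effect map encodes the study's qualitative
  findings — under Herceptin the resistant NT line keeps growing (1.6),
  DUSP8 silencing does not reverse resistance (2.0), DUSP16 silencing
  does (0.9) — with 5% replicate noise. The source reports no replicate
  variances or bar heights, so these magnitudes are free design choices
  fixed once here.
* **qPCR Ct tables** (`synth_qpcr()`): one target DUSP plus two
  housekeeping genes (β-actin, GAPDH), constructed so the noiseless
  ΔΔCt fold change of a silenced sample equals `1 - knockdown` (default
  knockdown 0.75, satisfying the >70% selection rule), with Gaussian Ct
  noise in cycles.

All generators are pure functions of their inputs and seed (the global
RNG state is saved and restored). Passing tests on these data shows the
pipeline's statistics and the model's directional predictions are
internally consistent; it does *not* validate the model against real
measurements — the synthetic tables contain no plate effects, primer
efficiencies, growth kinetics, or condition-dependent variance.

## Calibration

`fit_parameters()` minimises unweighted least squares between simulated
and observed species, replicates pooled — no variance model is available
from the source, so no weighting is imposed. Free parameters are
optimised in log space, which enforces positivity without explicit
constraints and makes the rate-constant scale natural; starting points
are supplied explicitly and there are no random restarts, so fits are
deterministic given data and guess. Non-convergence is flagged in the
result rather than thrown. The documented identifiable case is the
constitutive DUSP subsystem: observing `DUSPac` alone pins both the
relaxation rate $k_5 + d_5$ and the asymptote, hence $d_5$.
`recovery_experiment()` wraps generate-then-fit and reports
per-parameter relative error; recovery degrades monotonically in the
noise level (tested at 0–10% over 20 seeds).

## Experiment statistics and concordance

`delta_delta_ct()` implements relative quantification: replicate Ct
values are averaged per (sample, gene); the normaliser is the
*arithmetic mean* Ct of the two housekeeping genes (the source states
only "normalisation to the two housekeeping genes"; the arithmetic mean
in Ct space is geometric averaging of expression, the standard
convention and invariant to gene order); then
$\Delta\Delta C_t$ and fold change $2^{-\Delta\Delta C_t}$ follow
relative to the non-targeting reference. `z_test_counts()` is a
two-sample Z-test on means with independent standard errors — the
source names only "the Z-test", so the plainest two-sample variant is
used — significant at $p < 0.05$ by default.

`concordance()` scores model against experiment *directionally only*:
the source gives no mapping from survival-score magnitudes to 72-h fold
changes, so a silenced condition is mapped to an elevated $d_5$
(default: the scan grid's maximum, 500), the model's prediction is
"decrease" iff that trajectory eventually decreases, and the observed
direction is the Z-test-significant sign of silenced minus NT. In the
pipeline, DUSP16 silencing is scored under the constitutive topology
and DUSP8 silencing under the ERK12-induced topology — the pairing the
study's results support. A non-significant comparison is reported as
non-informative rather than forced into agreement or disagreement.

## Numerical choices and degenerate inputs

* The Hill term $(J \cdot P)^{0.6}$ is evaluated as 0 whenever the
  product is $\le 0$; no smoothing is applied. Tiny negative solver
  excursions therefore cannot produce NaN.
* Fixed points with vanishing denominators (e.g. $k_5 = d_5 = 0$) have
  no unique nonnegative solution and raise an error rather than
  returning an arbitrary root.
* Scan entries fail independently: an entry whose integration fails is
  recorded with its error message and the remaining grid is still
  scanned.
* Conservation checks divide by the protein total, falling back to
  absolute deviation for zero-total proteins.

## Problem sizes

Default runs integrate 11 states over 1001 output points; an
inhibition scan is six such integrations and completes in well under a
second. The test suite uses coarser output grids (101–201 points) for
shape-level checks and for the 80-fit noise-degradation study, and the
full default resolution wherever a numerical tolerance is asserted.
These sizes were chosen so the complete suite exercises every claim at
full precision while remaining quick to run routinely.

## Known limitations

* The unprinted rate constants are a reference reconstruction validated
  against qualitative regime behaviour, not fitted to data; absolute
  time and amount units are arbitrary.
* The single DUSP node conflates DUSP8 and DUSP16; topology variants,
  not separate nodes, distinguish their regulation.
* Survival is a proxy score linking proliferation and survival
  mechanisms it cannot distinguish.
* Concordance is directional; magnitudes of synthetic effects are design
  choices, not measurements.
* No stochastic (Gillespie) simulation, spatial structure, SBML export,
  or Herceptin pharmacokinetics.
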