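# duspkin

Kinetic modelling of DUSP-regulated HER2/MAPK signalling under
Herceptin.

HER2-positive breast cancer is commonly treated with Herceptin
(trastuzumab), but resistance frequently develops. Dual-specificity
phosphatases (DUSPs) — which dephosphorylate the MAP kinases ERK1/2,
JNK1/2 and p38 on both threonine and tyrosine — are central regulators
of this signalling, and DUSP8/16 are overexpressed in resistant cells.
`duspkin` is for systems biologists and modellers who want to ask,
quantitatively: *does inhibiting the DUSP re-sensitise resistant cells
to the drug, and does the answer depend on what induces the DUSP?*

## The model

Five proteins (HER2, ERK1/2, JNK1/2, p38, and a joint DUSP8/16 node),
each split into an active/inactive pair under first-order mass-action
kinetics, with Herceptin as a constant input *H* = 100 and an abstract
survival score *S* standing in for cell count:

    dHER2a/dt  = k1·HER2i − d1·HER2a·H
    dERK12a/dt = k2·ERK12i·HER2a − d2·ERK12a
    dJNK12a/dt = k3·JNK12i·HER2a − d3·JNK12a·DUSPa
    dP38a/dt   = k4·P38i·HER2a − d4·P38a·DUSPa
    dDUSPa/dt  = k5·DUSPi·ι − d5·DUSPa
    dS/dt      = s1·ERK12a − s2·(JNK12a·P38a)^0.6

(each inactive pool obeys the negated equation, so per-protein totals
are conserved exactly). The inducer factor ι selects the topology:
`constitutive` (ι = 1, the baseline DUSP16 model), `ERK12`
(ι = ERK12a) or `JNK12` (ι = JNK12a) for the two candidate DUSP8
induction mechanisms. The DUSP inactivation rate `d5` is the
inhibition knob: raising it emulates inhibition or shRNA silencing.

The package provides the model core with closed-form steady states and
an asymptotic survival-slope oracle, stiff ODE simulation and
`d5` inhibition scans, survival-regime classification
(increasing / inflected / decreasing), seeded synthetic cell-count and
qPCR data generators, least-squares parameter recovery, ΔΔCt
quantification, a two-sample Z-test, directional model–experiment
concordance, and a configuration-driven pipeline
(`run_pipeline()`). See the vignette in `vignettes/dusp-kinetics.Rmd`
for the full account of the methods.

## Worked example

Scan the baseline (constitutive-DUSP) model over the study grid of
inhibition strengths:

```r
library(duspkin)
model <- dusp_model("constitutive", dusp_params())
scan  <- inhibition_scan(model)   # d5 in {1, 10, 20, 50, 100, 500}
scan
#> <dusp_scan> topology constitutive, 6 d5 values, eps_frac 0.01, delta_frac 0.05
#>   d5     regime eventually_decreasing      s_end       s_max
#>    1 increasing                 FALSE   500.4505 500.4505472
#>   10 increasing                 FALSE   370.8726 370.8726180
#>   20 increasing                 FALSE   224.9111 224.9111099
#>   50  inflected                  TRUE  -144.6972  14.9216647
#>  100 decreasing                  TRUE  -560.3693   0.9281742
#>  500 decreasing                  TRUE -1437.7925   0.4317171
#> smallest eventually-decreasing d5: 50
```

Weak inhibition (`d5` ≤ 20) leaves survival rising throughout — the
proliferative ERK signal dominates. At `d5 = 50` the trajectory climbs
to a maximum of ~14.9 and then turns over (inflected): inhibition has
begun to reverse proliferation. At `d5` ≥ 100 survival collapses after
only a brief transient. The smallest eventually-decreasing `d5` is 50.

When DUSP8 is induced by ERK1/2 instead, strong inhibition cannot pull
the active phosphatase down — and survival never decreases:

```r
steady_state(dusp_model("ERK12", dusp_params(d5 = 500)))
#> <dusp_steady> topology: ERK12
#>    HER2ac   ERK12ac   JNK12ac     P38ac    DUSPac
#>  0.990099 49.751244  9.861669  9.861669  9.049774
#> eventual survival slope: 34.165
```

Active DUSP settles at ~9.05 (versus ~0.2 in the constitutive model at
the same `d5`), JNK1/2 and p38 stay suppressed, and the survival slope
stays positive — silencing an ERK-induced DUSP8 is predicted not to
reverse resistance, matching the DUSP8-silencing experiments.

Parameter recovery from noisy synthetic trajectories closes the loop
on the implementation:

```r
recovery_experiment(dusp_model("constitutive", dusp_params(d5 = 50)),
                    "d5", noise_sd = 0.05, n_reps = 3, seed = 7)
#>   parameter truth estimate       bias    rel_error
#> 1        d5    50  50.0268 0.02679589 0.0005359179
```

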