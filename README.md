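# saxakin

Mechanistic kinetic modeling of coupled PEG oxidation and saxagliptin
degradation in a tablet film coat.

## The problem

Saxagliptin (SAXA), a primary-amine DPP-IV inhibitor, is layered as an
active film coat onto inert tablet cores. In the coat, PEG 6000 plasticizer
autoxidizes into reactive low molecular weight impurities — glycolic acid
(GA), acetaldehyde (A), formaldehyde (F) and, via F, formic acid (FA). FA
lowers the micro-environmental pH, which steers the drug between two
degradation branches: OH⁻-catalyzed intramolecular cyclization to the
cyclic amidine (SCA) and its epimer (ESCA), and H⁺-catalyzed formylation to
the formyl amide (SFA). The package is for formulation and stability
scientists who want to simulate that coupled network, regress its Arrhenius
parameters from accelerated stability data, and stress-test the estimation
machinery on synthetic studies.

## The model

Nine species in molar equivalents per kg film coat, mass-action rate laws
with surplus oxygen folded into apparent constants:

    r1 = k1' c_PEG          (PEG -> GA)
    r2 = k2' c_PEG          (PEG -> A)
    r3 = k3' c_PEG          (PEG -> F)
    r4 = k4' c_F            (F -> FA)
    r5 = k5' c_OH- c_SAXA   (SAXA -> SCA)
    r6 = k6' c_OH- c_SCA    (SCA -> ESCA)
    r7 = k7' c_H+ c_SAXA c_FA - k8' c_SFA   (SAXA + FA <-> SFA)

with Arrhenius temperature dependence `k_i' = A_i exp(-E_a,i / RT)`, the
micro-environmental pH closed dynamically by the linear formic-acid law
`pH = 5.6703 - 570.45 w_FA` (mass fraction), ion concentrations from
`c_H+ = 10^-pH`, `c_OH- = Kw / c_H+`, and the reactive PEG fraction
`x_PEG = kH' a_w × out-of-phase fraction(PEG/(PEG+HPMC))`. Integration is
fixed-step fourth-order Runge-Kutta with step-halving convergence at an
absolute tolerance of 1e-5; regression is Levenberg–Marquardt on
log-transformed parameters with per-species range weights and one-sided
below-LOQ censoring. See `vignette("degradation-kinetics")` for the full
account.

## Worked example

Simulate the highest-PEG formulation (PEG:SAXA = 1.4) at 40 °C and water
activity 0.10:

```r
library(saxakin)
comp <- make_initial_composition(1.4)
env  <- stability_condition(40, 0.10, peg_saxa_ratio = 1.4,
                            peg_hpmc_ratio = comp$peg_hpmc_ratio)
traj <- simulate_kinetics(comp$init, default_parameters(), env,
                          t_grid = c(0, 7, 14, 30, 60, 108, 180))
round(as.data.frame(traj)[, c("time_days","F","FA","SAXA","SCA","ESCA","SFA","pH")], 5)
#>   time_days       F      FA    SAXA     SCA    ESCA     SFA      pH
#> 1         0 0.00000 0.00000 0.79260 0.00000 0.00000 0.00000 5.67030
#> 2         7 0.00202 0.00137 0.78858 0.00383 0.00019 0.00000 5.63443
#> 3        14 0.00199 0.00354 0.78501 0.00693 0.00064 0.00002 5.57742
#> 4        30 0.00095 0.00696 0.77819 0.01212 0.00220 0.00010 5.48770
#> 5        60 0.00015 0.00866 0.76728 0.01874 0.00622 0.00036 5.44290
#> 6       108 0.00001 0.00854 0.75067 0.02588 0.01523 0.00082 5.44610
#> 7       180 0.00000 0.00794 0.72586 0.03204 0.03326 0.00143 5.46185
```

Concentrations are mol/kg film coat. Formaldehyde peaks early (day 10,
2.1e-3 mol/kg via `formaldehyde_peak()`) and is oxidized on to formic
acid, which plateaus within ~50 days as the reactive PEG pool depletes;
the pH falls from 5.67 toward 5.44; the epimer (ESCA) overtakes the cyclic
amidine (SCA) late in the study while the formyl amide (SFA) keeps rising.

End-to-end parameter recovery — generate a noiseless full-factorial
synthetic study (4 compositions × 3 temperatures × 3 humidities, 7 pulls),
multiply all free starting values by 1.5, and refit with the staged
Levenberg–Marquardt sequence:

```r
rec <- recovery_experiment(seed = 1, sigma = 0)
rec$table[c("parameter", "truth", "recovered", "rel_error")]
#>     parameter     truth recovered  rel_error
#> k5         k5 1.600e+05 1.600e+05 -5.457e-16
#> k7         k7 4.000e+02 4.000e+02 -1.137e-15
#> kHp       kHp 2.500e-02 2.500e-02  4.163e-16
#> Ea5       Ea5 8.854e+01 8.854e+01  8.025e-16
#> Ea7       Ea7 1.516e+02 1.516e+02  0.000e+00
#> ... (k1-k4, k6 recovered identically)
```

Both anchored activation energies — 88.54 kJ/mol for cyclization and
151.6 kJ/mol for formylation — are recovered to machine precision on the
noiseless design.

A command-line wrapper over the same functions ships in
`inst/cli/saxakin.R` with subcommands `generate`, `simulate`, `fit`,
`doe` and `recover`.

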