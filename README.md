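# eldergame

An R package for analysing the regulation of "Internet + Community Elderly
Care" services as an **asymmetric four-population evolutionary game**. The
players are elderly-care service providers (high- vs low-quality service,
share *x*), service information platforms (positive vs negative return
visits, *y*), the government (positive vs negative regulation, *z*) and the
elderly themselves (online vs offline evaluation, *w*). The elderly's
omnichannel feedback — online evaluations, offline word of mouth in a social
network of relative size *γ*, complaints at rate *β*, and platform return
visits — disciplines provider and platform behaviour alongside government
fines and subsidies.

The package is aimed at health-systems and policy modellers who want to go
beyond the printed analysis: rerun the stability classification under their
own calibrations, locate the penalty/subsidy thresholds at which policy
starts to bite, and simulate how quickly each population converges under
alternative policy settings.

## The model

Each population follows replicator dynamics: its strategy share grows in
proportion to the payoff advantage of that strategy over the population
average,

    dx/dt = x(1−x)·G(y,z,w)      (providers)
    dy/dt = y(1−y)·H(x,z,w)      (platforms)
    dz/dt = z(1−z)·P(x,y)        (government)
    dw/dt = w(1−w)·(Cm−Cw)       (elderly)

where `G`, `H`, `P` are the incentive differences (expected payoff of the
first strategy minus the second) implied by a 16-cell payoff matrix over 25
scalar parameters — revenues `Rs`, costs `Csh, Csl, Cei, Ceo, Cg, Cw, Cm`,
fines `Fs, Fe, Fg`, subsidy `S`, compensation `Io`, reputational terms
`Is, Ds, Ie, De`, welfare terms `Rg, Dg, Ro, Do, Co`, and the rates
`α, β, γ`. Every vertex of the unit hypercube is a fixed point; the Jacobian
is diagonal there, so Lyapunov's first method classifies each of the 16
corners from four eigenvalue signs (all negative: evolutionarily stable
strategy, ESS). Closed-form thresholds (`w0`, `w1`, `x0`, minimum fine
`Fs'`, minimum subsidy `S'`, minimum superior penalty `Fg'`) and
strategy-volume probabilities complete the analytic layer, and a fixed-step
simulator (Euler, step 0.0125 on t ∈ [0, 3], matching the original
system-dynamics treatment) with five built-in sensitivity suites provides
the numerical layer.

## Worked example

```r
library(eldergame)
p <- game_params()       # baseline calibration
rep <- stability(p)
rep$ess
#> [1] "E13"
```

`E13 = (1, 1, 0, 1)` is the unique ESS at the baseline: providers deliver
high quality, platforms make positive return visits, the elderly evaluate
online — and the government can afford *negative* regulation, because the
feedback channels substitute for supervision. Its eigenvalues are
`(−27, −27, −10, −2)`: the provider margin `Csh−Csl−Is−Ds−Io = −27`, the
platform margin `Cei−Ie−De−S = −27`, the regulation saving `−Cg = −10` and
the evaluation-cost gap `Cw−Cm = −2`. The corners `E7, E8, E15, E16` are flagged
`always_unstable`: they pair compliant providers with costly positive
regulation, so one eigenvalue is `+Cg > 0` for every admissible calibration.

The simulation confirms the analytic picture:

```r
tr <- simulate_game(p)   # Euler, step 0.0125, from (0.5, 0.5, 0.5, 0.5)
tr
#> replicator trajectory: 240 steps of 0.0125 (euler), t in [0, 3]
#> final state: x = 1.0000, y = 1.0000, z = 0.0000, w = 0.9977
detect_converged_strategy(tr)
#>    x    y    z    w
#> "HQ" "PV" "NR" "ON"
```

Policy levers:

```r
threshold_w0(p, y = 0, z = 0)
#> threshold w0 = 0.566416  (at y = 0, z = 0)
#>   w > w0: providers evolve to high-quality service; w < w0: to low-quality service
strategy_volumes(p, "government")
#> government strategy volumes
#>   V0 (negative regulation): raw 0.430818, clamped 0.430818
#>   V1 (positive regulation): raw 0.569182, clamped 0.569182
```

With no platform follow-up and no active regulation, providers only turn
honest once more than ~57% of the elderly evaluate online; and over all
opposing-strategy configurations the government regulates positively with
probability ~0.57.

Sensitivity suites (and everything above) are also available from the
shell via the bundled CLI:

```sh
Rscript inst/cli/ecgame stability --out results/
Rscript inst/cli/ecgame scenarios --suites penalty_provider,complaint_rate --out results/
Rscript inst/cli/ecgame simulate --config my_calibration.yaml --out results/
```

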