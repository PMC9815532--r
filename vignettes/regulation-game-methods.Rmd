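---
title: "Methods: the four-party elderly-care regulation game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-party elderly-care regulation game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldergame)
```

## The model and its assumptions

"Internet + Community Elderly Care" couples four boundedly rational
populations. Service **providers** choose between high-quality (share
`x`) and low-quality service; high quality costs more (`Csh > Csl`) but
earns reputational gains `Is`, while low quality risks the government fine
`Fs`, compensation `Io` to the buyer, and reputational losses `Ds`.
Information **platforms** choose whether to make positive return visits
(share `y`) at cost `Cei`, rewarded by the subsidy `S` and reputation
`Ie`/`De`, or to skip them and risk the fine `Fe` when a low-quality
provider is caught. The **government** regulates positively (share `z`)
at cost `Cg`, collecting `Fs`/`Fe` from offenders, or negatively, in which
case sanctions only arrive when the elderly complain (rate `β`) and the
superior government may fine it `Fg`. The **elderly** evaluate online
(share `w`, cost `Cw`) or offline (cost `Cm`); offline feedback only
reaches a social network of relative size `γ`, so every reputational term
is discounted by `γ` in the offline column of the payoff matrix, and in
the no-visit/no-regulation cells all sanctions (`Fs`, `Fe`, `Fg`, `Io`,
`Co`) are discounted by the complaint rate `β`.

Each population follows continuous-time replicator dynamics,
`dx/dt = x(1−x)G(y,z,w)` and analogues, where the incentive differences
`G`, `H`, `P`, `Cm−Cw` are the expected-payoff gaps between the two pure
strategies. The model is deterministic; there is no mutation, drift or
finite-population noise.

Two layers encode the same algebra on purpose: `payoff_cell()` implements
the 16-cell matrix directly, and `incentive_difference()` implements the
closed-form gaps. Their agreement is a *test* (brute-force expectation
over the eight opposing pure-strategy combinations on 200 random
parameter sets), not an assumption — this catches transcription slips in
either layer. The replicator right-hand side calls
`incentive_difference()` only, so the algebra has one source of truth.

## Parameters

All 25 constants live in `game_params()`; the baseline calibration is the
package default. Monetary quantities are in abstract currency units (the
model never fixes a currency); rates are stored as fractions, so the
baseline has `alpha = 0.10`, `beta = 0.01`, `gamma = 0.05`. Admissibility
means non-negative magnitudes, rates in `[0, 1]`, and `Csh > Csl`;
`validate_params()` reports violations rather than raising, and
`scale_param()` (the elementary move of every sensitivity scenario)
always returns a validated copy, so scenario suites cannot
cross-contaminate. The provider fine `Fs` is modelled as the
administrative penalty on low-quality service, distinct from the
compensation `Io`.

```{r}
unlist(unclass(game_params()))[c("Fs", "Io", "S", "beta", "gamma")]
```

## Corner stability and the sign-sampling rule

Every vertex of `[0,1]^4` is a fixed point, and the Jacobian there is
diagonal with entries `(1−2x)G`, `(1−2y)H`, `(1−2z)P`, `(1−2w)(Cm−Cw)`,
so Lyapunov's first method reduces to four sign checks
(`classify_eigenvalues()`: ESS below `−tol`, unstable above `+tol`,
otherwise indeterminate — non-hyperbolic corners are never silently
classified; the tolerance defaults to `1e-9` and is configurable).

Some corners are unstable for *every* admissible calibration — pairing
compliant providers with costly positive regulation leaves a `+Cg`
eigenvalue. `stability()` detects this by sign-sampling: a corner is
flagged `always_unstable` when some eigenvalue slot is positive in all of
`n_draws` (default 1000) random admissible parameter sets. Sampling
avoids a symbolic-algebra dependency; 1000 draws make a false flag
vanishingly unlikely provided every genuinely sign-varying eigenvalue
expression actually varies under the sampler. That is why
`random_game_params()` draws magnitudes log-uniformly on (0.1, 100):
expressions such as `Is+Ds+Fs+Io−(Csh−Csl)` must go negative with
non-trivial probability, which requires draws that span scales rather
than concentrate near a common mean.

One bookkeeping note: at the all-cooperate corner `E16` the first
eigenvalue is taken as `−G(1,1,1) = Csh−Csl−Is−Ds−Fs−Io`, which follows
from the incentive algebra; some published tabulations of this model
carry an extra `−S` term there that the expected-utility layer does not
produce. The discrepancy does not affect the corner's classification
(its `+Cg` entry keeps it unstable).

## Thresholds and strategy volumes

All six policy thresholds are defined — and implemented — as exact roots
of `G`, `H` or `P` in the variable of interest, so substituting a
threshold back into its incentive function yields zero by construction;
the tests verify this on random draws and against independent bisection.
Defining the thresholds via the roots also resolves two typographical
ambiguities in circulated statements of the provider threshold (a
`(1−y)` where the `w`-coefficient of `G`, `(1−γ)(Is+Ds)`, belongs, and a
garbled `zIo` token): the root of `G` is unambiguous. Degenerate
coefficients (e.g. `γ = 1`, or a fine that never bites because `z = 0`
and `(1−y)(1−z)β = 0`) raise explicit errors rather than returning
infinities.

Strategy volumes integrate the unclamped threshold surface over the
opposing-probability cube; the government volume has the closed form
`Vz1 = 1 − Cg·ln|1+m/Fs|/m` with `m = Fe−βFs−βFe+βFg`, and the removable
singularity at `m = 0` is evaluated by its limit `1 − Cg/Fs` (switched
below `|m| < 1e-10`; the integrand is then constant and the limit exact
to machine precision). Because the surface is unclamped the raw pair can
leave `[0,1]` (it still sums to 1); both the raw and the clamped,
probability-interpretable pairs are reported. A consequence worth
flagging: the textbook monotonicities of the volumes in the reputational
terms (`∂Vy1/∂Ie > 0` and so on) implicitly assume the raw volume is a
genuine probability. At the baseline the platform surface lies entirely
below the cube (`Vy0 < 0`, every calibration of interest already
delivers positive visits) and those two derivatives flip sign; the
package reports what the closed form gives and the test suite checks the
monotonicities where their hypothesis holds.

## Simulation engine

`simulate_game()` advances the replicator field on a fixed grid —
defaults `t ∈ [0, 3]`, step `0.0125`, forward Euler — because that is the
scheme the model's system-dynamics formulation runs under fixed-step
Vensim-style engines; fidelity to that treatment comes first, and a
classical RK4 option plus an adaptive-integrator cross-check in the test
suite guard accuracy. On this field Euler at step 0.0125 is comfortably
stable (the largest own-strategy rate at the baseline is ~47, well below
the 2/step ≈ 160 stability bound) and halving the step moves the final
state by less than `1e-3`. After every step the state is projected back
to `[0,1]^4` (on by default): Euler overshoot at the cube boundary must
not produce invalid probabilities. States that arrive slightly outside
the cube are evaluated as-is by the vector field; clamping is the
integrator's job, not the algebra's.

The initial state is not part of the model's published configuration;
the package defaults to the maximally uninformative centroid
`(0.5, 0.5, 0.5, 0.5)`, always configurable and always recorded in the
trajectory's metadata. Convergence is operationalised by
`detect_converged_strategy()` (a trailing window — default 40 grid
points, i.e. half a time unit — within `tol` of a vertex) and evolution
speed by `time_to_threshold()` (first grid time the share crosses a
level in the direction of its eventual limit). The elderly equation
decouples (`dw/dt = w(1−w)(Cm−Cw)`), giving an exact logistic solution
that the suite uses as a closed-form oracle.

## Sensitivity suites

`builtin_scenarios()` freezes the five policy experiments: `Fs` and `Io`
±50% (values 10/20/30 and 5/10/15), `Fe` and `S` ±50% (2.5/5/7.5 and
5/10/15), initial `w` ∈ {0.25, 0.75}, the four reputational terms
jointly ×0.5 / ×1.5, and `β` ∈ {0.01, 0.41}. The online-evaluation suite
is interpreted as an *initial-condition* override — `w` still evolves —
because the elderly population does adjust its behaviour in the model; a
`hold` argument to `simulate_game()` provides the alternative
frozen-share reading. All variants run from the same initial state on
the same grid, so their threshold-crossing times are directly
comparable. The qualitative orderings the suites are tested for: larger
fines, compensation, subsidies and reputational stakes accelerate the
corresponding population's convergence; a larger initial online share
accelerates everyone; a larger complaint rate speeds providers up and
slows the government's drift to negative regulation. The platform fine
`Fe` is allowed to tie at grid resolution — negative return visits are
not illegal per se, so `Fe` bites only through the shrinking mass of
low-quality providers, and its effect is correspondingly weak.

## What the tests do and do not show

The test battery runs the game at the baseline and at hundreds of random
admissible calibrations: structural counts (16 corners, two
unconditionally unstable per evaluation face, 4+2 partition of the
conditionally stable corners), equality of the Jacobian eigenvalues with
the symbolic table expressions to `1e-9`, volume/quadrature agreement to
`1e-6`, threshold-root identities, and convergence of every built-in
variant with a unique ESS to that ESS. Problem sizes (1000 sign-sampling
draws, 100–200 random calibrations per property, 240-step trajectories)
were chosen to make the checks sharp while keeping the whole battery in
the tens of seconds. None of this validates the model *empirically*:
parameters are stylised, payoffs are linear in the shares, populations
are infinite and well-mixed, and real elderly-care markets add noise,
heterogeneity and strategic sophistication the replicator abstraction
deliberately omits. Passing tests certify internal consistency of the
algebra, the analytic layer and the simulator — not calibration to data.

## Known limitations

- Only corner (pure-strategy) equilibria are classified; interior mixed
  rest points of this asymmetric game are not strict Nash equilibria and
  are not solved for.
- The corollary-style derivative signs are checked numerically, not
  proved symbolically, and the volume monotonicities hold only where the
  raw volume is a genuine probability (see above).
- The sign-sampling `always_unstable` rule is probabilistic; it matches
  the known `+Cg` pattern with overwhelming probability at the default
  draw count but is not a proof.
- The elderly's feedback is honest by construction: distorted or induced
  evaluations are outside the model.
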