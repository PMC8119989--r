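# proxsir

Distance-coupled SIR epidemic models with prevalence-driven social
distancing.

## What it is for

Classical SIR models treat the transmission rate as a constant.  In
reality, people react to an unfolding epidemic by keeping more distance
from each other — and how much distance they keep in normal times is
cultural.  `proxsir` implements a compartmental model for
epidemiologists and modellers who want to study that feedback loop: the
transmission rate is a decreasing convex function of the *average
interaction-distance* `D(t)`, and `D(t)` itself is a state variable that
rises with observed point prevalence and relaxes back towards a
society's *natural-distance* `D*`.

The governing system is

```
S' = -beta(D) S I / N
I' = +beta(D) S I / N - gamma I
R' = +gamma I
D' = -lambda1 (D - D*) + lambda2 I / N
```

where `lambda1` [1/day] is the rate of cultural resistance pulling `D`
back to `D*` and `lambda2` [m/day] is the reaction velocity converting
prevalence into distancing.  Four transmission-rate forms are provided,
all normalised so that `beta(Dbar*) = beta*` at a scaling distance
`Dbar* = 1.05 m`:

| form  | beta(D)                                | limit at D = 0      |
|-------|----------------------------------------|---------------------|
| beta1 | `beta* [2 Dbar*/(Dbar* + D)]^nu`       | `2^nu beta*`        |
| beta2 | `beta* 2 Dbar*^nu/(Dbar*^nu + D^nu)`   | `2 beta*`           |
| beta3 | `beta* (Dbar*/D)^nu`                   | unbounded           |
| beta4 | `beta* exp[1 - (D/Dbar*)^nu]`          | `e beta*`           |

Societies are typed by natural-distance: **small** (`D* < 1 m`, e.g.
0.75 m), **medium** (`1–1.2 m`, e.g. 1.05 m), **large** (`> 1.2 m`,
e.g. 1.35 m).  Started at `D(0) = D*`, the basic reproduction number is
the classical threshold evaluated at the natural-distance,
`R0 = beta(D*)/gamma`.

The package also implements the model's analytic identities as
validators (the integrating-factor closed form for `D(t)`, the
susceptible log-identity, and the final-size expression with its
power-law special case), peak detection with prominence filtering,
figure-style scenario presets, parameter sweeps, a YAML scenario format
and a CLI.

## Worked example

A close-contact society (`D* = 0.75 m`) under the power-law rate:

```r
library(proxsir)

p <- model_parameters(nu = 1, D_star = 0.75)
basic_reproduction_number("beta3", p)
#> [1] 3.5

traj <- simulate_sir(p, initial_state(D0 = 0.75), "beta3", t_end = 500)
traj
#> Distance-coupled SIR trajectory (beta3, small society)
#>   5001 points on [0, 500] days; R0 = 3.500
#>   final: S = 0.155962, I = 2.34e-21, R = 0.844038, D = 0.750001 m

find_first_peak(traj)
#> Epidemic peak: prevalence 0.26664 at t = 25.21 days

susceptible_identity(traj)
#> Susceptible log-identity report
#>   max residual 2.189e-09 over 5001 grid points (cumulative composite Simpson, h = 0.1 day)
```

Reading: with `beta* = 0.5/day` and `gamma = 0.2/day`, a society that
keeps 0.75 m on average has `R0 = beta3(0.75)/0.2 = 3.5`; the epidemic
peaks at 26.7% of the population infectious on day 25, and 84.4%
are eventually infected.  The log-identity residual of order 1e-9
confirms solver and quadrature agree along the whole trajectory.  The
same scenario is available as the preset `"fig6_small"`
(`simulate_preset("fig6_small")`), and
`sweep_peaks("lambda2")` shows how faster social reaction lowers the
peak.  Strong distance sensitivity (`nu = 10.5`,
`simulate_preset("fig9_nu10.5_beta3")`) breaks the single-peak shape of
classical SIR and produces several epidemic waves —
`find_all_peaks()` counts them.

## Command line

```sh
exec/proxsir r0-table --out r0.csv
exec/proxsir simulate --preset fig6_small --out traj.csv
exec/proxsir validate --preset fig6_small        # exit 0 iff identities hold
exec/proxsir sweep --sweep lambda2 --out sweep.csv
```

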