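---
title: "Measuring and repairing spatial healthcare inequity with tele-health: the i2SFCA-TH model"
author: "teleaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and repairing spatial healthcare inequity with tele-health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleaccess)
```

## The problem

Chronic-disease care in a metropolitan district is delivered through three
channels: routine treatment at community hospitals, referral of a fraction
of patients to tertiary-A hospitals, and — increasingly — online
consultations served by tertiary physicians. The first two channels are
spatial: how much care a resident can reach depends on where the hospitals
are and how far away they live. The third is not: once physician time is
allocated to an online clinic, every division in the district competes for
it on equal footing, regardless of distance. `teleaccess` measures
per-division accessibility across all three channels and optimizes the
online allocation under an explicit equity constraint.

## The accessibility model

### Gravity-form two-step floating catchment

The offline backbone is a floating catchment area measure in gravity form.
Each site $j$ with supply $S_j$ (physician consultation-time units per day)
spreads its supply over all divisions in proportion to decayed demand, and
each division $k$ with demand population $M_k$ collects its shares:

$$a_k \;=\; \sum_j \frac{S_j\, f(d_{jk})}{\sum_l M_l\, f(d_{jl})},
\qquad f(d) = \max(d, d_{\mathrm{floor}})^{-\beta}.$$

Two properties make this form the right backbone:

* **Supply conservation.** Without a hard catchment cutoff,
  $\sum_k M_k a_k = \sum_j S_j$ identically — accessibility is exactly
  "supply per head, spatially disaggregated". This is the central invariant
  of the test suite (checked to $10^{-9}$ relative on hundreds of random
  instances).
* **Degenerate limits.** $\beta = 0$ collapses every division to the
  uniform ratio $\sum S / \sum M$; a fully symmetric instance yields a
  constant profile. Both are asserted exactly.

The classical hard-threshold two-step form (sum of site ratios within a
catchment radius $d_0$) is also provided (`catchment_accessibility()`,
`supply_ratio()`); with flat decay and an all-covering threshold the two
forms coincide, which the suite checks. The default pipeline uses pure
decay with no threshold, because that is the form the optimization model
constrains; $d_0$ remains available as an optional hard cutoff. An empty
catchment yields a zero ratio with a warning rather than an error, so
degenerate draws do not abort batch sweeps.

$\beta = 2$ is the default decay exponent, the customary value for
intra-urban hospital access in Chinese cities. Distances are floored at
$d_{\mathrm{floor}} = 0.1$ km before decay since $d^{-\beta}$ diverges at
zero; the floor only matters when a site and a division centroid nearly
coincide.

### Referral and the two hospital tiers

Community hospitals (supplies $S_j$) provide first-line chronic-disease
treatment; a referral rate $r$ of patients additionally visits a
tertiary-A hospital (supplies $T_i$):

$$a_k^{\mathrm{off}} = (1-r)\,a_k^c + r\,a_k^a.$$

No published value of $r$ for this setting is available to us; the package
default is $r = 0.2$, a moderate referral intensity, and the parameter is
exposed everywhere. With both tiers conserving, the blend conserves
$(1-r)\sum S + r\sum T$, another tested invariant.

### Online consultations

A division's online preference $Q_k$ is assigned by a two-tier rule: all
divisions with baseline offline accessibility strictly below the regional
mean count as poor-access and get $Q_k = 0.35$; the rest, ties included,
get $Q_k = 0.1$ (a deterministic tie-break). Online accessibility pools
the allocated tertiary time $V_i$ over online demand:

$$a_k^v = \frac{Q_k \sum_i V_i}{\sum_l Q_l M_l},$$

and the combined index is

$$a_k = (1-Q_k)\bigl[(1-r)a_k^c + r\,a_k^a\bigr] + Q_k\,a_k^v.$$

Note that $Q_k$ appears both inside $a_k^v$ and as the combination weight,
so the online contribution scales with $Q_k^2$. We implement this reading
as the default (`online_mode = "as_printed"`) for fidelity to the
formulation of the method as it circulates in the literature. It has the consequence that online supply is
*not* conserved across divisions
($\sum_k M_k Q_k a_k^v \ne \sum_i V_i$ in general). A second mode,
`"conserving"`, drops the $Q_k$ factor inside $a_k^v$ so that conservation
holds exactly; the property-based tests of online supply conservation run
in this mode. Which reading is intended is
genuinely ambiguous — the duplication may be typographical — so both are
first-class and switchable.

### The demand stratum

Demand $M_k$ can be the total, elderly, or chronic-disease population of a
division. The default is `"chronic"`: the model's scope is chronic-disease
care (community hospitals treat it, referrals and online clinics serve
it), so the chronic population is the coherent demand mass. The choice is
a single parameter and all strata are carried in every instance.

## Equity statistics

For a profile $a_1,\dots,a_P$ the package reports the gap
$a_{\max}-a_{\min}$, the **equilibrium index**

$$E = \frac{a_{\max}-a_{\min}}{a_{\max}+a_{\min}} \in [0,1],$$

a Gini-like spread measure that is scale-invariant and zero for a flat
profile, and a population-weighted Gini coefficient (weights default to
the demand populations, since divisions differ in $M_k$ by two orders of
magnitude; an unweighted version is the same call with equal weights). The
Gini implementation uses the sorted Lorenz-curve formula and is tested
against the $O(n^2)$ pairwise-difference oracle to $10^{-12}$.

## The allocation program

The optimizer chooses $V_i \ge 0$ to maximize the mean combined index
subject to:

* the cap $V_i \le \rho_i T_i$ (default $\rho_i = 0.4$);
* bracketing constraints $a_{\min} \le a_k \le a_{\max}$ for all $k$;
* the equity bound $E \le G$ (default $G = 0.7$), linearized exactly as
  $(1-G)\,a_{\max} \le (1+G)\,a_{\min}$, which is algebraically equivalent
  whenever $a_{\max}+a_{\min} > 0$.

$a_{\min}, a_{\max}$ are auxiliary decision variables by default
(`bounds_mode = "variable_extremes"`). Because any feasible choice must
bracket the realized extremes, the linearized constraint is satisfiable
exactly when the realized spread satisfies the bound, so no objective
pressure on the auxiliaries is needed. A `"fixed_bounds"` mode accepts
user-supplied limits instead, matching the alternative reading of the
bound as "a desired range".

Two offline treatments of the shifted time are provided.
`offline_mode = "resource_shift"` (default) replaces $T_i$ with
$T_i - V_i$ in the tertiary offline term, so total physician time is
conserved — this is the only reading under which high-access divisions'
indices can *decrease* when tele-health is introduced, which is the
behavior the method is designed to produce, and conservation is asserted
in the tests. `"as_printed"` leaves the offline tertiary term untouched
(online time is then additional capacity); in that mode, with a single
tertiary site and no binding equity constraint, the objective is
nondecreasing in $V$ and the optimum saturates the cap — an analytic fact
the suite verifies by sweep.

Since every $a_k$ is affine in $V$, the program is a linear program. It is
solved with the simplex implementation in the recommended `boot` package
behind a thin interface; feasibility is accepted at $10^{-6}$. The
returned profile is always *recomputed* from the optimal $V$ through
`i2sfca()` — the public model equations — as a guard against drift between
the LP matrix and the model. Allocations are continuous by default
(consultation time is divisible); `integrality = "integer"` solves a true
MIP by branch-and-bound on the LP relaxation, stopping at a relative gap
of $0.01$ (with the $10^{-6}$ feasibility tolerance), which matches
standard solver defaults for this problem class. When the equity bound is
unreachable the result carries status `"infeasible"` together with the
minimal achievable equilibrium index found by bisection on $G$ (to
$10^{-3}$).

If the profile is entirely independent of $V$ (for example $Q \equiv 0$
with fixed tertiary supply), every feasible allocation is optimal and the
solver canonicalizes to $V = 0$.

### The brute-force oracle

`brute_force_allocation()` enumerates $V$ on a regular grid over
$\prod_i [0, \rho_i T_i]$, evaluates the profile for every point through
the model equations (vectorized), filters by the equity bound, and returns
the best mean, breaking ties lexicographically. A combinatorial guard
restricts it to $L \le 4$ tertiary sites and at most 50 grid steps. On
random small instances the LP and the grid at 20 steps agree to a relative
gap of $10^{-2}$, and the grid optimum converges monotonically to the LP
optimum as the grid refines — both are part of the test suite. The oracle
never shares the LP's constraint matrix, so agreement is evidence against
construction errors.

## The synthetic district generator

Real hospital-level supply data for the kind of district this method
targets are typically restricted, so the package ships a seeded generator
(`generate_city()`) whose default configuration emulates a central urban
district: 13 residential divisions on a jittered grid over a 15 km square,
6 tertiary-A and 56 community hospitals, chronic populations of
$10^2$–$10^4$ per division.

Structural features, chosen to reproduce the regime such districts
exhibit, with all constants frozen by a one-off Monte-Carlo calibration:

* **Center–periphery population gradient.** Chronic populations are drawn
  log-scale from a blend (weight 0.6) of a Gaussian centrality score
  (width $0.3 \times$ extent) and uniform noise: the center is dense, the
  periphery sparse, and draws span the configured two-orders-of-magnitude
  range.
* **Old-town supply cluster.** Hospitals cluster around a point offset
  from the demographic center by $0.15 \times$ extent in a random
  direction, emulating historical siting. Tertiary sites use spread
  $\tfrac{ext}{2}(1-c) + 0.02\,ext$ and clustered community sites
  $\tfrac{ext}{2}(1-c) + 0.015\,ext$, with $c$ the `centralization`
  parameter (default 0.9).
* **Local community centers.** One community site per division (jitter
  0.8 km) reflects the sub-district service mandate of community health
  service centers; the remaining community sites join the central cluster.
* **Supply magnitudes.** Resources are lognormal (sdlog 0.4) around
  tier-specific levels with a tertiary:community ratio of 40 — a
  tertiary-A hospital operates a far larger physician staff than a
  community health service center — scaled so total supply is about 0.72
  consultation-time units per chronic resident. The ratio matters: with a
  much smaller tertiary share, the online channel (capped at
  $\rho \sum T$) is too small relative to online demand for any equity
  bound in the operating range to be satisfiable.

With the frozen defaults, a 100-seed Monte-Carlo check (rerun in the test
suite) finds baseline equilibrium indices above 0.5 in well over 90% of
draws, and the canonical `lubei_like` fixture (seed 1) exhibits a baseline
gap at least three times the mean and an equilibrium index of at least
0.7 — strong but repairable inequality, in which the default bound
$G = 0.7$ is active.

What the generator does **not** emulate: road networks (costs are
haversine kilometres between centroids; a user-supplied cost matrix in any
unit always takes precedence), intra-division population structure,
correlation between population and hospital siting beyond the two
gradients, insurance or economic heterogeneity. Passing tests on synthetic
instances therefore demonstrate the correctness and qualitative behavior
of the method, not calibrated predictions for any real district.

`make_fixture_suite()` additionally provides a fully symmetric instance
(constant profile) and a hand-calculable two-division toy whose
community-tier accessibility is exactly $(0.08, 0.02)$.

## Numerical and interface choices

* Travel costs: haversine km from lon/lat, Euclidean for planar
  coordinates, user matrix wins. Costs are stored long-form
  (`site_id, division_id, cost`) so the CSV schema is stable across
  instance sizes.
* All floats are serialized at 12 significant digits; reruns of the same
  configuration and seed are byte-identical (tested).
* Preference assignment ties ($a_k$ equal to the mean) classify as
  good-access, deterministically.
* Zero demand in a site's denominator contributes zero flow ($0/0 = 0$ by
  construction); an all-zero profile has equilibrium index 0 by definition.
* Schema violations raise conditions of class `teleaccess_schema_error`
  naming the offending record; solver infeasibility in the pipeline raises
  `teleaccess_infeasible`. The CLI maps these to exit codes 2 and 3.

Problem sizes in the shipped tests: property checks run on instances of
3–10 divisions and 4–11 sites (hundreds of draws); oracle comparisons on
$P \le 6$, $L \le 3$ with $21^L$ grid points; full-size checks on the
13-division, 62-site default district, including a 100-seed calibration
sweep. These sizes were chosen so the whole suite documents the model's
behavior in seconds while still exercising every code path at the
district scale the method targets.

## Known limitations

* The equilibrium index only sees the extremes; two profiles with equal
  extremes but different interiors are equally "equitable" to the
  constraint. The weighted Gini is reported alongside for that reason.
* The as-printed online mode double-counts $Q_k$ (see above); totals
  across divisions should be interpreted with care in that mode.
* The two-tier preference rule is a step function of baseline
  accessibility; real uptake of tele-health varies continuously and by
  condition, age, and digital literacy.
* The optimizer treats demand as inelastic: shifting physician time online
  does not change where patients live or their referral behavior.
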