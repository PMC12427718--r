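# teleaccess

Spatial accessibility of chronic-disease care in metropolitan districts,
and how tele-health can repair its inequity.

In many dense Chinese (and not only Chinese) cities, hospitals cluster in
the historical center while residents — above all elderly patients with
chronic diseases — live throughout the district. Classical two-step
floating catchment area (2SFCA) analysis makes this visible: each
facility's supply is spread over the demand it can reach, discounted by a
distance-decay weight, and each residential division sums the shares it
receives. `teleaccess` implements an improved form of this analysis for
chronic-disease care (i2SFCA-TH) that distinguishes community hospitals
from tertiary-A hospitals, routes a referral fraction of patients from the
former to the latter, and adds a third, *distance-free* channel: online
consultations served by tertiary physician time. On top of the measurement
model it provides an equity-constrained optimizer that decides how much
tertiary physician time each hospital should shift online.

The package is aimed at health-services researchers and urban planners who
want a reproducible, data-frame-in/data-frame-out implementation of the
method, with a synthetic-city generator so every step can be exercised
without access to restricted hospital data.

## The model

For division *k* and hospital tier with supplies *S<sub>j</sub>* (community)
or *T<sub>i</sub>* (tertiary), demand populations *M<sub>l</sub>* and travel
costs *d<sub>jk</sub>*, the gravity-form accessibility of a tier is

> a_k = Σ_j S_j f(d_jk) / Σ_l M_l f(d_jl),   f(d) = d^(−β), β = 2 by default.

A referral rate *r* blends the two offline tiers,
a_k = (1−r)·a_k^c + r·a_k^a. Online consultations pool the allocated
tertiary time V_i and distribute it over online demand,
a_k^v = Q_k·ΣV / Σ_l Q_l M_l, where Q_k is the division's online
preference (0.35 in poor-access divisions, 0.1 in good-access ones).
The combined index is

> a_k = (1−Q_k)·[(1−r)·a_k^c + r·a_k^a] + Q_k·a_k^v.

The allocator chooses V (capped at ρ_i·T_i per hospital, ρ = 0.4 by
default, and deducted from offline tertiary capacity so total physician
time is conserved) to maximize the mean of a_k subject to the equity
constraint (a_max − a_min)/(a_max + a_min) ≤ G, solved as a linear
program; a brute-force grid oracle verifies the optimizer on small
instances.

## Worked example

```r
library(teleaccess)

city <- generate_city(city_config(seed = 1))   # 13 divisions, 6 + 56 hospitals
baseline <- i2sfca(city, Q = setNames(rep(0, 13), city$divisions$id))
baseline
#> i2SFCA-TH accessibility profile (13 divisions)
#>   mean 0.199, min 0.04268, max 0.9292, gap 0.8865, equilibrium index 0.9122

res <- allocate_telehealth(city, G = 0.7)
res
#> Tele-health allocation (optimal)
#>   objective (mean accessibility): 0.2166
#>   equilibrium index 0.6195 (bound G = 0.7)
#>   online allocation V:
#>    tert01    tert02    tert03    tert04    tert05    tert06
#> 1121.6714  789.7360  662.0898 1171.8953  821.1680  528.1987
res$profile
#> i2SFCA-TH accessibility profile (13 divisions)
#>   mean 0.2166, min 0.1435, max 0.6108, gap 0.4673, equilibrium index 0.6195
```

Without tele-health the purely offline profile is strongly unequal: the
best-served division scores 0.93 consultation-time units per resident
against 0.043 for the worst, an equilibrium index of 0.91. Shifting 40% of
tertiary physician time online raises the mean accessibility (0.199 →
0.217), more than triples the worst division's index (0.043 → 0.144), and
halves the gap (0.887 → 0.467), bringing the equilibrium index under the
imposed bound of 0.7.

A command-line front end wrapping the same functions lives at
`inst/cli/teleaccess.R`
(`generate | access | optimize | report`, YAML/JSON configs, distinct exit
codes for schema errors and solver infeasibility).

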