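---
title: "Planning safe and adequate food-fortification schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning safe and adequate food-fortification schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortiplan)
```

## The problem

Population vitamin-D intake in northern countries is typically far below the
recommended intake (RI), and food fortification is one of the few strategies
that reaches all population groups, including non-users of supplements. The
design question is which food groups to fortify, and how strongly, so that
*every* sex/age stratum's median intake reaches its RI while nobody's intake
drifts toward the tolerable upper intake level (UL). fortiplan implements an
automated, data-driven answer: a linear program over dietary-survey
aggregates, followed by a full individual-level verification.

## The model

Fortification levels are expressed **per 10 MJ of a food group's energy**
(µg/10 MJ) rather than per mass. Because daily energy intake is roughly
10 MJ for most population groups, a common cap $C$ on all levels bounds the
added intake of even a hypothetical consumer who eats *only* fortified
foods: at total energy $E_{tot}$ the added amount is at most
$C \cdot E_{tot}/10$. Safety is therefore built into the parameterization
rather than checked after the fact.

For stratum $s$ with median background nutrient intake $B_s$ (µg/day, from
the unfortified diet) and median energy intake $E_{s,g}$ (MJ/day) from food
group $g$, the modelled intake under levels $f_g$ is

$$T_s = B_s + \sum_{g} f_g \, E_{s,g} / 10 .$$

The optimization is

$$\min_{f, d} \sum_s d_s \quad \text{s.t.} \quad T_s \ge RI_s,\;
d_s \ge T_s - RI_s,\; 0 \le f_g \le C,$$

with $f_g = 0$ fixed for groups outside the scenario's allow-list. Medians —
not means — feed the model because dietary surveys contain energy
misreporters and strongly skewed food-group intakes; the median is the more
robust location estimate, and no misreporter exclusion is performed.

Three modelling choices deserve comment:

* **Target attainment is a hard constraint.** "Deviation from target" is
  minimized only above the RI; below it, the program is simply infeasible.
  This is what gives the minimum-cap search (`find_min_cap()`) its meaning:
  the smallest cap at which the optimizer can deliver a result at all.
  Feasibility is monotone in the cap, which the tests assert over a sweep.
* **The objective is a linearized "smallest variation in deviation".** With
  hard attainment, deviation equals overshoot, so minimizing the *sum* of
  overshoots (default) or the *maximum* overshoot (`objective_mode =
  "max_overshoot"`) are both faithful linear readings. Both keep the problem
  a pure LP.
* **Alternative optima exist.** Different level vectors can achieve the
  same objective (two groups with proportional energy profiles are
  interchangeable). The solver — the two-phase simplex from the `boot`
  package — is deterministic with a fixed variable order, so results are
  reproducible, but they are one vertex of an optimal face, not a unique
  answer. No secondary lexicographic objective is imposed.

## Units and conversion

The survey pipeline is fixed as: energy kJ/100 g in the food-composition
table, MJ/day in aggregates (`grams × kJ/100g / 100 / 1000`), nutrient
µg/100 g and µg/day. A solved level $f_g$ (µg/10 MJ) becomes a label-ready
concentration via the *population-level* group energy density
$\rho_g$ = (total population energy from $g$, MJ) / (total grams of $g$):

$$\text{level}_{\mu g/100g} = f_g \cdot k_g, \qquad k_g = 10\,\rho_g .$$

Converting per group — not per food — is deliberate: it yields schemes that
are simple to implement. The price is an approximation: for a person whose
within-group item mix is lighter or denser than the population average, the
added intake recomputed from the fortified table differs from the model's
energy-based prediction. `added_intake_comparison()` reports both routes so
the discrepancy is observable; the two agree exactly in population total
(the conversion uses the same population ratio the model sums over), and
the per-person cap bound holds exactly in model space and, on the table
route, with fortified-group energy valued at the population-average density.
An exact per-item conversion would remove the discrepancy but produce a
different concentration for every food in a group.

## Evaluation

A scheme is verified the way it would be audited: the fortified
food-composition table is rebuilt, every individual's intake is recomputed,
and each stratum is summarized by median, P5 and P95. The median is compared
to the RI and the P95 to the UL. Percentiles use linear interpolation
between closest order statistics (`stats::quantile` type 7, the default
convention of R and of mainstream numerical environments) — stated
explicitly because P5/P95 in small strata are sensitive to the convention.
Notches for boxplot export use the standard rule
$\text{median} \pm 1.57 \cdot IQR/\sqrt{n}$.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| RI | 10 µg/day, all strata | common Nordic recommendation; configurable per stratum (e.g. 7.5 µg/day where a lower target applies) |
| UL | 50 µg/day for strata within ages 4–10, 100 µg/day otherwise | standard vitamin-D ULs for children vs adolescents/adults |
| cap $C$ | per scenario (12–30 µg/10 MJ in the bundled examples) | the scenario variable under study |
| strata | 6 age bands (4–6, 7–10, 11–14, 15–17, 18–50, 51–75) × sex | one attainment constraint per stratum; any partition covering the survey range is accepted |
| min-cap grid | start 10, step 1 µg/10 MJ | integer steps match how caps are quoted; `bisection = TRUE` exploits monotone feasibility |
| reporting | integer µg/10 MJ and 3-decimal µg/100 g | label precision; continuous optima stay authoritative, and the integer rounding is re-checked against the targets |

## The synthetic survey generator

Individual records from national surveys are rarely shareable, so the
package ships a generator that emulates one: 3,946 persons by default,
aged 4–75, two sexes, 17 food groups with three items each. Per person and
group, consumption is a Bernoulli gate (group-specific probability
0.5–0.99) times a log-normal amount, reproducing the zero inflation and
right skew that motivate the median-based design. Children's and women's
intakes are scaled (0.70/0.80/0.90/1.00 by age band; 0.85 for women), giving
adult men a median of about 10 MJ/day and children 4–6 about 6–7 MJ/day, with
background vitamin D of a few µg/day dominated by fish, eggs, fats and meat
— round figures in the range of 7-day-record surveys. All draws hang off a
single integer seed, and outputs are rounded to reporting precision so the
CSV files round-trip byte-identically.

What the generator does **not** emulate: day-to-day within-person variance
(records are already 7-day means), correlations between food groups
(e.g. diet patterns), recipe decomposition, item-level consumption
frequency differences within a group, and energy misreporting structure.
Passing tests on synthetic data therefore certify the *mechanics* —
aggregation, optimization, conversion, evaluation — under realistic
marginal distributions, not the numeric levels a specific real survey
would give.

`generate_known_answer_case()` is the sharper instrument: one stratum of
identical persons, one fortifiable carrier group with energy $E$ and a
non-fortifiable background group with intake $B$, so the LP optimum is the
closed form $f^* = 10(RI - B)/E$ exactly. The test suite drives ten random
such cases through the entire pipeline (generator → aggregation → LP →
conversion → fortified table → evaluation) and requires recovery to 1e-6.

## Numerical choices

* Attainment is checked at a tolerance of 1e-6 µg/day; solver pivots use
  the `boot::simplex` default epsilon of 1e-10.
* Grid-oracle cross-checks accept a gap of one grid step times the
  objective's slope ($\sum_{s,g} E_{s,g}/10$), the Lipschitz bound for
  rounding an optimum up onto the grid.
* Ties in the grid oracle resolve to the first enumerated point; the
  enumeration order is fixed.
* Medians of even-sized samples are the mean of the two central order
  statistics (R's convention); stratum medians are always computed from
  person-level values, never by pooling records or averaging medians.
* Groups never consumed get $\rho_g = 0$ with a warning; a *fortified*
  group with $\rho_g = 0$ is an error, since it cannot carry fortificant.
* Empty strata are hard errors, as is any stratum partition that fails to
  cover the survey's sex × age range exactly once.

## Problem sizes in the test suite

Unit and property tests run on an 800-person shared survey; the safety-bound
and acceptance checks regenerate a full 3,946-person survey; the fine
grid-oracle comparison uses a 2-group, 2-stratum instance at 0.01–0.05
µg/10 MJ resolution. The whole suite completes in well under a minute on one
core.

## Known limitations

* 100% of a group's items are fortified; partial market penetration is not
  modelled.
* One nutrient at a time; no joint multi-nutrient optimization.
* The LP stays continuous — selecting *which* groups to fortify under a
  cardinality constraint would need a mixed-integer extension.
* Group-average conversion, as discussed above, is an approximation whose
  per-person error the package reports but does not remove.
* Published aggregate tables can drive the optimizer (via the aggregates
  CSV), but individual-level evaluation requires individual records.
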