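---
title: "An agent-based model of C. elegans colony life history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of C. elegans colony life history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcolony)
```

## The question the model addresses

Wild *Caenorhabditis elegans* live as clonal colonies on small, ephemeral
food patches (rotting fruit or stems). A colony is founded by a single
dispersing larva, booms while the patch lasts, and, as the food runs out,
converts larvae into stress-resistant dauer propagules that disperse and
found new colonies. On this view the relevant unit of fitness is not the
brood size of one worm but the *dauer yield of the colony* — and traits
that look costly to an individual (a short lifespan, a brief reproductive
span, a declining feeding rate) can pay off at the colony level if they
reduce *futile* food consumption: food eaten by post-reproductive adults,
or by larvae doomed to starve before reaching the dauer stage.

`wormcolony` implements a discrete-time, spatially explicit, stage-
structured simulation of one such colony on one patch, plus the experiment
harness needed to map colony fitness across life-history parameters.

## The model

### Stages and the daily cycle

Each worm is in one of six stages: egg (L0), first-stage larva (L1),
arrested L1 (no food), L2, dauer, or adult. Every timepoint (one day) the
whole population passes through five steps in a fixed order:

1. **feed** — each worm attempts an all-or-nothing meal at its grid cell
   (competition within a cell is resolved in a seeded random order);
2. **stage** — the transition table is applied: eggs hatch, fed larvae
   develop (L1 to L2, L2 to adult), starved larvae arrest (L1 to
   L1_arrested, L2 to dauer), fed arrested stages resume development,
   starved arrested stages tick a starvation counter and die at their
   limit (6 days for arrested L1s, 30 for dauers), adults age one day;
3. **survive** — one Bernoulli death draw per worm: eggs never die,
   larvae die at `m_larva` (0.05/day), dauers at `m_dauer` (0.005/day),
   adults at `p_death(age) = 1 - M2^(M1 + age)`;
4. **move** — each worm takes an independent uniform integer step per axis
   in `[-floor(10 s), +floor(10 s)]`, with `s = s_fed` when fed and
   `s = s_hungry` (0.9, i.e. 9 cells/day) when starved, clamped to the
   grid;
5. **reproduce** — each adult lays `max(0, floor(F1 - F2 * age^2.5))`
   eggs at its own cell, clonally; reproduction does not require the
   adult to have fed.

Colony fitness is the cumulative number of distinct individuals that ever
entered the dauer stage by the end of the run (re-entry cannot
double-count because dauers resume only into adulthood). Peak concurrent
dauer number is recorded alongside.

### The eleven genotype parameters

| parameter | meaning | default |
|---|---|---|
| `F1` | progeny on adult day 1 | 50 |
| `F2` | fecundity decline coefficient | 0 |
| `M1` | mortality age offset | 0.5 |
| `M2` | daily survival base; 1 = no aging | 0.99 |
| `m_larva` | daily larval death probability | 0.05 |
| `m_dauer` | daily dauer death probability | 0.005 |
| `s_fed` | movement scale when fed (0.1–0.9 = 1–9 cells/day) | 0.9 |
| `s_hungry` | movement scale when starved | 0.9 |
| `c_adult` | adult meal, food units/day | 1,000 |
| `c_larva` | larval meal, food units/day | 50 |
| `L1s_s` | days an arrested L1 survives without food | 6 |
| `L2s_s` | days a dauer survives without food | 30 |

`make_schedule(F1, span)` encodes curtailed reproductive schedules: it
returns the smallest `F2` for which fecundity is exactly zero from adult
age `span` onwards (`F2 = F1 / span^2.5`); `span = 1` gives the
"reproduction on day 1 only" genotypes and `span = Inf` gives sustained
reproduction. An optional per-age `consumption_schedule` scales the adult
meal; `precipitous_schedule()` models an abrupt feeding shut-off after
adult day 2.

### Age and day-counting conventions

Adult age is 0 on the first adult day, so `fecundity(g, 0) = F1` ("F1
progeny on day 1") and a worm that matures, survives its first death draw
and reproduces does all of that within one timepoint. The engine's death
draws therefore use exponents `M1 + 0, M1 + 1, ...`.

The standalone lifespan estimators (`estimate_mean_lifespan()` and its
closed form `analytic_mean_lifespan()`) default to a slightly different
bookkeeping: the first death draw at exponent `M1 + 1` and the day of
death counted as lived. This is the unique convention that reproduces
*both* reference mean lifespans simultaneously (≈12.06 days at
`M2 = 0.99` and ≈2.41 days at `M2 = 0.80`, with `M1 = 0.5`); counting
from age 0 gives 13.0 and 3.15, and dropping the death day gives 12.0 and
2.15, each matching only one of the two anchors. Both switches
(`age_offset`, `count_death_day`) are explicit arguments and the chosen
convention is echoed in the estimator's output, so the alternative
bookkeepings remain testable.

### The food patch

The patch is a dense `300 x 300` grid holding ~10^6 food units distributed
as an isotropic 2D Gaussian at the centre, rescaled to the exact total.
The Gaussian width is not dictated by the biology, and it matters; the
default is `sigma = 5` cells, chosen on a mechanistic argument: the peak
cell then holds `1e6 / (2 pi sigma^2) ≈ 6,366` units, about 6.4 adult
meals, so that adult feeding — and hence adult–larva food competition,
the heart of the consumer-sacrifice question — can actually operate. A
much wider patch (sigma above ~12) would leave no cell able to serve a
1,000-unit adult meal and adults could never feed at all; sigma = 5 also
keeps more than 99% of the food within a 16-cell radius, a patch small
enough that movement off the food is a real hazard. The flatter/steeper
robustness presets use 2x and 0.5x this width, and `read_grid()` /
`write_grid()` accept any dense CSV grid in place of the generated one.

### Feeding economics

Meals are all-or-nothing: a worm is fed if and only if its cell currently
holds at least its demand, and a fed worm removes exactly its demand, so
a starved adult (demand 1,000) leaves a 999-unit cell intact for the
larvae (demand 50) behind it in that day's randomized order. Eggs demand
nothing and are trivially "fed" — which matters only in that their first
post-hatch move uses the fed speed, keeping newborns on the natal cell in
viscous genotypes. Arrested stages feed like the larvae they are: a fed
L1_arrested or dauer pays one 50-unit larval meal and resumes development
(to L2 and adult respectively). An earlier design in which arrested
stages merely probed the cell without consuming was rejected after it
proved dishonest in the ledger: whole cohorts of arrested L1s could
resume simultaneously off the same unconsumed 50 units and then starve
into dauers, producing dauers that had never eaten — under the current
rule every dauer has paid for at least one meal on its way through L2,
and cumulative consumption plus food remaining equals the initial total
exactly at every timepoint.

### Termination

A run ends when (a) the population is extinct, (b) no cell on the grid
holds enough food for any feeding-capable stage *and* no L2 is alive —
from that point no worm or descendant can ever be fed again, so the dauer
count and food ledgers are provably final and simulating the tail (often
long-lived adults laying doomed eggs for days) would change nothing but
the series length — or (c) the safety cap `t_max` (default 100) is hit,
which is recorded as truncation. A run whose colony died before any
reproduction is flagged *null* and excluded from mean-fitness
aggregation, with the exclusion counted.

## The experiment harness

`scenario()` bundles a genotype template with the sweep grids — by
default the five aging rates `M2 = 0.99, 0.95, 0.90, 0.85, 0.80` (mean
lifespans ~12 down to ~2.4 days; the five printed values are not all
given, so the grid is configurable) and the nine dispersal speeds 1–9
cells/day — plus patch, founder and replicate settings. `run_sweep()`
runs every combination with per-run seeds mixed deterministically from
the base seed and the cell/replicate indices, so replicates are
independent, results are identical under serial or parallel execution,
and a repeated sweep is bit-identical. `heatmap_matrix()` lays the cell
means out as the familiar lifespan-by-dispersal heatmap;
`food_share_series()` and `dauer_fraction()` compute the adult/larval
split of cumulative consumption and the fraction of hatched individuals
that ever reached dauer. `scenario_presets()` ships the named
configurations used in the reference experiments (progeny rates 2–50
without decline, curtailed schedules, day-1-only broods, adult
consumption 50/250/1,000, the feeding shut-off, and the robustness
variants: 3/5/7 founders, 200²/500² grids, 5x and 0.5x patches, flatter
and steeper morphology).

The dauer fraction uses *hatched* individuals (worms that reached L1,
founders included) as its denominator: eggs laid on the final timepoint
never hatch and are not animals.

## What the generator does and does not emulate

The simulated conditions are those of the reference study: a single L1
founder, one genotype per patch, no males or genotype competition, no
mutation or selection, no food regrowth, and no effect of starvation on
adult survival (a starved adult simply eats nothing that day and keeps
laying). Real *C. elegans* colonies differ in ways the model deliberately
ignores — pheromone-mediated dauer induction, density sensing, partial
meals, egg retention under starvation, and multi-patch metapopulation
dynamics among them — so passing tests show that the implementation
reproduces the model's documented behaviour, not that the model captures
field biology.

Two behavioural notes from working with the implementation, both visible
in the sweep outputs. First, at the high-viscosity/fast-aging corner the
two headline genotypes behave as in the reference experiments (a day-1
burst of 50 progeny out-yields sustained 50/day, ~6.4k dauers at the
optimum, with a much larger fraction of hatchlings reaching dauer).
Second, in this implementation colony yield keeps rising toward high
dispersal at high fecundity: a fed L2 that moves off the food converts to
a dauer after roughly two larval meals, so emigration interrupts the
expensive L2-to-adult step and raises conversion efficiency. The
reference landscape instead peaks at dispersal 1 at high fecundity; the
published description of feeding and movement leaves no parameter that
reproduces that damping (patch width, egg flags and arrest economics were
each examined), so the discrepancy is reported rather than papered over,
and grid-maximum statistics should be read with it in mind.

## Problem sizes and numerics

The test suite and the acceptance script run the full 45-cell sweeps at
20 replicates per cell (the reference used 100) and restrict the
criterion checks to the optimal heatmap region where appropriate; the
Monte-Carlo lifespan checks use the reference's 5,000 trials. Grid cells
are stored as doubles and conservation is asserted to 1e-9 relative;
stage bookkeeping uses integer vectors throughout. All randomness flows
from a single seed per run through R's generator; the within-day feeding
order is the only place where ordering matters, and it is drawn from that
same stream.

```{r example, eval = FALSE}
g <- genotype(F1 = 50, F2 = 50, M2 = 0.80, s_fed = 0.1)
run <- run_colony(g, seed = 42)
run$summary$fitness          # cumulative dauer yield
dauer_fraction(run)          # fraction of hatchlings that reached dauer

sw <- run_sweep(scenario(genotype(F1 = 50, F2 = 50), base_seed = 1),
                replicates = 20)
heatmap_matrix(sw)
```
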