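---
title: "Comparing survey, GSM and GPS mobility measures on a synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing survey, GSM and GPS mobility measures on a synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobitriad)
```

## The problem

Pandemic-era mobility research drew on three families of measures: survey
self-reports of how often people left home and why; mobile-network (GSM) data
summarising how far devices physically moved; and GPS/location-history
place-visit indices published as percent changes from a pre-pandemic baseline.
They differ in construct (frequency of leaving home vs. absolute displacement
vs. visits-and-duration at place types), in error structure (recall and
desirability bias vs. tower-resolution coarseness vs. opt-in coverage), and in
scale. The empirical finding that their *relative changes over time*
nonetheless agree closely rests on data that are largely proprietary, so the
comparison itself cannot be re-run at will.

`mobitriad` rebuilds the comparison as a simulation study. One latent
behavioural process generates ground-truth trips; three observation models
turn those trips into channel-native data; a harmonization layer converts each
channel to baseline-relative weekly changes matched to survey waves; and a
comparison layer quantifies agreement. Because the latent process is known,
every step has a recoverable target.

## The latent mobility model

For person $i$ in age group $g$, day $t$, and activity category
$c \in \{$work, sports, friends, medicine, food, non-food shopping, pets,
boredom, other$\}$, the daily trip count is

$$N_{ict} \sim \text{Poisson}(\lambda_{ict}), \qquad
\log \lambda_{ict} = \log r_{cg} + \beta_c S(t) + a\cos\!\big(2\pi(d_t - 196)/365\big) + \varepsilon_{it},$$

with $S(t) \in [0,100]$ a piecewise-constant policy stringency index,
$\beta_c \le 0$ the category's log-rate response per stringency point, $d_t$
the day of year (the cosine peaks in mid-July, giving the summer mobility
peak), and $\varepsilon_{it} \sim N(0, \sigma)$ a day-level shock shared
across categories within a person-day.

Defaults (`default_latent_model()`) were chosen once as a plausible
pre-pandemic activity mix and are the package's study conditions, not tuning
dials:

* base rates sum to about 2.7 trips/person/day (work 0.55 — employed persons
  only —, food 0.50, pets 0.35, friends 0.35, non-food 0.30, sports 0.25,
  boredom 0.20, other 0.15, medicine 0.08), with age multipliers (younger:
  more sports/friends/boredom; older: more medicine, no work effect beyond
  employment);
* stringency responses make discretionary mobility elastic
  (non-food $-0.020$, friends $-0.018$, boredom $-0.015$) and essential
  mobility inelastic (food $-0.003$, medicine and pets $-0.002$); at $S = 85$
  (hard lockdown) non-food shopping falls to $e^{-1.7} \approx 18\%$ of its
  base rate while food barely moves — the familiar retail-vs-grocery pattern;
* trip distances are lognormal per category (km; e.g. median 2 km for food,
  5 km for visiting friends); employed persons' work trips go to a fixed
  per-person workplace drawn at a lognormal commute distance (median 8 km);
* stay durations are fixed per category (hours; work 8, friends 2.5, food 1),
  capped at 22 h/day in total so a home stay always remains;
* seasonal amplitude 0.15 and day-noise SD 0.15 on the log scale.

Each day is tiled 00:00–24:00: trips get non-overlapping slots whose free time
is split into home stays by random stick-breaking, so time weights are
well-defined and sum-checkable. Coordinates are planar km on a synthetic grid
— exact Euclidean geometry makes the radius-of-gyration oracles analytic
(haversine mode exists for real lon/lat input). Each person has their own RNG
substream keyed on `(seed, person_id)`, so output is bit-reproducible and
independent of processing order or population subsetting.

## The three observation channels

**GSM.** Every covered person (default coverage 0.7) is one device. Within
each stay, communication events arrive as a Poisson process (default 1/h —
data communications dominate event counts in modern networks) and are located
at the nearest node of a 0.75 km tower grid. An event's dwell weight is the
time until the device's next event that day (the last event keeps its weight
until midnight): a device "stays" at a tower until re-observed. The device-day
statistic is the time-weighted radius of gyration; because its distribution is
heavily right-skewed, daily aggregates are medians over devices, taken within
age × gender subgroups first and combined with target population shares
afterwards (device-level attributes exist only as group labels in real GSM
deliveries, so weights enter as subgroup shares; shares are the product of the
independent margins). Single-event device-days are kept (ROG 0): no
minimum-event filter is imposed. The robustness measure is the share of
devices with ROG strictly above 500 m ("more than" read as strict).

**GPS.** Each opted-in person's (default opt-in 0.6) stays become place visits
in six categories via a fixed activity→place map (food/medicine → grocery &
pharmacy, non-food and friends → retail & recreation, work → workplaces,
sports/pets/boredom → parks, other → transit, home → residential). The daily
measure blends the two public readings of "visits and length of stay":
$\alpha \cdot \text{count} + (1-\alpha) \cdot \text{duration}$ with
$\alpha = 0.5$ by default ($\alpha$ is a declared free parameter; the upstream
definition is undocumented). The baseline is the per-category, per-day-of-week
median over the five weeks 2020-01-03 to 2020-02-06, and daily values are
reported as $100(v - b)/b$. The composite index is the plain sum of the six
percent changes; whether residential should enter with reversed sign is not
derivable from the index's literal definition, so inversion is a flag
(default off). Any missing component makes the composite missing rather than
silently rescaling the sum. The CMR CSV dialect is read and written
bit-faithfully, including empty cells.

**Survey.** A 22-wave panel (waves 1–10 weekly, 11–14 bi-weekly, 15–22 every
four weeks; wave 1 = 2020-03-23 to 2020-03-29) asks nine 5-point frequency
items. The true quantity per item is the number of days (0–7) in the field
week with at least one trip in the category; the response model adds Gaussian
recall noise (SD 0.7 days), maps counts to codes via
$\{0\}\to0,\ \{1\}\to1,\ \{2,3\}\to2,\ \{4,5,6\}\to3,\ \{7\}\to4$
(0 = "never", 4 = "daily"; the intermediate labels are a declared convention
centralised in one function), subtracts an optional social-desirability shift
(optionally stringency-dependent; not applied to the stay-home item, where
staying home is the desirable direction), clamps to 0–4, and injects item
nonresponse (1%) and wave-over-wave attrition (4%) with replacement
refreshment from never-sampled persons so wave sizes stay roughly constant.
Analysis filters mirror standard practice: drop the 75+ age group, then
listwise-delete responses with any missing item, logging both counts. The
mobility index is the sum of the nine codes (0–36), with subindices
food+medicine (0–8), non-food (0–4) and work (0–4) matching the GPS categories
grocery & pharmacy, retail & recreation and workplaces.

## Weighting

Survey waves are raked (iterative proportional fitting on unit weights) to the
population margins for age group, gender and region, in that fixed order —
IPF limits are order-independent at convergence, but iteration counts are not,
so a fixed order keeps logs reproducible. Convergence requires every weighted
margin within $10^{-6}$ of target (default; max 100 cycles), weights are
normalized to mean 1, and optional trimming clamps then renormalizes (off by
default, since trimming can reopen small margin gaps). Marginal raking rather
than full poststratification cells is deliberate: joint population counts are
not used. Infeasible targets (positive target on an empty sample level) and
non-convergence are errors, the latter carrying the worst margin gap.

## Harmonization

All channels are reduced to ISO Monday-start weeks (the wave-1 field week
2020-03-23 is a Monday, so field weeks are clean ISO weeks). Weekly levels are
means of available daily values; weeks with fewer than 4 days are treated as
missing (guards against one-day edge weeks; the threshold is configurable).
Relative change is $100(v_t - v_b)/v_b$ against the baseline week, which
therefore maps to exactly 0; a missing or zero baseline is an error naming the
channel and subgroup. For the GPS channel the level entering this second
anchoring is the day-of-week-adjusted index $100 + \text{pct}$ (equivalently
$100\,v/b$ per baseline cell): the raw percent change is negative during the
baseline lockdown week, and a ratio-scale transform needs a positive level;
$100+\text{pct}$ is exactly proportional to the underlying visit measure after
removing the weekday profile. Changing the baseline week $b'$ relates the two
relative-change series by
$r' = 100\big((1 + r/100)/(1 + r_{b'}/100) - 1\big)$, which the tests assert
numerically. A centered 7-day moving average (edges missing) is available as a
smoothing toggle; weekly averages use all seven ISO-week days, not field-period
days only (a stated convention).

## Comparison layer

Wave-matched relative changes are compared by Pearson correlation with
two-sided p-values from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df (22 waves
is small, so the t transform matters; $|r| = 1$ reports $p = 0$), and by OLS
trend lines whose slope measures relative variation strength (slope 1 =
channels move 1:1). The time-fixed-effects regression puts wave indicators
next to channel, subgroup and channel × subgroup terms, with reference levels
(first channel/subgroup/wave) as the rank-reduction convention; interaction
coefficients quantify between-channel subgroup differences net of the common
trend, and rank deficiency is an error listing aliased terms. The DiD
estimator is the two-group, two-period cell-means contrast, with its standard
error taken from the interaction term of the equivalent `value ~ group*period`
OLS (the two are identical to $10^{-10}$, asserted on random panels). Wave
aggregates are treated as fixed observations — no within-wave sampling
uncertainty is propagated — and no autocorrelation-robust errors are computed,
matching the aggregate-level analysis the pipeline emulates.

In the end-to-end pipeline the lockdown DiD uses non-food shopping (treated)
versus food & medicine (control) around the 2020-11-03 partial lockdown, for
the survey and GPS channels — the category pair with the sharpest expected
differential response, and the only pair observed by two channels (GSM has no
category dimension). The window is ±8 weeks so that two monthly waves fall on
each side.

## Default study conditions and problem sizes

The default configuration simulates 500 persons over 62 ISO weeks
(2019-12-30 to 2021-03-07), covering the GPS baseline window and all 22 waves,
with a stringency profile shaped like Austria's 2020–21 course (first
lockdown mid-March, stepwise summer re-opening, November/December lockdowns).
The survey panel is 300 persons per wave. One full run takes about a minute on
one CPU and is byte-reproducible under a fixed seed. Recovery studies use
deliberately small designs: the correlation study simulates 22-wave trend
pairs directly (200 replicates); the DiD study uses 30 persons × 4 weeks per
replicate with a stringency jump of 50 points at $\beta = -0.02$, so the true
multiplier is $e^{-1}$ and the true effect on the relative-change scale is
$100(e^{-1}-1) \approx -63.2$.

## Numerical choices

Quota rounding uses the largest-remainder method with ties broken by position.
The ROG implementation short-circuits single-tower device-days to exactly 0
(the two-pass formula would otherwise leave $O(10^{-16})$ floating-point
residue, breaking the "zero iff one tower" equivalence). Baseline medians with
even counts use the mean of the central order statistics. Empty aggregation
cells propagate as missing, never as 0. Raking tolerance $10^{-6}$, IPF oracle
comparisons at $10^{-6}$, ROG oracle at $10^{-9}$, analytic ROG cases at
$10^{-12}$, DiD/OLS equivalence at $10^{-10}$.

## What the generator does and does not emulate

It emulates: one shared latent process observed by three error-prone channels;
stringency-driven, category-specific mobility collapse; seasonal shape;
GSM positional coarseness and event sparsity; GPS opt-in subsampling and the
CMR percent-change construction; survey recall noise, desirability shift,
item nonresponse, attrition with refreshment, and quota composition.

It does not emulate: real geography, road networks or gravity-model
destination choice; household structure; weekday/weekend activity profiles
(the CMR day-of-week baseline machinery is exercised, but the synthetic
weekday profile is flat); differential-privacy noise in published CMR data;
multi-SIM devices or roaming; quota recruitment mechanics or panel
conditioning; regional stringency variation (one national index drives
everyone). Passing tests therefore show that the estimators recover known
effects under the stated error models — they do not certify any particular
real-world dataset.

## Known limitations

Correlations between channels observing the same latent process on the same
simulated persons share sampling noise; the pipeline's cross-channel
correlations are accordingly optimistic relative to independent-sample
settings. The GSM weighting assumes independence of the age and gender margins
when forming subgroup shares. The DiD standard error comes from a tiny OLS
(two waves per cell at monthly cadence) and should be read as descriptive.
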