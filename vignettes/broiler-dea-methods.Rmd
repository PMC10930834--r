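---
title: "Benchmarking broiler production with DEA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking broiler production with DEA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilerDEA)
```

## The problem

Integrated broiler producers are paid by performance: the agro-industry
records, per closed batch, the number of birds housed, the days to
slaughter, the feed delivered, the mortality and the total live weight,
and prices the batch through indices built on them. A batch's *technical
efficiency* asks a sharper question than any single index: given what every
other producer achieved, could this batch have produced its weight with
proportionally less of every input? Data Envelopment Analysis (DEA) answers
it nonparametrically, by enveloping the observed input-output points with a
piecewise-linear frontier and measuring each unit's radial distance to it.

This package analyses decision-making units (DMUs) described by five inputs
-- housed birds, age at slaughter (days), feed consumed, mortality
(a fraction), unit cost (currency per kg) -- and one output, the total
available weight. Feed and weight must share a mass unit; in the packaged
reference dataset of 31 batches ([`broiler_batches()`]) that unit is the
tonne, the only reading under which the dataset's feed conversion ratios
(~1.5 kg feed per kg live weight) are coherent. Including the unit cost
among the inputs is what distinguishes this analysis from a purely
zootechnical one: two batches with identical growth curves can differ in
the working capital they consumed.

## The efficiency models

For unit $o$ with inputs $x_o \in \mathbb{R}^n_{>0}$ and outputs
$y_o \in \mathbb{R}^m_{>0}$, the input-oriented envelopment problem under
constant returns to scale (the CCR model) is

$$\theta_o^* \;=\; \min_{\theta,\lambda \ge 0}
\Bigl\{\, \theta \;:\; \textstyle\sum_k \lambda_k x_k \le \theta x_o,\;
\sum_k \lambda_k y_k \ge y_o \Bigr\},$$

the largest proportional input contraction still producible by some
nonnegative combination of observed units. The variable-returns (BCC)
model adds the convexity constraint $\sum_k \lambda_k = 1$, so each unit is
compared only against units of comparable scale; BCC scores therefore
dominate CCR scores ("frontier nesting"). Output orientation expands
outputs at fixed inputs, giving a factor $\varphi \ge 1$; the package
reports $1/\varphi$ so that all published scores live in $(0, 1]$. Under
constant returns the input- and output-oriented scores coincide exactly,
which the test suite asserts on every dataset it touches.

The dual (multiplier) form prices the variables: it seeks nonnegative
virtual weights $\mu$ (outputs) and $v$ (inputs) with $v'x_o = 1$
maximising $\mu'y_o$ subject to $\mu'y_k - v'x_k \le 0$ for every unit
$k$ (plus a sign-free scale term under BCC). `dea()` solves it alongside
the envelopment form and returns the weights; they are generally not
unique at optimum and are reported as one optimal choice, not asserted
against in reproduction tests.

### The non-Archimedean epsilon

The classical multiplier formulation bounds all weights below by an
infinitesimal $\varepsilon$ to rule out weakly efficient optima. An
explicit small constant distorts scores at roughly its own magnitude, so
the package's default realisation is the standard two-phase scheme: phase
1 computes the radial factor exactly, phase 2 maximises the slack sum at
that fixed factor. Radial scores are then exactly
$\varepsilon$-independent, which is what published DEA score tables
report. `dea_model(epsilon = "explicit", eps_value = 1e-6)` provides the
explicit mode for comparability with desktop DEA tools; on the reference
dataset the two modes agree to about $2\times10^{-6}$, consistent with
the chosen $\varepsilon$.

### Inverted frontier and composite ranking

Efficiency-1 units are not discriminated by the standard frontier, and a
unit can be "efficient" merely by being extreme. The double-frontier
device re-runs the same model on the table with input and output roles
exchanged ([`invert_dmu_table()`]); a score of 1 there marks *worst*
observed practice. [`composite_efficiency()`] combines both sides:

$$\text{composed} = \frac{\text{standard} + (1 - \text{inverted})}{2},
\qquad
\text{composed}^* = \frac{\text{composed}}{\max_k \text{composed}_k},$$

and ranks by composed\* descending (ties by ascending id). The composed
formula is the convention of the SIAD family of DEA tools; it is verified
arithmetically against the reference results in the test suite. A unit on
both frontiers scores composed 0.5 and is flagged `ambiguous`: the
composite ranking cannot tell whether its extremity is a virtue.

## The zootechnical panel

[`zootech_indicators()`] derives the industry's batch indicators:
viability $= 100(1-\text{mortality})$ (%), feed conversion ratio
$\mathrm{FCR} = \text{feed}/\text{weight}$ (dimensionless, lower is
better), daily weight gain in g/bird/day computed over *surviving* birds,

$$\mathrm{DWG} = \frac{\text{weight} \times s}
{\text{housing}\,(1-\text{mortality})\,\text{age}},$$

with $s$ the factor converting the weight unit to grams (default $10^6$,
i.e. tonnes), and the European production efficiency factor

$$\mathrm{PEF} = \frac{\text{viability} \times \mathrm{DWG}}
{10 \times \mathrm{FCR}}.$$

Two conventions deserve a note. The surviving-bird denominator in DWG is
the one under which the reference dataset's published per-batch gains are
recovered (dividing by housed birds understates individual growth when
mortality differs across batches). And the PEF combination above is the
standard European formula; the reference study describes its index only
as a weighted combination of the same three indicators, so agreement is
asserted at 1% rather than exactly. [`gap_report()`] turns the panel into
an improvement agenda: direction-aware signed gaps to a chosen benchmark
unit (which must lie on the standard frontier), ordered by composite rank.

## Numerical choices

* **LP engine.** Envelopment and multiplier problems are solved by a
  package-internal dense two-phase primal simplex with Bland's
  anti-cycling rule. DEA LPs are small but systematically degenerate at
  efficient units (several basis variables sit at zero), which is exactly
  where off-the-shelf educational simplex routines fail; the engine pivots
  artificial variables out explicitly and drops redundant rows. It is
  cross-checked in the tests against an exhaustive dual-vertex-enumeration
  oracle on small instances and against planted-frontier constructions
  with analytically known scores.
* **Conditioning.** Columns are divided by their means before LP assembly
  (housing ~ $10^6$ birds against cost ~ 4 currency units would otherwise
  span six orders of magnitude in one basis). DEA scores are invariant to
  positive column scalings; the tests bound the drift under deliberate
  rescalings at $10^{-9}$.
* **Tolerances.** Pivot tolerance $10^{-9}$ on mean-scaled data;
  "efficient" means score $\ge 1 - 10^{-6}$; benchmark peers are intensities
  above $10^{-6}$.
* **Degenerate inputs.** Tables need at least 2 units; correlations need 3
  and no constant column; mortality must lie strictly inside (0, 1); a
  feed conversion outside (0.5, 5) warns of a likely unit mismatch.

## The simulators

[`simulate_farms()`] generates tables with the reference data's structure:
log-normal housing (mean 513,000 birds, CV 56%), truncated-normal age
(42 ± 1 days on [40, 45]), mortality as a scaled Beta(2, 4) on
(3%, 9.2%) (mean ~5.1%), per-bird daily gain N(72, 3) g/day, feed
conversion N(1.55, 0.05), and cost N(4.33, 0.10) tied negatively to the
batch's PEF (correlation strength configurable). Weight and feed are built
structurally from these, which reproduces the near-collinearity of
housing, feed and weight that the real data show. One explicit integer
seed governs all draws and the global RNG state is restored afterwards.

What the simulator does *not* emulate: cost-size economies (real unit
costs fall with scale; simulated cost depends only on PEF, so the
simulated cost-weight correlation is near zero rather than mildly
negative), seasonal and health-shock dynamics, and correlated mortality
across batches of one producer. Tests passing on simulated tables
therefore validate the algebra and the solver, not the economics of any
particular farm population.

[`planted_frontier()`] is the solver's validation harness. Efficient units
are drawn on a common supporting hyperplane $u'y = v'x\,(+\,w)$ with
strictly positive prices $u, v$; every convex (CRS: conic) combination of
them stays on that hyperplane, and an inefficient unit built by inflating
such a combination's inputs by $1/\theta$ has input-oriented score exactly
$\theta$: any deeper contraction $t < \theta$ would give
$u'y_o \le \sum_k \lambda_k u'y_k = \sum_k \lambda_k v'x_k
\le t\, v'x_o < \theta v'x_o = u'y_o$, a contradiction. Recovery of the
planted scores is asserted at $10^{-5}$ over 50 seeded instances of 10
efficient plus 20 inefficient units with 3 inputs -- sizes chosen to
exercise many random bases while keeping the default check fast.

## Reproducing the published 31-batch analysis, and its limits

The packaged dataset reproduces the published study's findings: exactly
two batches (4 and 23) span the constant-returns frontier, nine display
1.00 under variable returns at 2 decimals, batch 31 anchors the
anti-frontier (inverted score 1), and the composite ranking runs from
batch 4 down to batch 31.

One reproducibility bound must be stated honestly. The dataset is printed
with rounded cells (feed and weight as integers, age and mortality at 2
decimals), while the original analysis ran on unrounded source records.
Scores computed from the printed table therefore differ from the published
ones by up to about $2\times10^{-3}$ -- enough to flip 4 of the 124
two-decimal score cells (batches 3 and 31 under constant returns) and to
preclude six-decimal agreement with the published double-frontier table;
the same propagation puts one printed viability (batch 17), one feed
conversion (batch 7, by 0.0002) and one PEF (batch 7, by 0.03%) just
outside their nominal bands. The acceptance tests assert the published
precision anyway and let those rows fail visibly rather than widen the
bands; everything else -- frontier memberships, rankings, statistics,
correlations, indicators -- reproduces at the stated precision. Two
further quirks of the published tables are handled explicitly: batch 11's
normalized composed score is internally inconsistent (its composed score
divided by the maximum gives 0.9259, not the printed 0.8259 -- and the
published indicator-panel ordering follows 0.9259), so it is excluded
from the six-decimal comparison; and the published variable-summary table
uses the population (divisor $n$) standard deviation, which is why
`descriptive_stats()` defaults to that convention.

Finally, the usual DEA caveat: efficiency is *relative to the sample*. A
unit efficient among these 31 batches may be dominated in a larger pool,
and the scores say nothing about welfare, biosecurity or environmental
externalities, which are outside the variable set.
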