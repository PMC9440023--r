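---
title: "Delphi consensus statistics and boundary-value screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delphi consensus statistics and boundary-value screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphiScreen)
```

## The procedure

A Delphi consultation for indicator-system construction sends the same
questionnaire to an anonymous expert panel over successive rounds. Each
expert scores the importance of every tertiary indicator of a three-tier
hierarchy on a bounded integer scale, self-rates their familiarity with the
topic on a six-point ladder, and self-rates the four bases of their judgment
(practical experience, theoretical analysis, understanding of peers,
insight). Between rounds the organisers compute consensus statistics, screen
indicators with the boundary-value method, discuss borderline cases with the
panel, and revise the hierarchy; the consultation closes once coordination
is sufficient.

`delphi_round()` runs one round's pipeline in a fixed order — engagement,
authority, concentration, coordination, screening — and returns a classed
object holding every intermediate table. The package deliberately follows
the classic R modelling idiom as far as the subject allows: one central
analysis function returning an S3 object with `print`, `summary` and `plot`
methods, base-R internals throughout. There is no formula/`predict`
interface because nothing is being fitted to covariates; `generate_panel()`
plays the simulation role instead.

### Engagement

The positive coefficient of a round is the questionnaire recovery rate,
$100\,r/d$ for $r$ returned of $d$ distributed. It proxies the panel's
engagement; 70% is the conventional adequacy gate (`response_rate()` flags
it, nothing is auto-enforced).

### Authority

For one expert and indicator, the familiarity coefficient $C_s$ is the
coefficient mapped from the six-point ladder
($1, 0.8, 0.6, 0.4, 0.2, 0$ from very familiar down to unfamiliar), and the
judgment coefficient $C_a$ sums one impact coefficient per judgment basis,
selected by the self-rated band of that basis:

```{r}
judgment_basis_matrix()
```

The row sums give the anchor points: an expert rating every basis high has
$C_a = 1$, every basis mid $0.8$, every basis low $0.6$. Per indicator,
$C_s$ and $C_a$ are unweighted means over the responding experts — the only
aggregation consistent with "average familiarity of the consultants" — and
the authority coefficient is $C_r = (C_a + C_s)/2$, with $C_r \ge 0.7$ read
as acceptable reliability. Band counts (`authority_band_counts()`) use
strict outer comparisons ($C_r > 0.75$, $C_r < 0.5$); this choice reproduces
the 29/22/3 and 8/36/2 splits of the bundled reference tables exactly, which
is the evidence that the published counts used strict comparisons too.

A panel-level $C_r$ (the unweighted mean of per-indicator $C_r$) is reported
in the round summary for orientation only. How published studies aggregate
their single panel-level authority number (over indicators, experts or
rounds) is typically unstated, so no exact-match test is attached to it.

### Concentration

Per indicator $j$ scored by $m_j$ experts with scores $C_{ij}$:
$M_j = \frac{1}{m_j}\sum_i C_{ij}$, full-score frequency
$K_j = m'_j / m_j$ with $m'_j$ the number awarding the maximum score, and
coefficient of variation $V_j = \delta_j / M_j$. Missing scores are excluded
indicator-wise ($m_j$ is per indicator), matching the definition of $m_j$ as
the number participating in that indicator's evaluation.

### Coordination

Kendall's $W$ is computed from descending average ranks (most important =
rank 1; $W$ is invariant to the direction, which is fixed only so
intermediate output is reproducible) with the standard tie correction:

$$W = \frac{12\,S}{m^2(n^3 - n) - m\sum_i T_i}, \qquad
  T_i = \sum_g (t_g^3 - t_g),$$

where $S$ is the sum of squared deviations of the indicator rank sums from
their mean and $t_g$ the sizes of expert $i$'s tie groups. Significance uses
$\chi^2 = m(n-1)W$ on $n-1$ df — the approximation behind the usual
"$P < 0.001$" statements; a permutation test is available via
`panel_config(permutation_test = TRUE)` for small panels, off by default.
Whether to pool all active indicators into one ranking or test per tier is a
genuinely open choice; the default ranks all active indicators jointly
(`boundary_grouping` does not affect $W$), since the closing rule is stated
for the consultation as a whole.

### Boundary-value screening

Across the indicators of a grouping, each criterion gets a retention
threshold from its own cross-indicator distribution: $\bar{M} - s_M$ for
$M_j$, $\bar{K} - s_K$ for $K_j$ (keep above), $\bar{V} + s_V$ for $V_j$
(keep below). The phrase "higher/lower than the boundary" is taken
literally: comparisons are strict, so a value exactly at its boundary fails
that criterion. Failing all three criteria means elimination; one or two,
expert discussion; none, retention.

Two consequences are worth spelling out. First, the degenerate case: if all
indicators have identical statistics, every boundary equals the common value
and everything fails by strictness — a group that carries no information
cannot rank its members, and the all-fail outcome surfaces that loudly
rather than silently retaining everything. Groups with fewer than two
indicators skip screening with a warning (no sd exists). Second, the screen
only proposes: `apply_review()` requires an explicit panel decision for
every review item (or, with `unresolved = "keep"`, treats an absent entry as
"reviewed and kept", the convention when a published edit log records only
changes), and expert edits may override the statistics in either direction —
flagged `expert-override` in the audit column, because real panels do delete
statistically acceptable indicators on substantive grounds.

Boundary grouping defaults to global across all active indicators in the
round; per-tier grouping is available (`boundary_grouping = "per_tier"`) for
panels whose tiers live on different scales.

### Rounds and the edit log

`advance_hierarchy()` replays a structured edit log (`delete`, `add`,
`rename`, `move`, `keep`) onto the hierarchy, stamping `origin_round` on
additions and refusing to delete a parent whose children stay active.
Deleted nodes are kept with status `deleted` so the evolution is fully
auditable: replaying the log always reproduces the next round's hierarchy
exactly, and rerunning `final_report()` on identical inputs writes
byte-identical files (fixed ordering by hierarchy position then id, fixed
half-up rounding, no hidden randomness).

## Numerical choices

- **Importance scale.** The reference consultation never states its
  importance scale; printed means up to 9.15 rule out 1–5, which is read as
  describing the familiarity/judgment self-ratings instead. The default is
  0–10 with full score 10, configurable via `panel_config()`.
- **Standard deviations** use the sample ($n-1$) denominator by default,
  configurable to $n$; printed tables cannot discriminate the two without
  raw scores, and the same setting is applied to the per-indicator
  dispersion and the boundary computation for coherence.
- **Display rounding** is half-up (not R's banker's rounding): $M_j$, sd,
  $V_j$ and $K_j$% at 2 decimals, $C_s$/$C_a$/$C_r$ at 3 — the convention
  of the published tables, and required to reproduce rows such as
  $C_r = (0.920 + 0.927)/2 = 0.9235 \to 0.924$. Internal values are never
  rounded; rounding happens only at the write/report boundary.
- **Zero mean.** $V_j$ is undefined at $M_j = 0$ (possible when the scale
  starts at 0); such indicators are flagged rather than given a value.
- **Ties in $W$.** Average ranks with the exact tie-correction term; without
  ties the formula reduces to $12S/(m^2(n^3-n))$, which is tested.

## The synthetic panel

`generate_panel()` emulates the study conditions of a two-round burn-model
consultation: 15 experts (7 clinical medicine, 8 animal research; 5/8/2
across the experience bands; 10 associate professors, 5 professors — the
per-expert assignment is constructed to match these marginals, which is all
the published characteristics table determines), an 8/16/54 hierarchy, and
2 experts lost in round 2 (a 13/15 = 86.67% round-2 return; the two
dropouts are clinical-medicine experts with 15–30 years, one of each title,
the unique composition consistent with the round-2 marginals).

Scores are $C_{ij} = \mathrm{clip}(\mathrm{round}(\mu_j + \varepsilon_{ij}))$
with $\varepsilon \sim N(0, \sigma^2)$ i.i.d.; $\sigma = 2$ by default, a
typical per-expert spread on a 0–10 importance scale given the reference
tables' printed sds of roughly 1–3. True importances $\mu_j$ default to an
even spread over $[2, 10]$, giving distinctly ordered indicators spanning
the range the reference tables show. Familiarity levels and judgment bands
are drawn i.i.d. from configurable marginals whose defaults put most mass on
the familiar/mid-to-high end, landing $C_s$ and $C_a$ in the ranges the
reference tables print. Two optional mechanisms: a shifted-binomial noise
mode (integer, tie-heavy — exercises the tie correction), and a full-score
affinity bonus that adds probability of scoring exactly full when $\mu_j$ is
within 2 points of the top, because rounded Gaussian noise under-produces
full marks at high $\mu$; both default off.

What the generator does **not** model: expert anchoring or confirmation-bias
dynamics across rounds (round-2 scores are fresh draws around the same
truth), correlation between an expert's familiarity and the accuracy of
their scores, systematic severity differences between experts, and any
dependence between indicators. Passing tests therefore demonstrate that the
statistics, screen and bookkeeping behave correctly under a clean
independence model — not that real panels satisfy that model.

`recovery_check()` closes the loop: with $\sigma = 0$ the pipeline recovers
$\mu$ exactly and $W = 1$; under noise, mean importance recovers planted
truths within the $3\sigma/\sqrt{m}$ standard-error bound, deliberately
low-importance indicators fail the $M_j$ criterion, and mean $W$ decreases
in $\sigma$ — all verified in the test suite at fixed seeds (200 replicates
per noise level in the acceptance suite; smaller panels elsewhere to keep
the default run fast).

## Reference data and its known faults

The bundled tables are transcriptions of printed per-indicator summaries,
with their faults preserved and documented rather than corrected: the
round-1 $K_j$ column duplicates the $M_j$ column (typesetting fault — the
package always recomputes $K_j$ from scores and never consumes that column),
one round-2 $K_j$ cell (28.46) is not $k/13$ for any integer $k$, and a
handful of printed derived cells differ in the last printed digit from what
their own row's inputs give — the inevitable artifact of recomputing a ratio
from 2-decimal inputs. Round-trip identities in the tests always refer to
values at the configured rounding.

Published round-level quantities that require the raw per-expert scores
(the study's $W$ of 0.435/0.530, its panel $C_r$ of 0.73/0.67, and its
exact 11-indicator deletion set, which involved expert discussion) cannot be
recomputed from printed tables; the property-based synthetic checks above
stand in for them.

## Limitations

- The pipeline treats rounds independently; it reports the closing rule
  ($W > 0.5$) but never auto-enforces it, and supports any number of rounds.
- Experts are unweighted everywhere; weighting by title or experience is out
  of scope.
- Free-text expert comments appear only as the structured edit log; no text
  processing is attempted.
- The problem sizes in the test suite (panels of 15 × 54 and smaller,
  hundreds of Monte-Carlo replicates) were chosen to make the full suite run
  in well under a minute while keeping binomial/standard-error tolerances
  tight.
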