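# delphiScreen

Consensus statistics and boundary-value indicator screening for multi-round
Delphi expert consultations.

Delphi studies build evaluation index systems — for example the three-tier
indicator hierarchy used to standardise how a rat third-degree-burn model is
constructed and assessed — by sending the same questionnaire to an anonymous
expert panel over several rounds and screening the indicators statistically
between rounds. `delphiScreen` implements the full quantitative side of that
procedure for panels scoring hierarchical indicators on a bounded integer
scale:

- **Engagement.** The positive coefficient of a round is the questionnaire
  recovery rate, `100 × returned / distributed`; ≥ 70% counts as good.
- **Authority.** Each expert's familiarity self-rating maps to a coefficient
  *Cs* ∈ {1, 0.8, 0.6, 0.4, 0.2, 0}; their four judgment-basis self-ratings
  (practical experience, theoretical analysis, understanding of peers,
  insight) map through a 3-band × 4-basis impact table to a judgment
  coefficient *Ca* (all-high = 1, all-mid = 0.8, all-low = 0.6). The
  authority coefficient of an indicator is *Cr = (Ca + Cs) / 2*, averaged
  over its respondents; *Cr* ≥ 0.7 is acceptable reliability.
- **Concentration.** Per indicator *j* with *m<sub>j</sub>* respondents:
  mean importance *M<sub>j</sub> = (1/m<sub>j</sub>) Σ C<sub>ij</sub>*,
  full-score frequency *K<sub>j</sub> = m′<sub>j</sub>/m<sub>j</sub>* (the
  fraction awarding full marks) and coefficient of variation
  *V<sub>j</sub> = δ<sub>j</sub>/M<sub>j</sub>*.
- **Coordination.** Tie-corrected Kendall's
  *W = 12S / (m²(n³−n) − m ΣT<sub>i</sub>)* over the expert × indicator rank
  matrix, tested with *χ² = m(n−1)W* on *n−1* df. *W* > 0.4 reads as fair
  coordination, *W* > 0.5 as sufficient to close the consultation.
- **Boundary-value screening.** Across indicators, the retention threshold is
  `mean − sd` for *M<sub>j</sub>* and *K<sub>j</sub>* (keep strictly above)
  and `mean + sd` for *V<sub>j</sub>* (keep strictly below). An indicator
  failing all three is eliminated; failing one or two goes to expert
  discussion, recorded in an auditable edit log that advances the hierarchy
  to the next round.
- **Synthetic panels.** A seeded generator emulates a 15-expert panel scoring
  an 8/16/54 hierarchy with controllable noise, round-2 dropout and
  self-rating distributions, so every stage is testable end to end.

The package also ships a transcribed reference dataset: the per-indicator
tables of a published two-round consultation on rat third-degree-burn model
indicators (54 tertiary indicators in round 1, 46 in round 2) plus its
hierarchy and review edit log.

## Worked example

```r
library(delphiScreen)

# a seeded synthetic consultation: 15 experts, 8/16/54 hierarchy, sigma = 2
panel <- generate_panel(panel_sim_config(seed = 42))
r1 <- delphi_round(panel$rounds[[1]], panel$hierarchy)
r1
#> Delphi round 1: 15/15 returned (100.00%, good)
#>   54 indicators; panel Cr 0.766; bands >0.75/mid/<0.50 = 37/17/0
#>   Kendall's W 0.619 (chi2 491.9, df 53, p < 0.001)
#>   screening: 41 retain, 13 review, 0 delete
```

Every questionnaire came back (engagement good), the panel's mean authority
coefficient 0.766 clears the 0.7 reliability gate, W = 0.619 > 0.5 says the
expert rankings agree well enough to close, and the boundary screen retains
41 indicators outright while sending 13 to expert discussion (none fails all
three criteria). `summary(r1)` lists the boundaries and the flagged
indicators; `plot(r1)` draws the M–V scatter against the boundary lines.

The bundled reference tables reproduce their published summaries:

```r
s1 <- burn_example_stats(1)
authority_band_counts((s1$Cs + s1$Ca) / 2)
#>   above between   below
#>      29      22       3

advance_hierarchy(burn_example_hierarchy(), burn_example_edits())
#> Indicator hierarchy (round 2): 8 primary / 14 secondary / 46 tertiary active
#>   (11 deleted nodes retained for audit)
```

— 29 round-1 indicators carry authority above 0.75 and 3 fall below 0.5, and
replaying the panel's review edits (11 deletions, one addition, one rename,
one re-parenting) turns the initial 8/16/54 system into the final 8/14/46
index system.

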