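---
title: "Methods: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yawnscope)
```

`yawnscope` turns raw behavioral event tables from video-sampled primate
groups into the standard quantitative results of a yawning study: yawn-morph
discovery from FACS action units, dominance indices, context-dependent
duration and morph models, state-change slot analyses, and yawn-contagion
attribution. This vignette is the package's own account of the models it
fits, the conventions it fixes where field practice is silent, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind.

## Time conventions

Every within-session time is seconds from session start; the absolute clock
time of an event is the session's start clock plus that offset. All
intervals are half-open, `[start, end)`. Frame-coded data are effectively
continuous (0.02 s resolution), so which side of a boundary is closed is
arbitrary — but it must be fixed once, because three downstream rules
depend on it:

* **Daytime bins.** Five 2-h bins over the 08:00–18:00 observation day,
  each `[lower, upper)`. An event at exactly 10:00:00 is in `10-12`.
  Events in the trailing 18:00–18:30 stretch belong to no bin (`NA`,
  reason `after_bins`); outside 08:00–18:30 they are rejected.
* **Tension tail.** The tension context spans an aggressive interaction and
  the 180 s after its end, `[agg_start, agg_end + 180)`. A yawn starting
  exactly 180 s after the end is *not* tension.
* **Shift windows.** A posture transition at time `t` counts for the window
  `[a, b)` iff `a <= t < b`. Consequently a transition exactly at the yawn
  onset t~0~ is credited to the *post*-yawn half of the Y slot, and a
  transition exactly at a window's end never double-counts into it.

Where tension and resting windows overlap, tension wins: an aggressive
interaction is directly observable, whereas the resting/sleeping
classification is an inference from posture. Witnessing an aggression is an
input annotation (a per-event witness list), not something recomputed from
the tables — it is an observational judgement made at coding time.

## Morph discovery

AU configurations are sets over a fixed 12-code vocabulary; `AU25+26` (jaw
drop) and `AU25+27` (mouth stretch) are mutually exclusive and exactly one
of them is present in any codable yawn. One-hot encoding expands each code
into a present and an absent dummy (24 columns, row sums 12).

Two separate steps operate on that matrix, deliberately not chained:

1. `project_mixed_pca()` — correspondence analysis of the indicator matrix
   (the all-categorical special case of principal component analysis of
   mixed data), computed by SVD of the standardized residuals
   `D_r^{-1/2}(P - rc')D_c^{-1/2}`. It is used for the 2-D visualization
   and variance fractions only.
2. `cluster_kmeans()` — k-means with k = 2 on the one-hot matrix itself
   (10 restarts under a fixed seed), never on the MCA scores.

Purity is the best of the two cluster-to-label mappings, in percent. When
any AU is present in 100% of one a-priori morph and 0% of the other — true
of six codes in the reference sample — the two morphs occupy disjoint
orthants of the dummy space and purity is forced to 100% for every seed;
a green purity test therefore establishes correct plumbing, not a
discriminative achievement. The per-AU contrasts use the two-sided Fisher
exact test with the mainstream convention (sum of hypergeometric
probabilities not exceeding the observed table's, with a 1e-7 relative tie
guard). The reference fixture (`fixture_table3()`) reconstructs only the
published per-morph *marginal* counts; joint AU co-occurrence was never
published, so free AUs are assigned independently by a seeded draw and the
2-D variance fractions of the projection are not comparable to the
originally reported ones.

## Dominance

`adi()` implements the Average Dominance Index: per subject, the unweighted
mean over *interacting* opponents of the proportion of that dyad's decided
conflicts won. Dyads with no decided conflicts are excluded from the mean
(that exclusion is the point of the ADI relative to score-based indices in
sparse matrices), and subjects with no interacting opponent — infants,
typically — get `NA`, which propagates into the model datasets and excludes
those rows. Contact and no-contact decided events count equally by default;
`intensity = "contact"` restricts the matrix if wanted.

## State-change slots

Only spontaneous yawns with one visibility interval covering
`[t0 − 90, t0 + 90)` enter the slot analysis, so C1 and C2 always exist and
the three slots partition that 3-min window exactly. The baseline minute is
drawn on the same subject and calendar date: a 60-s block *starting* in the
same posture state as at t~0~ (it may run on into other states — that is
precisely a baseline shift), containing no yawn by the subject, and not
overlapping any of the subject's C1/Y/C2 slot sets that day. The last
restriction is stricter than a bare "absence of yawning" but keeps the four
conditions disjoint. Candidates sit on a 1-s grid; among several, one is
drawn uniformly under a caller-supplied seed, so baseline selection is
reproducible. Yawns whose slot sets overlap a neighboring yawn's slots are
retained but flagged (`overlap_flags`). t~0~ is the yawn's *onset* (lips
first parted); the slot definition only requires that the yawn event lie
inside Y, and onset is the only timestamp available for every yawn.

Shift shares (`summarize_shift_shares`) are reported rounded *and*
truncated alongside the exact percentage, because printed integer shares in
the literature are not consistent about the rounding rule and the two
disagree for some counts.

## Contagion attribution

For each annotated exposure (trigger yawn, receiver, seen/not-seen), a
response is a receiver yawn in `(t_trigger, t_trigger + 180]`. Every
receiver yawn inside a *seen* trigger's window is labeled `response` and
leaves the spontaneous pool; with overlapping windows the earliest seen
trigger claims the yawn. Attribution is chained by default (`chain = TRUE`):
a response yawn can trigger further responses, with chain depth recorded.
Receivers not followable for the full window who showed no response are
dropped as `censored`; yawns inside the window of a trigger with unknown
seen status become `unassigned`. The three labels partition the yawn set,
and attribution is idempotent and order-invariant. Note one asymmetry that
is a property of observational designs, not a bug: a receiver's yawn inside
a *not-seen* window still makes that exposure record a "response = yes"
observation (the receiver did yawn within 3 min), while the yawn itself
stays spontaneous — only perception reassigns status.

## Inference

All mixed models are fit by maximum likelihood (never REML), so the
full-vs-control likelihood-ratio tests on fixed effects are valid; Gaussian
responses use `lmer`, binomial ones `glmer`. Each stage pairs a full model
with a control model (random intercept plus the control covariates only)
and reports `2(l_full − l_control)` against the chi-square with the
parameter-count difference. Degenerate covariates (single level after row
exclusion, common at reduced scale) are pruned from both formulas rather
than crashing the fit. Collinearity is summarized with generalized VIFs
from the correlation matrix of the fixed-effect model matrix — a specific
variant choice, documented here because mixed-model VIFs are not uniquely
defined. Variance explained is reported as the marginal/conditional
decomposition with distribution-specific residual variance (σ² for
Gaussian, π²/3 on the logit scale).

`tukey_pairwise()` computes all pairwise contrasts of a fixed factor from
the coefficient vector and its covariance, and applies the single-step
familywise adjustment: the adjusted p of contrast *i* is
`1 − P(max_j |Z_j| < |z_i|)` under the joint null with the exact contrast
correlation matrix, evaluated by quasi-Monte-Carlo multivariate-normal
integration (degrees of freedom treated as infinite, the convention for
binomial mixed models). On balanced designs this reproduces the
studentized-range probabilities to better than 1e-6, at the price of a few
seconds per factor; `fit_stage(..., tukey = FALSE)` skips it.

**Limitation worth knowing.** With the field-typical ~10 subjects, tested
fixed effects that vary only *between* subjects (sex, ADI) have an
anticonservative chi-square reference: in null simulations of the duration
design with 10 clusters we measured 9–11% rejection at nominal 5%,
regardless of the number of observations. The package's type-I acceptance
audit therefore uses 40 cluster levels, where the reference is accurate
(measured 5.6%). Substantive conclusions about between-subject effects at
real group sizes deserve extra caution.

## The synthetic world

`generate_bundle()` emulates a 13-member zoo group — 2 adult males, 2 adult
females, 7 juveniles, 2 infants — observed in short sessions across the
08:00–18:00 day. Defaults were chosen once, from the published summary
structure or, where nothing is published, from what a field ethologist
would call realistic; they are never tuned against test outcomes:

| Parameter | Default | Basis |
|---|---|---|
| yawn rate per h | adult ♂ 2.5, adult ♀ 0.3, juvenile 0.25, infant 0.05 | adult males dominate the published per-subject counts |
| morph log-odds (UCT) | male +1.1, female offset −1.7 | male-skewed uncovered-teeth odds |
| log-duration | μ = 1.0, β~female~ = −0.32, β~UCT~ = +0.24, σ = 0.35 | reported sex and morph effects on log duration |
| per-morph AU probabilities | reference marginal rates | published per-AU percentages |
| shift hazard multiplier | 6 in the 30 s after a yawn | strong published Y-vs-C1 contrast |
| contagion | p₀ = 0.05, p₁ = 0.25, latency ~ Exp(17 s) truncated to (0, 180] | reported not-seen/seen rates and mean latency |
| seen probability | 0.52 | seen share of exposure records |
| posture dwell means | lying 300 s, sitting 180 s, standing 120 s, walking 90 s | unpublished; plausible captive budget |
| aggression | 2/h group-wide, p(decided) = 0.9, p(higher rank wins) = 0.85 | unpublished; sparse-but-decisive hierarchy |
| receivers per trigger | 2 | see below |
| yawns inside lying bouts | 60% | see below |

Two structural choices deserve their rationale. First, exposures are
emitted for a small sampled subgroup of receivers per trigger rather than
all ten non-infant group mates: with ten annotated receivers the contagion
branching factor (receivers × response probability) exceeds one and
response chains explode, which contradicts the scale of any observed
dataset; opportunistic focal-subgroup filming also means only a few animals
are followable per trigger. Second, 60% of spontaneous yawns are placed
inside lying bouts: yawning concentrates in drowsy resting phases, and
without this the majority of yawns would fall in unclassifiable contexts,
starving the context covariate that every published model includes.

Posture dynamics are a four-state semi-Markov chain with exponential dwell
times; the post-yawn hazard boost is implemented as an extra forced
transition in `(t0, t0 + 30]` with probability
`1 − exp(−(m − 1)·λ_state·30)`, which matches an `m`-fold hazard
multiplier over that window. Seen/not-seen is an independent Bernoulli per
exposure — no enclosure geometry, no gaze model. The generator does *not*
emulate: temperature or any thermoregulatory covariate, observer presence
effects, kinship structure, within-morph AU co-occurrence (free AUs are
independent), or realistic visibility geometry (a single random gap per
subject-session). A green end-to-end test therefore establishes that the
pipeline recovers the encoded effect *signs* from data with this
structure — not that the generator is a behavioral model of any real
group, nor that published coefficient values are reproduced (the raw
per-event data behind those are not available, and their exact
reproduction is explicitly out of scope).

## Reproducibility notes

Everything stochastic takes an explicit seed (`generate_bundle`,
`cluster_kmeans`, `select_baseline`, `fixture_table3`,
`simulate_coder_pair`) and restores the caller's RNG state, so identical
(config, seed) pairs give byte-identical bundles and pipelines are
replayable. Test-suite simulation sweeps run at documented reduced scale
(observation effort down, effect parameters untouched). The acceptance
report (`scripts/acceptance.R`) recomputes its target from scratch at run
time: it reconstructs the 64-event reference fixture under the given seed,
one-hot encodes it, clusters with k = 2 over ten seeds and reports the mean
best-mapping purity.
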