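---
title: "Integrating self-report and psychophysiological message tests with MADM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating self-report and psychophysiological message tests with MADM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madmsg)
```

## The problem

Formative testing of health-risk messages — here, twelve messages warning
young adults about waterpipe (hookah) tobacco smoking — typically produces
two kinds of evidence that do not arrive on a common scale. A crowdsourced
survey arm yields self-reported receptivity, engagement, positive attitude,
and negative emotional response; a laboratory arm yields psychophysiological
indices of message processing: heart-rate deceleration (cognitive resources
allocated to encoding), recognition-memory hit rate (encoding into short-term
memory), and eye-tracking dwell time on areas of interest (visual attention).
Campaign designers must nevertheless pick a handful of messages.

`madmsg` implements a multi-attribute decision-making (MADM) integration of
the two arms. Each message is a row of a decision matrix, each measured
construct a column, each cell the construct's mean score for that message.
Within each attribute, messages are ranked; ranks are then combined under
explicit weighting scenarios into summary scores, and messages that stay in
the top half under *every* scenario form the consensus selection. The method
deliberately performs no hypothesis testing: it is a transparent ordering
and aggregation device for decision support, not an inferential model.

## Ranking and aggregation

**Competition ranking.** Within an attribute, the best mean receives rank 1
and tied means share the *minimum* rank of their group, with the next
distinct value skipping ahead by the group size (1, 2, 2, 4). The rank of
message $m$ on attribute $a$ is

$$ r_{ma} = 1 + \#\{m' : x_{m'a} \succ x_{ma}\}, $$

where $\succ$ is "strictly better" in the attribute's direction. All seven
bundled attributes are higher-is-better, including negative emotion: under
fear-appeal logic a message that evokes stronger worry is the more effective
risk message. Direction is nevertheless configurable per attribute for
reuse. Ties are detected by exact numeric equality — appropriate for means
read from a published table, where intended ties are digit-identical; means
computed from raw data at full precision tie only when genuinely equal.

**Study totals.** Within each arm the attribute ranks are summed per message,
and the sums are themselves competition-ranked (smaller sum = better).

**Weighting scenarios.** A scenario is a list of components — individual
attribute ranks or study-total ranks — with nonnegative weights. The summary
score of message $m$ is the weighted mean of its component rank values,
so it always lies in $[1, n]$ for $n$ messages, and scenario ranks are
competition ranks of the summary scores (ties flagged, rendered as `*`).
The four standard presets are: equal attribute weights (all 7 attribute
ranks), equal study weights (the 2 study-total ranks), prefer self-report
(4 self-report attribute ranks + the lab total rank), and prefer lab
(the self-report total rank + 3 lab attribute ranks). Summary scores are
computed in full precision and only *displayed* rounded (one decimal for
the first three presets, two for prefer-lab, following the bundled study's
presentation); ranking never uses rounded values.

**Consensus.** `consensus_top_half()` keeps the messages whose rank is at
most $\lfloor n/2 \rfloor$ in every supplied scenario. On the bundled
matrix this yields exactly five messages (HF2, HS2, H2, H1, A1).

**Weight sensitivity.** Four fixed scenarios are points in a simplex of
possible weightings. `weight_sweep()` samples weight vectors uniformly on
the simplex over all attribute ranks (exponential spacings, i.e. a flat
Dirichlet) and reports each message's frequency of attaining rank 1, ties
counting as wins for all tied messages. It is deterministic given its seed.

## The published-total reproduction mode

The bundled study's printed lab total-rank column does not equal the
competition rank of its printed lab rank sums: AF1 holds the smallest lab
sum (7) yet is printed as lab rank 2, and the printed column coincides,
message for message, with the visual-attention rank column. The printed
scenario table demonstrably uses that printed column wherever a scenario
consumes the lab study-total rank. Whether this was intent or a transcription
slip cannot be settled from the publication, so the package takes no side:
by default `study_totals()` ranks the sums (the stated method), and
`run_scenarios(..., published_total_ranks = )` accepts explicit published
columns so the printed table is reproduced bit-for-bit. Both paths are
under test; `reproduce_tables()` uses the override and verifies every
published score, rank, and tie flag.

```{r repro, eval = FALSE}
rep <- reproduce_tables()   # errors if any published cell disagrees
rep$consensus
```

## Scoring the two arms

**Self-report.** Four constructs with fixed item counts and bounds:
receptivity (9 items, 1–7), engagement (3, 1–7), positive attitude
(9 semantic differentials, 1–7), negative emotion (4, 1–4). A participant's
construct score is the plain item mean; per-message attribute means average
those scores across participants, with the standard error using the sample
(n−1) standard deviation — the conventional reading where a published table
prints "Mean (SE)" without definition. Records with missing or out-of-range
items are **rejected, not prorated or clamped**: silent proration would move
means invisibly, and out-of-range values signal upstream data corruption
rather than usable signal. Cronbach's alpha is provided as the standard
internal-consistency quality check,
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$.

**Heart rate.** The package consumes per-second BPM traces plus the last
pre-message baseline second (raw ECG processing is upstream). The change
score subtracts the baseline from each exposure second, takes absolute
values, and averages across the exposure — in that order. Because the
absolute value precedes averaging, seconds of *acceleration* also raise the
score; with planted decelerations of 1.5–3 BPM and ~1 BPM per-second noise
the induced upward bias is only a few hundredths of a BPM at 3 BPM but
grows as the true deceleration approaches the noise floor. Traces of
unequal length are scored over however many seconds they contain and then
averaged across participants unweighted, matching a design in which every
participant contributes one trace per message.

**Recognition.** Hit rate over target fragments only; foils never enter the
proportion. Hits are aggregated per participant first and then averaged
across participants — identical to pooling when every participant kept the
same number of targets, and robust to dropped trials otherwise. The task
assumes 2 targets per message (24 targets + 24 foils = 48 fragments), the
only allocation consistent with the published task description.

**Visual attention.** Three AOI dwells (sentence 1, sentence 2, hashtag)
are averaged within a record, then across participants, in absolute
milliseconds. An AOI without any recorded fixation counts as 0 ms — absence
of fixation is informative non-attention, and dropping such AOIs would bias
dwell upward — and each substitution is reported.

## The synthetic cohort generator

No participant-level data are deposited for the bundled study, so the
generator exists to exercise the full pipeline end-to-end with known truth.
Defaults mirror the study conditions: 713 crowdsourced participants, each
rating one message (balanced assignment); 120 lab participants, each viewing
all twelve.

*Self-report.* Items are a participant-level latent construct value
(planted mean + normal participant effect) plus independent normal item
noise, rounded to integer scale points and clipped to the bounds. The two
variance components are derived from interpretable targets: the construct's
published alpha (0.92 / 0.94 / 0.94 / 0.91) via the Spearman-Brown relation
$r = \alpha / (k - (k-1)\alpha)$, and a between-participant construct-score
SD (1.31 / 1.16 / 1.47 / 0.89) consistent with the published standard
errors at ~59 participants per message. Discretization produces realistic
ceiling effects: observable means are attenuated toward the scale interior,
by about 0.08 at a planted 5.29 on a 7-point scale.
`planted_observable_mean()` returns the exact expectation of the
discretized, clipped item, and is the correct target for parameter-recovery
checks on discretized cohorts; `discretize = FALSE` yields continuous items
for exact noise-free pipeline checks.

*Lab.* One resting baseline per participant (N(72, 8) BPM, floored at 40);
per-message exposure of 15 s (a configurable default; the study does not
publish durations) at baseline − planted deceleration − participant trait
(SD 0.4) + per-second noise (SD 1). Recognition responses are Bernoulli
draws at the planted hit probability, foils at a 0.2 false-alarm rate
(foils affect nothing downstream; the rate only makes the task realistic).
A `deterministic_recognition` mode instead allocates `round(p × trials)`
hits so noise-free runs reproduce planted orderings to within the trial
resolution. Dwell-record means are lognormal with mean equal to the planted
value and SD 770 ms — matching the published dwell SDs of roughly 750–800 ms
and the strictly positive, right-skewed shape of real dwell times — spread
over the three AOIs with 100 ms jitter. One root seed derives independent
per-arm streams, so either arm regenerates reproducibly on its own.

*What the generator does not emulate:* response styles and inattentive
responders in the survey arm, autocorrelated cardiac dynamics (per-second
noise is i.i.d.), gaze-measurement loss, within-person correlation of
recognition across messages, dropout, and demographic structure. Passing
recovery tests therefore demonstrates pipeline correctness under a clean
generative model, not robustness to every pathology of real data.

## Numerical and testing choices

- **Problem sizes.** Parameter-recovery tests run at 5 000 participants per
  arm, where three-standard-error bands are tight enough to expose scoring
  mistakes in any attribute. Rank-ordering recovery uses 6 000 survey and
  2 000 lab participants with planted means that follow the published
  attribute *orderings* (ties preserved) at gaps of at least ~3.5 estimator
  SDs: under the realistic default noise the published means themselves are
  not resolvable at feasible cohort sizes (adjacent dwell means sit 0.78 ms
  apart against a ~17 ms standard error), so ordering recovery is tested
  where ordering is identifiable. Convergence is additionally checked
  against a 50-participant cohort on the same seed.
- **Degenerate inputs.** Empty item sets, zero target trials, zero total
  variance (alpha), non-positive BPM, and missing decision-matrix cells all
  raise typed errors naming the offending construct, message, or cell;
  single-participant summaries return an `NA` standard error rather than 0.
- **Determinism.** Every stochastic entry point (generators, weight sweep)
  takes an explicit seed and restores the caller's RNG state.

## Limitations

The MADM integration inherits the method's scope: it orders messages, it
does not test whether their differences exceed sampling error, and a rank
gap of one can reflect a mean gap of 0.01. The consensus rule is sensitive
to the chosen scenario set. The absolute-value heart-rate score conflates
acceleration with deceleration by construction. And the bundled per-message
means are inputs reproduced from a published table, not recomputable from
raw data within this package.
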