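---
title: "Models and methods: play faces, mimicry and sequential play structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: play faces, mimicry and sequential play structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playmimicry)
```

## The data model

Everything in this package operates on a long-format event log: one row per
event, where an event is either a **behavioral pattern** (a timed play act
by one player, possibly directed at the partner) or a **facial expression**
(a play face, PF, or full play face, FPF, with onset and offset). Sessions
are dyadic; times are seconds from session start, 0-based, with ties broken
by file order. The session end is taken as the latest event time or
expression offset, because the log format carries no explicit end marker —
in practice the last recorded act closes the session.

Patterns are classified by an **ethogram** into *offensive* (attack-like
acts toward the partner), *defensive* (avoidance/protection) and *neutral*
(neither, including solitary acrobatics). The packaged gorilla ethogram has
41 entries; the directed play jump is offensive while its solitary form
(`play jump solo`) is a separate neutral entry, and the two play-face
entries are carried as neutral patterns so a single catalog validates full
logs. Pattern matching is case-insensitive after trimming, and the ethogram
is the single source of category truth: a pattern's category is always
looked up, never trusted from the input file.

## Rapid facial mimicry

A stimulus is any expression one player emits toward the partner; it counts
as **replicated** when the partner emits an expression of the *same* type
(exact facial matching) with onset strictly after the stimulus onset and at
most `window_s = 1` s later. Onset-to-onset latency is used because onset
is the only frame-anchored instant the duration coding defines; the window
boundary is inclusive. Pairing is greedy earliest-first and a partner
expression answers at most one stimulus. An expression consumed as a
response keeps its own stimulus record (it may itself be answered) but is
flagged `is_response`, and such records are excluded from the contingency
table, the mimicry levels, the mixed-model design table and the focal-event
list — a response is not a *first* stimulus.

Perception is an annotation, not a computation: frontal or lateral view of
the responder counts as perceived, the blind area as not perceived, and
doubtful cases stay `unknown` and are discarded from analysis. The
perception-by-replication table is tested with a Yates-corrected 2×2
chi-square; the model-based route builds a design table (binary response,
binary perception, group code, trigger–responder dyad id) and delegates the
binomial mixed-model fit with dyad random intercept entirely to `lme4`,
with the full model compared to a random-factors-only null by likelihood
ratio. The package owns the design-table contract, not the estimation.

## Sequential indices

For two players A and B and a window of patterns,

$$\mathrm{PAI} = \frac{(\mathrm{off}_{A\to B} + \mathrm{def}_{B\to A}) -
(\mathrm{off}_{B\to A} + \mathrm{def}_{A\to B})}
{\mathrm{off} + \mathrm{def} + \mathrm{neutral}} \in [-1, 1],$$

where the denominator counts *every* pattern in the window, solitary and
neutral included. The index is antisymmetric under player relabeling, so an
orientation convention is required: by default player A is the **session
initiator** (the first pattern-performer). The orientation is configurable
(`"as_recorded"`) and recorded in the output, since group comparisons of
magnitudes do not depend on it but before/after means do.

Play variability is the natural-log Shannon index over pattern *names*
(not categories), $H' = -\sum_i p_i \ln p_i$, bounded by $\ln k$ for $k$
distinct patterns. For the worked five-pattern session with counts 3/1/1
the index is 0.9503.

Windows are cut around **focal events** — unreplicated expressions
(`PF_not_mim`, `FPF_not_mim`) and mimicry events (`PF_RFM`, `FPF_RFM`,
anchored at the stimulus onset): the `k = 4` patterns strictly before and
strictly after the onset. Consecutive focal events are both used only when
at least `2k + min_separation = 12` patterns lie between them, so the two
windows never share patterns and at least four separate them; a too-close
event is skipped and spacing is measured from the last retained one. Events
with an empty side yield no window pair and are dropped *before* the
spacing chain is applied — a design choice the windowing rule leaves open;
dropping them first means an unusable event cannot block a usable
successor. Sides with one to three patterns are kept short rather than
discarded, which preserves sample size while keeping both indices defined.

## Session conditions and durations

Each session gets exactly one label: mimicry of both types
(`PF_and_FPF_RFM`), of FPF only, of PF only, at least two unreplicated PFs
with no FPF at all (`PF_not_mim`), the symmetric FPF case, or `excluded`
(no expressions, single unmimicked expressions, or ambiguous sessions
mixing unreplicated PFs and FPFs). **Time remaining** is the span from the
first qualifying event — the first unreplicated expression for the
not-mimicked conditions, the first mimicry stimulus for the mimicry
conditions — to session end. The midpoint flag codes whether the first
mimicry stimulus fell strictly before half the session duration (ties
conservatively to "after"; they are measure-zero in real data).

One artifact deserves emphasis. Under the first-mimicry time origin, the
conditions are *selection-defined*: even with no causal effect of mimicry
on termination, the first mimicry event sits later in a session than the
first of several unmimicked expressions, so time-remaining distributions
differ across conditions under a pure null. `classify_condition()`
therefore exposes `first_event = "first_expression"`, which anchors all
conditions at the first expression of any kind and makes the origins
comparable; the default stays at the first mimicry stimulus because the
scientific comparison targets mimicry's effect. Calibration checks of the
randomization test itself are run on exchangeable synthetic groups, where
nominal size is well-defined.

## The statistical toolbox

All tests return one-row tibbles with `tidy()`/`glance()` methods and the
field's reporting conventions:

- `yates_chi2()`: $\chi^2 = N(\max(|ad-bc| - N/2,\, 0))^2/(r_1 r_2 c_1
  c_2)$, df = 1. The correction is clamped at zero so near-independent
  tables cannot gain spurious association.
- `wilcoxon_exact()`: zero differences are dropped and reported as the
  `ties` count; absolute differences are midranked and `T` is the smaller
  signed-rank sum. For up to 25 nonzero pairs the p-value is exact — the
  null distribution is built by convolution over doubled ranks, which
  enumerates all $2^m$ sign assignments and handles midrank ties exactly;
  beyond that, a normal approximation with tie and continuity corrections
  takes over. The two-sided p sums both tails of the (symmetric) null.
- `kruskal_wallis_mc()`: tie-corrected H on pooled midranks with a
  Monte-Carlo randomization p using the add-one estimator
  $(1 + \#\{H^* \ge H\})/(1 + B)$, default $B = 10000$; the p-value can
  never be exactly 0 and the seed is recorded, so a fixed seed gives a
  bit-identical p. Degenerate all-equal input returns H = 0, p = 1.
- `dunn_bonferroni()`: pairwise mean-rank differences on the pooled
  ranking, tie-corrected z, and p multiplied by the number of pairs, capped
  at 1; both the raw difference and z are reported because published
  post-hoc "Q" values are sometimes one, sometimes the other.
- `paired_t()`, `binomial_exact()` (two-sided by summing outcomes no more
  likely than the observed one), `cohens_kappa()` (unavailable when
  expected agreement is 1) and `duration_ioa()` (mean of per-trial
  smaller/larger duration ratios, in percent) follow their closed forms.

Every implementation is cross-checked in the test suite against an
independent oracle: full enumeration over sign vectors and group
assignments at small n, and the corresponding base-R tests
(`chisq.test`, `wilcox.test`, `kruskal.test`, `t.test`, `binom.test`)
where their conventions coincide.

## Action units

FACS-style binary configurations are summarised by presence frequency: an
AU is "always or almost always present" when it appears in at least 80% of
an expression's configurations (threshold 1.0 gives exactly the
intersection). OpenFace-style per-frame intensity tables are reduced to one
record per clip; the default aggregator is the per-AU **maximum** — the
expression's apex — with mean and median available because the reduction
used in published analyses is typically unstated. Across clips of one
subject the per-expression **median** is used, and each AU is compared
between PF and FPF across subjects with the exact signed-rank test at a
Bonferroni threshold of `alpha_family / n_AUs` (0.005 for 10 AUs at 0.05).

## The synthetic generator

`simulate_play()` builds sessions pattern by pattern with known ground
truth. Its defaults are fixed to the study conditions the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| mean inter-pattern gap | 2.75 s | with the hazard below, baseline sessions average ≈43 s (observed play sessions average 42.8 s, range 5–405 s) |
| termination hazard | 0.06 per pattern | geometric session length ≈17 patterns |
| expression rate | 0.8 per player per minute | ≈1.1 expressions per session, matching ≈1150 expressions over ≈1000 sessions |
| FPF fraction | 0.72 | FPFs outnumber PFs roughly 830:320 |
| p(perceived) | 0.7 | pooled perceived fraction of printed stimulus counts |
| p(replicate \| perceived / not) | 0.45 / 0.12 | replication levels of the printed contingency tables |
| hazard multiplier after first mimicry | 0.4 | effects-on condition for the prolongation analysis |
| offense bias after unmimicked FPF | 0.3 for 4 patterns | effects-on condition for the asymmetry analysis |
| diversity boost after unmimicked PF | uniform draw for 4 patterns | effects-on condition for the variability analysis |
| pattern concentration | Dirichlet 0.15 | sessions reuse a small favorite repertoire, so windows sit at H′ ≈ 0.6–1.0 as real windows do |

Post-event effect windows last exactly four patterns so that recovery of
the injected effects is a direct test of the windowing rule. The offense
bias is directed toward the session *initiator* — necessary because the
sequential PAI is initiator-oriented, so a bias toward a random player
would cancel in the mean. Perception is drawn independently per stimulus
(no head-pose geometry), replication latency is uniform on (0, 1] s, and
expression durations are uniform on [0.5, 4] s (they matter only to
duration statistics). `null_params()` switches every effect off for
type-I-error suites. Identical parameters and seed yield byte-identical
logs.

What the generator does *not* emulate: the demographic structure of real
groups (ages, kinship, per-individual session counts), unbalanced dyad
participation, within-session non-stationarity beyond the injected
four-pattern effects, and annotation noise in perception coding. Passing
recovery tests therefore show that the pipeline detects the stated effects
when they are present in data of this shape and size — not that real
gorilla data contain them.

## Numerical choices and problem sizes

Exact signed-rank enumeration switches to the normal approximation above 25
nonzero pairs; permutation p-values use the add-one estimator; Yates and
Dunn statistics carry tie corrections on midranks; midpoint ties code 0;
window ties at the focal onset belong to neither side. The validation
suite runs the full pipeline on 100 replicates of 500 sessions for effect
recovery, 500 exchangeable replicates for randomization-test calibration,
1000 random windows for index bounds and antisymmetry, and full
enumeration oracles at up to eight pairs / nine pooled observations —
sizes chosen so the whole suite completes in a few minutes on one core
while keeping Monte-Carlo error well below the tested margins.

## Known limitations

- The per-individual session counts in the packaged composition table sum
  to the dataset total although sessions are dyadic; the counting
  convention of the source table is not documented, and the table is used
  as printed.
- The mixed-model stage requires `lme4` and inherits its convergence
  behavior on sparse dyads (singular fits are possible and reported as
  such).
- Accidental mimicry is possible in generated data (two independent
  expressions within a second); detection-side proportions therefore sit a
  fraction of a percent above the generating probabilities at realistic
  rates.
- By default the Monte-Carlo tests shuffle observations freely; the
  published analyses' randomization scheme for repeated individuals across
  dyads is unspecified, so `kruskal_wallis_mc()` exposes an optional
  `strata` argument (within-dyad permutation) rather than guessing one.
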