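---
title: "Methods: simulating and analysing perceptual crossing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing perceptual crossing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrossing)
```

## The paradigm

In the perceptual crossing paradigm two people interact through a minimal
virtual interface: each moves an invisible "avatar" along a shared
one-dimensional space that wraps around after 600 units, and each receives
only binary tactile feedback — a vibration whenever their avatar overlaps
any object. Three objects can be encountered by a player: the partner's
avatar (touching it stimulates *both* players, because the partner's sensor
is co-located with their body), the partner's *shadow* (a lure rigidly
attached 150 units from the partner's avatar, which copies the partner's
motion but carries no sensor, so touching it stimulates only the toucher),
and one *static* object private to each player. All objects are 4 units
long. Players click when they judge that they are in contact with the
partner's avatar; clicking the avatar earns the team a point, any other
click loses one. Trials last one minute and state is recorded every 10 ms.

The scientific interest is in what distinguishes the partner's avatar from
its perfect kinematic copy: only the avatar affords *responsive*
interaction. This package provides (i) a simulator in which scripted agent
controllers stand in for the human players, and (ii) the complete analysis
pipeline for such recordings.

## Environment model and conventions

`env_config()` collects every constant. Choices the analysis depends on:

* **Positions** are continuous reals wrapped to `[0, 600)` at every step;
  there is no spatial grid. `signed_displacement()` returns the
  minimal-magnitude signed offset in `(-L/2, L/2]`, with the tie at exactly
  half the circumference resolved to `+L/2`.
* **Overlap** between two 4-unit objects is declared when the wrapped
  distance between their centres is *strictly* less than the body length,
  so abutting objects do not stimulate. For equal-length segments the
  centre-distance criterion and the segment-intersection criterion
  coincide, so no further convention is needed.
* The **shadow offset** is applied with the same sign (+150) for both
  players. Only relative geometry enters any analysis, but the convention
  is recorded in every trial-log header.
* **Mutual avatar contact** is computed once per step in a fixed
  (player 1, player 2) argument order. Scripted trajectories place
  crossings arbitrarily close to the 4-unit overlap boundary, where the two
  argument orders can differ in the last floating-point bit; a single
  canonical evaluation keeps the mutual-contact channel exactly symmetric
  between the players, as it is physically.

## Contact segmentation

A *contact* is a maximal run of uninterrupted stimulation. Every object
type that overlaps the player at any step of the run contributes to that
contact, and contributes once even if it leaves and re-enters within the
run — one unbroken vibration is a single event from the player's
perspective. `segment_contacts()` implements this; the package ships an
18-step illustrative series (`contact_example()`) whose three runs yield
avatar = 2, static = 2 and shadow = 1 contacts:

```{r}
count_contacts_by_type(contact_example_contacts())
```

## Click-target attribution

A click is attributed by sampling relative positions exactly one second
before the click (clamped to the trial start for earlier clicks; the
behaviour near the start is otherwise unspecified by the paradigm). If the
partner's avatar lies within the inclusive range of ±70 units of wrapped
displacement it is the target; otherwise the partner's shadow is tried,
then the player's own static object; otherwise the click has no
identifiable target. Because 2 × 70 < 150, the avatar and its shadow can
never both be in range, so the only genuine priority decision is that the
avatar or shadow beats a co-occurring static object. Ranges are measured
centre-to-centre.

## Turn-taking

Movement is binarized per step: a step moves when the absolute wrapped
displacement exceeds 0.5 units (an eighth of the body length, strictly).
Players produce micro-pauses inside a single "turn", so a sub-threshold
step becomes a genuine pause only inside a run of at least 50 consecutive
sub-threshold steps (500 ms); shorter gaps remain "moving". Binarization is
applied to the full trial and then windowed, so pause runs are measured on
the whole trajectory rather than being cut by the window.

For two binary series `B1`, `B2` over a window of `T` steps, with
`D = B1 NAND B2`, the active contributions are `C1 = sum(B1 & D)` and
`C2 = sum(B2 & D)` and the turn-taking score is

    TT = 4 * C1 * C2 / T^2 .

By the AM–GM inequality `TT <= 1`, with equality exactly when each player
is the sole mover for half the window; it is 0 when both always move, or
when only one ever moves. `tt_before_click()` scores the 10 s window
preceding a click, half-open at the click step, truncated (with `T` the
actual length) for clicks earlier than 10 s.

## Classification, scoring and rating summaries

A trial is a *Joint Success* when both retained clicks hit the avatar, a
*Single Success* when exactly one does, *WrongOnly* when there are only
wrong clicks, *NoClicks* otherwise. Clicks without an identifiable target
count as wrong for scoring: the published per-team scores are consistent
with that reading, and the package reproduces every printed score from the
corresponding click counts (see `tournament_table()`). Clicking accuracy is
undefined — `NA`, never 0 — for a player who never clicked. Rating tables
normalize the 4-level awareness (PAS) and confidence (CR) scales to unit
mass within each click category, excluding (and separately counting) absent
ratings.

## Variance-gated comparisons

Group comparisons use a one-tailed two-sample t-test whose variant is
chosen by an F-test of equal variances: pooled (Student) when the F-test
does not reject, Welch otherwise. The gate level is 0.05 (a standard
default; the procedure's source does not state one) and is recorded in
every result. The hypothesized direction must always be supplied
explicitly — the package never infers it from the data. The F statistic is
reported with the larger sample variance in the numerator and a two-sided
p-value. Degenerate input (both groups constant) is an error, not a
silent zero.

## Click synchrony

For Joint Success trials the pairwise distribution collects `|t1 - t2|`
within each trial, and the randomized null collects the delays between
clicks from *different* trials — all cross-trial (player 1, player 2)
pairings, enumerated deterministically rather than sampled, since the
reference analysis uses all jointly successful clicks. A seed is used only
if the optional cap on very large pair sets is engaged. Both distributions
are binned on a shared grid (2 s bins from 0, configurable) and normalized
to unit mass; normalization to unit mass (rather than to a trial count) was
chosen as the convention because it makes the two curves directly
comparable as relative frequencies. An excess of short pairwise delays over
the null indicates that near-simultaneous recognition is produced by the
interaction itself, not by independent entrainment to trial time.

## What the generator emulates — and what it does not

`generate_dataset()` produces tournament-style datasets from two scripted
behaviours:

* **Turn-taker pairs** model the coordinated strategy successful human
  pairs converge on. A pair starts in mutual contact, confirms sustained
  contact (25 consecutive stimulated steps, monitored from a per-trial
  engagement onset drawn between 2 s and 47 s), then trades fixed 2.5 s
  bursts of oscillatory movement (0.6 units/step, reversing every 0.25 s,
  an amplitude of 15 units) with complementary passivity for two full
  exchanges, and clicks with a small seeded jitter (up to 0.8 s). The
  schedule — onset, burst length, role — is agreed at construction, as
  human pairs agree on conventions; at run time each agent reads only its
  own stimulation. Clicks are therefore near-synchronous within a trial
  but spread widely across trials, and the pre-click window contains
  near-perfect turn-taking.
* **Scanner pairs** model independent searchers: triangle-wave sweeps with
  seeded speed (0.55–0.9 units/step, kept above the movement threshold),
  span (120–500 units) and phase, clicking at the first stimulation after
  a seeded arming time (15–55 s). Both partners move continuously, so
  pre-click turn-taking is essentially zero and click targets scatter over
  whatever the sweep happens to touch.

The `mixed` scenario alternates the two by team, standing in for the range
of human strategies; `stationary` is a no-activity control. Static objects
are placed uniformly at random, at least two body lengths from both
starting positions (40 units in the turn-taker scenario, keeping the
oscillation corridor clear) to avoid spawn-in-contact artifacts. Each
click's ground-truth target is computed by the generator from its full
internal state at the click-lookback instant, so every analysis stage can
be scored against it. Synthetic questionnaire ratings are drawn from click
context (jointly correct clicks report high awareness and confidence most
often, wrong clicks low levels), which makes rating summaries testable by
construction.

What the generator does *not* emulate: human exploration before first
contact (turn-takers are placed already touching), trackball gain (the
absolute speed scale of human movement is unknown, so only relative
dynamics are meaningful), hesitation and strategy drift across trials, and
any genuine decision process behind clicks. Passing analyses on synthetic
data therefore validate the *pipeline* — segmentation, attribution,
scoring, statistics — under known ground truth; they do not certify the
behavioural conclusions that require real human data, and group means from
the original study (mean PAS or TT levels and their p-values) are not
reproducible without those raw data.

## Numerical and size choices

* Times are serialized in ms (integer step × 10 ms) and positions at full
  double precision (`%.17g`), so trial logs round-trip exactly.
* Test-suite simulations use 17 × 15 trials (the tournament's size) for
  the label-recovery and turn-taking contrasts, 6 × 15 turn-taker trials
  for the synchrony contrast, and a few hundred 20–200-step random
  instances for the oracle-equivalence checks; the type-I-error check of
  the gated test uses 10,000 null replicates at n = 12 per group.
* Random placement loops (static objects) are rejection-sampled from the
  same seeded stream as everything else; a whole dataset is a pure
  function of its arguments and seed, and report bundles are
  checksum-identical across reruns.

## Known limitations

* The scripted turn-taker coordinates via a pre-agreed schedule rather
  than emergent coordination; a stimulation-driven alternation is
  ill-posed in mutual avatar contact (the "active" player is itself
  stimulated while crossing its partner), so the schedule is the cleanest
  deterministic emulation of the described behaviour.
* Only one click per player per trial is retained (later clicks are
  discarded by the simulator, mirroring the paradigm), so within-trial
  click-revision behaviour cannot be studied.
* The attribution rule samples a single instant one second before the
  click; it does not integrate over the preceding interval.
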