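---
title: "Start- and end-sequence scoring of immediate recall protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Start- and end-sequence scoring of immediate recall protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallseq)
library(dplyr)
```

## The problem

In an immediate recall experiment a participant sees (or hears) a short
list of n items and then recalls as many as they can, either in the
presented order (immediate serial recall, ISR) or in any order
(immediate free recall, IFR). The raw datum of both tasks is the same:
an ordered output protocol. Conventional scoring collapses it in one of
two ways — serial scoring (SR: an item is correct only at the output
position equal to its input position) or free scoring (FR: an item is
correct anywhere) — and the choice of scoring rule, rather than the
underlying memory behaviour, accounts for much of the apparent
difference between the two tasks.

`recallseq` implements a third description of the protocol built from
two kinds of runs:

* a **start-sequence**: a run of recalls from consecutive input
  positions 1, 2, ..., s, in forward order, initiating with the first
  list item;
* an **end-sequence**: a run of recalls from consecutive input
  positions n−e+1, ..., n, in forward order, terminating with the last
  list item.

Either run may sit anywhere in the output: in the 8-item protocol
`FGHCABG` the end-sequence F,G,H occupies outputs 1–3 and the
start-sequence A,B outputs 5–6. Items recalled in neither run are
**Other** items; the remaining events are repetitions, intrusions
(tokens not on the list), and explicit omission marks (the reserved
`"blank"` token, for paradigms where participants mark skips).

The package's main scientific claim to support is a null model: given
only each trial's start-sequence, end-sequence and set of Other items,
output the start items first, the end items last, and place the Other
items in random order in between. The transposition-error gradients this
model produces are locality-constrained — errors pile up near the
diagonal — even though the Other items carry no positional information
at all. Whether that resembles observed gradients can then be assessed
without assuming per-item position codes.

## The scanner and its conventions

Sequence detection is deterministic. The published definition leaves
several cases open; the package fixes them as follows, and every choice
is controlled by `sequence_policy()`:

* **Eligibility** (`occurrence`). By default only the *first* recall of
  each item can join a sequence; later recalls are labelled
  `repetition`. This prevents one physical response from serving two
  sequences. The `"any"` rule makes every recall eligible, which is
  required to realise published cross-tabulation cells implying
  s + e > n (those need a boundary item output twice).
* **Contiguity** (`break_intrusion`, `break_omission`). A run is a run
  of consecutive response events, so an interleaved intrusion or
  omission mark breaks it by default. Either can be made transparent
  for sensitivity analysis. An item event that does not match the next
  expected position always terminates a run.
* **Maximality and ties.** The longest qualifying run wins; among equal
  lengths, the earliest output index wins. The tie-break is total, so
  identical trial and policy always give identical annotations.
* **Start priority.** The end-sequence is scanned over events not
  already claimed by the start-sequence. The two runs can only compete
  for the same events in degenerate protocols (e.g. an uninterrupted
  `1..n` prefix followed by extra events); giving the start-sequence
  priority matches the convention below and the package's general
  preference for preserving start-sequences, which are the
  rehearsal-linked quantity.
* **Complete-correct convention.** A protocol equal to `1..n` exactly
  is recorded as s = n, e = 0, mirroring the published table layout in
  which fully correct trials occupy the full-start row.
* Singleton anchors count: a lone recall of item n is an end-sequence
  of length 1, and symmetrically for item 1. Consequently s = 0 exactly
  when item 1 is never (eligibly) recalled, and e = 0 exactly when item
  n is not.

The scanner is verified against an independent brute-force oracle that
enumerates every contiguous output window over every protocol of length
at most 6 for lists of 2–6 items, including intrusions, omission marks
and repetitions.

```{r}
trials <- parse_letter_trial(rep("ABCDEFGH", 4),
                             c("FGHCABG", "HGABCE", "ABCFEGH", "GFAC"))
annotate_trials(trials) |>
  select(trial_id, start_len, end_len, other_count, n_repetition)
```

## Scoring rules and curves

`score_trials()` scores each input position under SR, FR, or START_END
(correct only inside a detected sequence). SR uses the output rank as
the positional slot — the spoken-recall convention: omission marks and
intrusions occupy a slot and shift later recalls, and unmarked early
termination does not back-fill. This convention is what makes terminal
items land "too early" to score when earlier items are omitted, the
mechanism behind the small recency effect of serially scored data; the
explicit-skip condition restores it:

```{r}
score_trials(parse_letter_trial("ABCDEF", "ACDEF"), "SR")$correct
score_trials(parse_letter_trial("ABCDEF", "A-CDEF"), "SR")$correct
```

`position_curve()` aggregates per condition and list length (never
across lengths) with an `include_complete` switch, and
`residual_other_curve()` plots the proportion of trials on which each
position was recalled as an Other item, recency-justified (distance 0 =
last item) so residual recency lines up across list lengths. Only first
occurrences of items enter curves and transposition matrices.

## The null model

For each annotated trial the null model uses only (s, e, Other set).
The number of output slots equals the number of counted recall events —
s + k + e under the default intrusion policy — so when a trial has
fewer outputs than items, its end-sequence necessarily lands
prematurely at early output positions. The k Other items are a uniform
random permutation over the intervening slots.

Two estimators are provided and are equivalent: `estimated_gradient_mc()`
simulates (default 1000 replications per trial, one RNG stream per
trial derived from the seed and trial id, so results are invariant to
trial order), and `estimated_gradient_analytic()` computes the exact
expectation (each Other item occupies each intervening slot with
probability 1/k). The analytic form is the reference in tests; the
Monte Carlo path exists because the estimate is defined procedurally
and the convergence of the two is itself a useful correctness check
(total-variation distance below 0.01 at 10^5 replications). Intrusions
are excluded from the null by default (the estimate concerns order
errors among presented items); an `"occupy"` policy gives them slots
instead. Both observed and estimated gradients are reported error-only:
the diagonal is removed and the remaining cells are normalised to sum
to 1. A data set with no order errors yields an explicit empty-gradient
signal rather than a division by zero.

```{r}
ann <- annotate_trials(parse_letter_trial("ABCDEF", "ABEF"))
estimated_gradient_analytic(ann)
```

## The synthetic generator

`generate_trials()` emulates the output statistics of 6-word ISR (the
conditions under which the published cross-tabulation was collected)
without modelling any cognitive process. Defaults, chosen once:

* `list_length = 6`, the standard span-range list length; 2–15 are
  supported.
* `p_complete = 0.383`, the completely-correct rate of the closed-set
  condition — the package's reference condition for simulation.
* `start_dist` uniform over 0..n−1: observed start-length
  distributions are broad and condition-dependent, and a flat prior
  exercises all cells.
* `end_dist` geometric with ratio 0.5: end-sequences are short and
  their distribution is far less condition-dependent than start
  lengths.
* `other_dist` with mass 0.5/0.3/0.2 on 0/1/2 Other items, matching
  the small residual counts implied by 6-item protocols.
* All noise rates 0 by default; intrusions, repetitions and omission
  marks are injected per middle-region gap at the configured rates.

Sampling is s first, then e truncated to the feasible range, then k
(truncation order k, then e, preserving the start-length distribution
preferentially; if a distribution has no mass on the feasible range the
length falls back to 0). Other items never include positions already
used by the sequences, nor item 1 when s = 0 or item n when e = 0,
since recalling either anchor forces a sequence under the content-based
definition.

In **strict mode** (default) arrangements that would change the
annotated (s, e) — an Other item s+1 landing immediately after the
start run, or n−e landing last — are rejected and resampled, and the
final protocol is verified with the actual scorer, so the annotation
recovers the sampled lengths *exactly*. With `strict = FALSE` the
generator exhibits the "lucky positioning" inflation that real
annotations are subject to: the annotated start length can only equal
or exceed the intended one (in the extreme, a lucky arrangement
completes the whole sequence, which then takes the (n, 0) convention).
This gives the package a measurable handle on how much observed
sequence lengths overstate the sequence knowledge that produced them.

`generate_from_crosstab()` replays a published cross-tabulation as
concrete trials, cell for cell. Cells with s + e = n use a repeated
item as a run separator (item 1, or item n when s = 1 under the
any-occurrence policy, where a repeated item 1 would anchor a full run
itself); overlap cells with s + e > n repeat the boundary items and
exist only under `"any"`. Published tables do not report Other counts
per cell, so replay defaults to k = 0; an `other_dist` can inject
strictly placed Other items. Replayed Other-free protocols slightly
understate middle-position error mass relative to the original raw
data, which is the main caveat when comparing estimated gradients to
the published panels.

## What the tests do and do not show

The packaged transcription of the published table carries both the
printed per-cell counts and the running-text trial totals; three of the
four disagree, and all derived proportions use the printed cells, whose
sums reproduce the printed completely-correct proportions (0.472,
0.383, 0.209, 0.152). Because replay is exact, those quantities are
reproduced to the printed precision; they validate the scorer's
conventions against the published layout, not the package's ability to
recover structure from noisy raw data. That ability is tested
separately by parameter recovery on synthetic protocols (exact in
strict mode; inflation-bounded otherwise, chi-square goodness of fit on
the joint (s, e) distribution at 10,000 trials) and by the oracle
equivalence checks. Synthetic protocols share the real data's
output-statistics but none of its item-level structure (no
phonological similarity, no word frequency, no serial-position-graded
omission rates), so passing tests say nothing about those effects.

Problem sizes used by the test suite and the acceptance script — about
half a million enumerated protocols for the oracle check, 10^5 null
replications, 10,000-trial recovery runs, and full replay of all four
table blocks (~24,000 trials) — run in a few minutes on one CPU.

## Known limitations

* Vocal-order convention only: grid-position (written) scoring is out
  of scope, and SR scoring here uses output rank, not grid assignment.
* The scanner's start-priority and tie-break rules are conventions; the
  source analyses never encounter the ambiguous cases, so no empirical
  comparison can distinguish them.
* The occurrence-rule ambiguity is real: some published cells require
  repeated items (`"any"`), while the default scorer forbids them. Both
  policies are first-class and the discrepancy is surfaced, not
  resolved.
* The null model conditions on the *observed* sequences, which are
  themselves partly products of guessing; it is an existence proof that
  locality needs no positional codes, not a generative model of recall.
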