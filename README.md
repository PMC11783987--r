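# recallseq

Scoring and analysis of immediate recall output protocols.

Immediate serial recall (ISR) and immediate free recall (IFR) produce
the same raw datum — an ordered sequence of responses to a short list —
but are conventionally scored so differently (in-position "SR" scoring
vs anywhere "FR" scoring) that the two literatures barely touch.
`recallseq` scores protocols by the runs they contain instead:

* a **start-sequence** — a run of recalls from consecutive input
  positions `1, 2, ..., s`, in forward order, beginning with the first
  list item, located anywhere in the output;
* an **end-sequence** — a run `n-e+1, ..., n` terminating with the
  last list item;
* **Other** items — recalled list items in neither run.

On top of the scanner the package provides serial-position curves under
SR, FR and start/end scoring; recency-justified residual curves of the
Other items; observed transposition matrices and error-only gradients;
and a **"start + guess + end" null model**: place the start items
first, the end items last, and allocate the Other items at random to
the intervening output positions. Because the number of output slots
equals the number of responses, end items on short protocols land
prematurely, and because the Other items are boxed in between the two
runs, the null gradients concentrate near the diagonal — the locality
constraint of serial recall — with *no* per-item positional information
at all. The null expectation is available in closed form
(`estimated_gradient_analytic()`) and by simulation
(`estimated_gradient_mc()`).

A synthetic protocol generator (`generate_trials()`) with controllable
start/end-length distributions, Other counts and
intrusion/repetition/omission rates makes every pipeline stage testable
without any data download, and `generate_from_crosstab()` replays a
packaged transcription of a published start-by-end frequency table
(four conditions of 6-word ISR; `osth_dennis_table1()`) as concrete
trials, cell for cell.

## Worked example

Four recall protocols for the 8-item list `ABCDEFGH`, in letter
notation:

```r
library(recallseq)
library(dplyr)

trials <- parse_letter_trial(rep("ABCDEFGH", 4),
                             c("FGHCABG", "HGABCE", "ABCFEGH", "GFAC"))
annotate_trials(trials) |>
  select(trial_id, start_len, end_len, other_count, n_repetition)
#> # A tibble: 4 × 5
#>   trial_id start_len end_len other_count n_repetition
#>   <chr>        <int>   <int>       <int>        <int>
#> 1 t1               2       3           1            1
#> 2 t2               3       1           2            0
#> 3 t3               3       2           2            0
#> 4 t4               1       0           3            0
```

`FGHCABG` opens with the end-sequence F,G,H (e = 3), continues with the
Other item C, then the start-sequence A,B (s = 2), and closes with a
repetition of G. In `HGABCE` only H itself forms the end-sequence — the
G after it is in backward order — and in `GFAC` nothing ends with H, so
e = 0 while the lone A still counts as a start-sequence of 1.

The packaged published table and the null model:

```r
tab <- osth_dennis_table1("Closed ISR")
glance(tab)
#> # A tibble: 1 × 5
#>   list_length n_trials prop_complete mean_start mean_end
#>         <int>    <int>         <dbl>      <dbl>    <dbl>
#> 1           6     6128         0.383       3.84    0.365

pol <- sequence_policy("any")   # published cells include repeated items
ann <- generate_from_crosstab(tab, policy = pol) |> annotate_trials(pol)
g <- estimated_gradient_analytic(ann)
locality_correlation(g)
#> [1] -0.2231881
```

0.383 is the completely-correct proportion of the closed-set condition,
recomputed from the replayed cells. The negative correlation says the
estimated error mass falls off with transposition distance |input −
output| — a locality-constrained gradient produced purely by the
start/guess/end constraint. `autoplot()` methods display curves,
cross-tabulations and gradients; `plot_gradient_comparison()` puts
observed and estimated gradients side by side.

A thin command-line wrapper with subcommands `score`, `curves`, `null`,
`simulate` and `replay-table1` is installed under
`system.file("scripts", "recallseq", package = "recallseq")`.

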