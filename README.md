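# pcrossing

Simulation and analysis of the **perceptual crossing paradigm** — the
minimal virtual-reality setup for studying how two people detect each
other's presence through interaction alone.

Two players each move an invisible avatar along a shared 1D space that
wraps around after 600 units, receiving only on/off tactile feedback when
their avatar overlaps an object. Each can encounter three identical 4-unit
objects: the partner's avatar (contact stimulates *both* players), the
partner's "shadow" (a lure rigidly attached 150 units from the partner's
avatar — it copies the partner's motion but stimulates only the toucher),
and a private static object. Players click when they believe they are
touching the partner's avatar; a correct click earns the team a point, a
wrong one costs a point. Only the avatar affords *responsive* interaction,
so distinguishing it from its own kinematic copy is a test of sensitivity
to social contingency.

The package is written for researchers in interactive social cognition and
agent-based modelling who want a tested, reusable implementation of this
paradigm's full analysis chain, plus a simulator with scripted agents for
method validation under known ground truth.

## What it computes

* **Contacts** — maximal runs of uninterrupted stimulation, each involved
  object type counted once per run (`segment_contacts()`).
* **Click targets** — avatar / shadow / static / none, from wrapped
  displacements within ±70 units sampled 1 s before the click
  (`assign_click_target()`).
* **Turn-taking** — movement binarization (`dx > 0.5` units/step, pauses
  merged below 50 steps) and the score `TT = 4·C1·C2 / T²`, where `C1`,
  `C2` count the steps on which exactly one player moves in a `T`-step
  window (`turn_taking_score()`, `tt_before_click()`). `TT = 1` is a
  perfect exchange of activity and passivity; 0 is no exchange.
* **Trial outcomes and scores** — Joint/Single Success classification,
  tournament team scores, clicking accuracies, per-contact click
  probabilities (`classify_trials()`, `team_scores()`,
  `click_probability_per_contact()`).
* **Subjective ratings** — relative-frequency tables of 4-level awareness
  (PAS) and confidence (CR) ratings by click category
  (`rating_frequency_table()`).
* **Inference** — one-tailed two-sample t-tests gated by an F-test of
  equal variances (Student vs Welch; `gated_comparison()`), and a
  click-synchrony analysis comparing within-trial inter-click delays
  against an exhaustively enumerated cross-trial null
  (`synchrony_analysis()`).
* **Simulation** — `simulate_trial()` with scripted controllers
  (`make_turn_taker_agent()`, `make_scanner_agent()`) and
  `generate_dataset()` for whole tournaments with ground-truth click
  targets and synthetic questionnaires.

Results come back as tibbles (with `tidy()` / `glance()` methods for
fitted objects and `autoplot()` for recordings and synchrony results), so
everything composes with dplyr and ggplot2.

## Worked example

```r
library(pcrossing)

ds  <- generate_dataset(4, 15, scenario = "mixed", seed = 42)
rep <- run_pipeline(ds)
rep
#> <pc_report>
#>   60 trial(s), 2550 contact(s), 116 click(s)
#>   outcome       n_trials
#> 1 JointSuccess        30
#> 2 SingleSuccess        9
#> 3 WrongOnly           21
#>   type   clicks contacts probability
#> 1 avatar     69     1644        4.20
#> 2 shadow      8      451        1.77
#> 3 static     11      473        2.33

mean(rep$clicks$target == rep$clicks$true_target)
#> [1] 1
```

Sixty trials from two coordinating ("turn-taker") and two independently
searching ("scanner") teams yield 2550 contacts and 116 clicks; every
click's attributed target matches the generator's ground truth. A click is
more than twice as probable after an avatar contact (4.20 %) than after a
shadow contact (1.77 %) because coordinating pairs click while engaged
with each other. The gated comparisons and synchrony summary:

```r
rep$gated_tests$table[, c("comparison", "mean1", "mean2",
                          "chosen_test", "p_one_tailed")]
#>   comparison          mean1 mean2 chosen_test p_one_tailed
#> 1 tt_joint_vs_single  0.924  0    welch           2.72e-79
#> 2 tt_joint_vs_wrong   0.924  0    welch           2.72e-79
#> 3 pas_joint_vs_single 3.72   2.89 student         3.40e- 6
#> 4 pas_joint_vs_wrong  3.72   2.06 welch           5.87e-21
#> 5 pas_single_vs_wrong 2.89   2.06 student         1.73e- 3

glance(rep$synchrony)
#>   n_trials n_randomized_pairs short_pairwise short_randomized
#> 1       30                870              1            0.422
```

Turn-taking before jointly successful clicks averages 0.92 versus 0 before
wrong clicks (the F-gate picks Welch because the scanner group is
constant), synthetic awareness ratings are highest in Joint Success
trials, and all within-trial click delays fall under 10 s versus 42 % of
the randomized cross-trial pairings — the synchrony signature of genuinely
interactive recognition.

A command-line wrapper is included:

```sh
Rscript inst/scripts/pcrossing-pipeline.R simulate --teams 2 --trials 15 \
        --scenario mixed --seed 1 --out logs/
Rscript inst/scripts/pcrossing-pipeline.R analyze --in logs/ --out report/
```

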