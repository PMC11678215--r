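# mascore

Net-promoter-style acceptability scoring for medicinal formulations.

Palatability panels for (mostly paediatric) oral medicines usually collect
hedonic-scale taste scores and compare formulations by means or medians with
ad-hoc cutoffs. `mascore` implements the **Medicine Acceptability Score
(MAS)**, which instead counts respondents: each participant is classed, by
their taste score, as a *promoter* (above a predefined passives score
range), a *passive* (inside it), or a *detractor* (below it), and

```
MAS = %promoters − %detractors            ∈ [−100, 100]
```

The companion **Willingness-to-Take-Medicine Score (WTMS)** is the signed
deviation of the affirmative-response rate from the design's neutral point:
50% for yes/no (and two-alternative) questions, 100/k for a k-alternative
forced choice,

```
WTMS = %affirmative − 100/k .
```

Because the passives range is a free parameter, the package also implements
its calibration: sweep candidate ranges, keep those whose MAS signs agree
with the WTMS signs (an MAS of 0 against a decided WTMS fails), and pick the
survivor whose MAS ranking best matches the WTMS ranking (Kendall tau-b,
by default over the positive-WTMS formulations). A calibrated range
transposes to other rating scales (centre × 2, ± 1, clipped — mapping the
5-point optimum {3} to 5–7 on a 0–10 scale), and cohorts stratify by age.

Two supporting layers make the method testable without raw trial data:

* `reconstruct_counts()` exhaustively enumerates every integer score
  distribution consistent with published summaries (n, median, mean/SD to
  their printed decimals, MAS values, category-share statements). Published
  MAS values for several passives ranges jointly *force* category tallies,
  so some unpublished table cells are recoverable exactly.
* `simulate_cohort()` draws synthetic cohorts from a latent-liking model
  (normal liking, threshold discretisation, logistic or Gumbel-choice
  willingness link) with known ground truth.

Bundled under `inst/extdata/` are reconstructed datasets for four reference
taste studies (midazolam, tramadol, flucloxacillin, prednisolone sodium
phosphate; tablets vs liquid comparators), loadable via `study_fixtures()`.

## Worked example

Five participants score a formulation 1, 3, 3, 4, 4 on a 5-point hedonic
scale (1 = dislike very much, 3 = not sure, 5 = like very much):

```r
library(mascore)
sc <- rating_scale(1, 5, "5-point hedonic")
cc <- categorize(c(1, 3, 3, 4, 4), sc, passives_range(3))
cc
#> <category_counts> promoters 2, passives 2, detractors 1 (n = 5)
mas(cc)
#> [1] 20
```

Mean and median are both 3 ("not sure"), yet two participants are positive
and one negative: the MAS of +20 surfaces that balance. Calibrating the
passives range on the bundled 5-point studies:

```r
fx <- study_fixtures()
res <- select_passives_range(fx[c("study1", "study2", "study3")])
res
#> survivors: 2-3, 3
#> tau-b (positive_wtms): 2-3=0.333, 3=0.913
#> selected: 3
transpose_range(passives_range(3), rating_scale(1, 5), rating_scale(0, 10))
#> <passives_range> 5-7
```

Only the ranges 2–3 and {3} keep every tablet's MAS positive where its WTMS
is positive; {3} wins on rank concordance (tau-b 0.913 vs 0.333) and maps to
5–7 on the 11-point scale.

A command-line wrapper is installed at
`system.file("exec", "mascore", package = "mascore")`:

```sh
mascore score --in study2.csv --design study2.json --passives 3 --mode paper
mascore transpose --range 3 --from 1:5 --to 0:10
```

## Scope

The package scores and calibrates; it does not run trials, model
formulation chemistry, or compute inferential statistics on MAS (no
confidence intervals — the method as specified has none). See the methods
vignette (`vignettes/mas-methods.Rmd`) for the model, conventions
(rounding, missing data, tie-breaks), and limitations.
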