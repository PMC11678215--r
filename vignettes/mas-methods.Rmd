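---
title: "The MAS model: scoring, calibration, and reconstruction methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MAS model: scoring, calibration, and reconstruction methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mascore)
```

## The model

Taste panels for oral medicines elicit widely dispersed scores: the same
formulation draws extreme likes and dislikes, so means and medians blur the
question a formulator actually asks — *how many* panellists would accept the
medicine. The Medicine Acceptability Score answers it by counting. Given
taste scores on a discrete rating scale and an inclusive *passives range*
$[\ell, h]$, each respondent is a promoter (score $> h$), passive
($\ell \le$ score $\le h$), or detractor (score $< \ell$), and

$$\mathrm{MAS} = 100\,\frac{P - D}{n} \in [-100, 100],$$

with $P$, $D$ the promoter and detractor counts and $n$ the number of
scoreable responses. Passives carry no weight: the score deliberately
ignores the intensity of opinions and the undecided middle.

Willingness to take the medicine again anchors the calibration. For a
yes/no question the Willingness-to-Take-Medicine Score is the affirmative
percentage minus the 50% neutral point; for a forced choice among $k$
formulations the neutral point is $100/k$ (an even split signals no
preference). Binary WTMS therefore lives in $[-50, 50]$ and $k$-choice WTMS
in $[-100/k,\; 100 - 100/k]$ — unlike MAS it cannot reach $100$, which is
why the two are compared by sign and rank, never by magnitude.

### Assumptions

* Scores are consecutive integers on a declared scale; no half-points,
  no visual-analogue readings.
* Every respondent contributes equally (no weighting) and independently;
  repeated-measures designs are handled only through the willingness
  question (one vote per participant).
* Missing responses are uninformative: a record lacking a taste score drops
  out of the MAS denominator only, one lacking a willingness response out of
  the WTMS denominator only. Each exclusion is reported via `message()`.
  This is the least-assumption default; no imputation is attempted.

## Rounding conventions

Reported scores use a single convention, exposed as `mode = "paper"`
(default) next to unrounded `mode = "exact"`:

* all roundings are half-away-from-zero (`round_half_away()`), not the IEC
  half-even of `base::round()`;
* MAS is rounded **once, on the final difference**:
  $\operatorname{round}(100(P-D)/n)$. Rounding the two percentages first
  and then subtracting is *not* equivalent — at $P-D = -52$, $n = 70$ it
  yields $-75$ where the single final rounding yields $-74$ — and only the
  single-rounding form reproduces every reference value consistently;
* WTMS rounds the affirmative percentage and the neutral point separately,
  then subtracts: for $k = 3$ the neutral point is
  $\operatorname{round}(100/3) = 33$, so 1 vote in 21 gives $5 - 33 = -28$
  (exact arithmetic would give $-28.57$, i.e. $-29$ after rounding — the
  separate-rounding form is the one consistent with the reference tables).

The two modes never differ by more than $0.5$ MAS points plus, for
$k$-choice WTMS, the neutral-point rounding residue. No reference value
sits on an exact $.5$ boundary, so the tie direction is unobservable in the
data; half-away-from-zero was chosen for being the simpler convention to
state.

## Calibrating the passives range

The passives range is the method's one free parameter. On a 5-point scale
the candidate set is the four ranges that leave at least one promoter and
one detractor score: 2–3, 2–4, {3}, 3–4. Widening the range is monotone —
absorbing detractor scores into the passives weakly raises MAS, absorbing
promoter scores weakly lowers it — so the candidates are strictly ordered
column-wise, a property the test suite checks on random data and on the
bundled matrix.

Selection proceeds in two stages (`select_passives_range()`):

1. **Sign filter.** A candidate survives only if every formulation with a
   nonzero WTMS has an MAS of the same sign. An MAS of exactly 0 against a
   decided WTMS *fails* (`zero_fails_sign = TRUE`): a range that
   neutralises a formulation the willingness data ranks is uninformative.
   On the bundled studies this removes 2–4 (two tablets at MAS 0) and 3–4
   (three tablets negative against positive WTMS).
2. **Rank concordance.** Among survivors, "the MAS ranking that most
   closely matches the WTMS ranking" is formalised as Kendall's tau-b —
   the tie-corrected rank correlation, appropriate because integer MAS
   values tie often — restricted by default to the positive-WTMS
   formulations. The restriction reflects how the reference calibration was
   argued: the liquid comparators are so strongly negative under every
   candidate that they carry no ranking information, and the decision rests
   on the tablets. With `concordance_subset = "all"` the unrestricted
   comparison is available.

Ties in concordance break deterministically: narrower range first (it
leaves more respondents informative), then lower midpoint. A sweep with no
survivor returns an explicit no-selection result carrying per-candidate
failure reasons rather than raising an error.

`stats::cor(method = "kendall")` computes tau-b under ties; the test suite
cross-checks it against an exhaustive pair count on every input of size
$\le 8$.

## Transposing between scales

A range calibrated on one scale must be restated before use on another.
The default `"paper"` rule multiplies the range centre by `factor = 2`,
rounds, and takes `centre ± halfwidth` (default 1), clipped to the target:
{3} on 1–5 becomes centre 6, range 5–7, on 0–10. The proportional
alternative (`rule = "affine"`) maps bounds linearly between the scale
spans and would centre the same range on 5. The two disagree because
doubling treats the scale as ratio-like while the affine map respects the
endpoints; the package defaults to the doubling rule because it is the
convention the reference results were produced under, and keeps the affine
map available for designs that prefer it.

## Reconstructing distributions from published summaries

`reconstruct_counts()` inverts published summary tables: it returns *every*
integer count vector $(c_{\min},\dots,c_{\max})$, $\sum c_s = n$,
consistent with the supplied constraints. Conventions:

* **Printed decimals as inclusive intervals.** A mean printed as 3.69
  admits any true mean in $[3.685, 3.695]$, both ends closed, because the
  publisher's tie rule is unknowable. Same for SD (with the $n-1$ divisor).
* **Integer medians.** For odd $n$ the middle order statistic must equal
  the printed median; for even $n$ both middle order statistics must (all
  reference medians are integers, which this rule encodes exactly).
* **MAS cells.** A printed MAS $v$ constrains the count difference $d$ for
  its range to the integer interval where
  $\operatorname{round}(100d/n) = v$. For the study sizes involved that
  interval usually contains a single integer, so three printed rows can
  force the promoter, passive, and detractor tallies of a fourth — the
  mechanism by which the singleton-range MAS values for the tramadol tablet
  (41) and the midazolam liquid (−74) are recovered without raw data, with
  the search asserting the value is identical across all surviving vectors.
* **Category-share statements.** Published claims of the form "at least
  48% promoters" / "more than 70% detractors" are accepted as constraints
  on the *displayed* integer percentage (rounded half away from zero). The
  displayed reading is forced by the data: one tablet's promoter share can
  reach at most $10/21 = 47.6\%$ raw under any vector consistent with its
  MAS row, which displays as 48.

The search is a depth-first enumeration over count cells with interval
pruning on the running score total and on each MAS difference, returning
vectors in lexicographic order. It is exact and bounded at $n \le 200$
(larger cohorts would need constraint propagation; every bundled use is
$n \le 74$ and runs in milliseconds). SD constraints are supported but
deliberately unused in the bundled reconstructions: the tramadol tablet's
printed SD sits at the edge of its rounding interval, so forcing it would
over-commit to an unverifiable convention.

### The bundled fixtures

`study_fixtures()` loads four reconstructed studies (two paediatric
binary-willingness trials, a three-way forced-choice adult study, and a
two-way 11-point adult study). They are synthetic reconstructions, not
trial records: willingness tallies are exact; each 5-point taste
distribution is the lexicographically smallest vector satisfying all
published constraints (`fixture_constraints()` exposes them for replay);
yes-answers attach to the highest taste scores first; age labels cycle
through the published stratum age ranges, youngest first. One reference
inconsistency is preserved deliberately: the midazolam tablet's published
cohort is 74 but its published age strata sum to 39 + 36 = 75, so the
fixture carries one participant with an age and no recorded responses,
keeping both tallies simultaneously true. The 11-point study's
distributions are underdetermined by print; the bundled vectors are a
documented canonical choice matching the published n, medians, means, and
MAS values, shipped in both forced-choice and rating-mode variants.

What the fixtures therefore do and do not show: scores, calibration, and
stratum sizes computed from them reproduce the published tables exactly,
but record-level joint structure (which child gave which score at which
age, score–willingness association) is a canonical invention, so analyses
sensitive to that joint structure — per-stratum MAS, for instance — are
not certified by the fixtures and are excluded from their guarantees.

## The synthetic cohort simulator

`simulate_cohort()` provides ground truth the fixtures cannot: a
participant's latent liking for formulation $f$ is
$L \sim \mathcal N(\mu_f, \sigma^2)$; the observed score discretises $L$
through strictly increasing thresholds; willingness follows the declared
link — $\Pr(\text{yes}) = \operatorname{logit}^{-1}(a + bL)$ for binary
designs, Gumbel-noise utility maximisation (the standard discrete-choice
construction) for forced choice, and threshold discretisation of
$a + bL + \varepsilon$ for rating designs. Identical parameters and seed
reproduce the dataset exactly.

Defaults are fixed once to emulate the binary-willingness study arms: a
5-point scale with thresholds $1.3\,\Phi^{-1}(j/5)$, $j = 1,\dots,4$
(symmetric, slightly heavy-shouldered), $\mu_{\mathrm{TMT}} = 0.5$ and
$\mu_{\mathrm{LQD}} = -1.3$ with $\sigma = 1$ (a mildly liked tablet whose
mean score lands near 3.5 against a disliked liquid near 1.9), link
$a = 0.3$, $b = 1.2$ (willingness rates near 75% and 25%), and $n = 70$
per formulation, matching the 68–74 arm sizes of the reference studies.

The simulator checks the estimator, not the world: under the model,
empirical MAS at large $n$ matches the analytic value
$100[(1 - \Phi(\frac{t_3-\mu}{\sigma})) - \Phi(\frac{t_2-\mu}{\sigma})]$
(tested at $n = 10{,}000$ within 3 Monte-Carlo standard errors), a flat
link ($b = 0$) drives WTMS to its neutral point, and stochastic ordering
in $\mu$ propagates through to MAS and WTMS. Real taste data violate the
model freely — multimodal likings, age-dependent scale use, willingness
driven by factors other than taste — so passing simulator tests certifies
the arithmetic and the calibration machinery, not any claim about real
cohorts.

## Numerical and degenerate-input choices

* Empty score lists categorise to all-zero counts; a zero denominator makes
  the *score* undefined (`mascore_undefined_score`), and `score_study()`
  flags the formulation with `NA` rather than failing the study.
* Rank concordance on fewer than two formulations is an error where called
  directly, but a single-survivor calibration still selects that survivor
  (its concordance is reported as `NA`).
* Transposition clips to the target scale and errors only if clipping
  empties the range.
* CSV cells that are empty strings are absent values; `willing_binary`
  serialises as `yes`/`no`. Round-trip identity is tested field by field.
* All randomness flows through a single integer seed; the CLI's `simulate`
  writes byte-identical files for identical seeds.

## Problem sizes

The test suite runs the full reconstruction of all seven 5-point
formulations (n = 21–74, seven constraint sets of up to seven constraints
each), calibration sweeps over four candidate ranges, and simulator checks
at $n = 10{,}000$; the whole suite completes in a few seconds on one core.

## Known limitations

* The exhaustive reconstruction bound ($n \le 200$) is a hard error, not a
  fallback; no approximate mode exists.
* Only consecutive-integer scales are supported (no VAS, no half-points),
  and only two-group age stratification at a single cutoff.
* MAS carries no uncertainty quantification by design; users comparing
  formulations at small $n$ should remember that a one-respondent change
  moves a 21-person MAS by about 5 points.
* The calibration's positive-WTMS restriction is the documented default,
  not a theorem; with other data the unrestricted subset may be preferable,
  and both are exposed.
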