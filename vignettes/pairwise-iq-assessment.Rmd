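---
title: "Pairwise-comparison ranking for subjective image quality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise-comparison ranking for subjective image quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqrank)
```

## The problem

Subjective image quality (IQ) of CT scans is usually scored on a 5-point
Likert scale. Likert scores are absolute judgments without a reference, so
different observers anchor the scale differently, and most raters avoid the
extreme categories — both effects depress inter- and intraobserver
agreement. A forced-choice pairwise-comparison (PC) protocol sidesteps the
anchoring problem: the observer only ever decides which of two scans looks
better, and a sorting algorithm assembles those relative judgments into a
complete ranking.

The catch is the comparison budget. Ranking 50 scans by round-robin
comparison needs `pair_count(50)` = `r pair_count(50)` forced choices,
which is not feasible for a human reader. `iqrank` therefore drives the
comparisons with the Ford-Johnson (merge-insertion) sort, the comparison
sort with the smallest known worst case, and provides everything around it:
agreement statistics, synthetic observers for protocol design, and the
standard diagnostics.

## The ranking engine

`fj_rank()` implements canonical merge-insertion:

1. Pair the items and compare within pairs.
2. Recursively rank the winners; they form the main chain.
3. Insert the losers (and, for odd n, the unpaired straggler, treated as
   the last loser) into the chain by binary insertion, processed in groups
   delimited by the Jacobsthal numbers 3, 5, 11, 21, ..., descending within
   each group.

The Jacobsthal schedule is the whole point: it keeps every binary-search
window at most `2^k - 1` elements wide, which yields the worst case
`fj_worst_case(n)` = &Sigma;<sub>k=1..n</sub> &lceil;log2(3k/4)&rceil;
— for n = 50, `r fj_worst_case(50)` comparisons instead of 1225. The bound
is evaluated in integer arithmetic (smallest *t* with 2^(t+2) &ge; 3k);
no floating-point logarithm is trusted near a power of two. The test suite
verifies, exhaustively over every permutation for n &le; 8, that the engine
recovers the true order, never repeats an unordered pair, and that its
empirical maximum equals the closed form — the strongest evidence that the
implementation is the canonical variant.

Numerical and protocol choices:

* **Rank direction.** Rank 1 is the lowest quality, rank n the highest.
* **Ties.** There is no abstain option; the oracle must choose. A
  noiseless simulated observer facing exactly equal perceived qualities
  breaks the tie by scan identifier, purely for determinism.
* **Intransitive answers.** Human (and noisy simulated) observers produce
  cyclic preferences. Because no redundant pair is ever asked,
  intransitivity is undetectable in-session; the engine accepts answers as
  given and the ranking is whatever the insertion sequence produces. This
  is a documented limitation of any sorting-based PC protocol, not an
  error.
* **Presentation sides.** Which scan appears left is a seeded coin flip
  per comparison (bias control); it is part of the log, so sessions replay
  exactly.
* **Session state.** A serialized session stores items, seed and the log
  only. State is rebuilt by replaying the log, making the JSON files
  robust to internal refactoring. Replay costs O(comparisons) per step,
  negligible at n = 50.
* **Adversarial measurement.** `adversarial_oracle()` is a lazy adversary
  over the transitive closure of its committed answers; free choices steer
  the item currently being inserted toward the side with more remaining
  positions. It is used to probe the comparison budget from above;
  together with seeded random permutations it attains the closed-form
  worst case.

## Agreement statistics

Both rating methods produce a complete subjects × raters matrix: PC ranks
1..50 or Likert scores 1..5. Agreement is quantified by the intraclass
correlation coefficient from the two-way random-effects model with
absolute agreement,

$$x_{ij} = \mu + s_i + r_j + e_{ij}, \qquad
s_i \sim N(0, \sigma_s^2),\; r_j \sim N(0, \sigma_r^2),\;
e_{ij} \sim N(0, \sigma_e^2),$$

estimated from the crossed ANOVA mean squares (`anova_mean_squares()`):

* single measures (one rater's reliability; used for intraobserver
  agreement across two sessions):
  ICC(A,1) = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE));
* average measures (reliability of the k-rater mean; used for
  interobserver agreement):
  ICC(A,k) = (MSR − MSE) / (MSR + (MSC − MSE)/n).

Confidence intervals are the F-based intervals with a Satterthwaite
denominator df for the single-measures case; the average-measures interval
applies the Spearman-Brown step to the single-measures bounds. This is the
convention of mainstream statistical software, so published SPSS-style
tables are reproducible from the same matrix. Raw estimates may be
negative (they estimate a ratio of variance components with a noisy
numerator); report tables conventionally floor them at zero, so every
`icc_result` carries both the raw values and a `clamped` copy. Two
degenerate directions are handled explicitly: a constant matrix has no
variance to apportion and raises an error, and a matrix whose raters agree
perfectly on varying subjects (MSE = MSC = 0) returns exactly 1 with a
degenerate [1, 1] interval, the analytic limit of both bounds.

Calibration is tested by Monte Carlo: at n = 50 subjects and k = 6 raters,
over 1000 matrices simulated from the model above, the mean single-measures
estimate sits within 0.02 of
$\sigma_s^2 / (\sigma_s^2 + \sigma_r^2 + \sigma_e^2)$ and the 95% interval
covers the truth between 93% and 97% of the time. A fully independent
brute-force implementation (explicit elementwise sums, formulas recoded)
lives in the test helpers and must agree with the main path to 1e-9
relative tolerance on random matrices.

## The synthetic study

No pixels are processed anywhere. The simulation layer emulates the
*effect* of dose reduction and reconstruction choice as a latent scalar
quality per scan:

$$q = \beta_c \log(\mathrm{current}/100) + \beta_{\mathrm{recon}} + u_{\mathrm{patient}}.$$

`generate_scan_pool()` emits 17 scans per patient: the original acquisition
(100% tube current, IR2 reconstruction) plus all 16 combinations of
{60, 70, 80, 90}% current × {FBP, IR2, IR3, IR4} — the unique reading under
which 30 patients give 510 scans. Defaults, chosen once as plausible for
contrast-enhanced abdominal CT and not revisited: `beta_current = 2` IQ
units per log current fraction (a 60% scan loses ≈ 1 unit), reconstruction
offsets FBP = −1.5 (markedly noisier), IR2 = 0, IR3 = +0.6, IR4 = +1
(stronger iterative smoothing a modest perceived gain), patient SD 0.5.
The scale is arbitrary; only ratios relative to observer noise and Likert
threshold spacing matter.

`compose_dataset()` reproduces the two 50-scan study datasets: all 25
originals of the included patients plus one non-original scan per patient,
drawn to match a cell-count profile over reconstruction × current. The
high-variation profile spreads the 25 extras over the full grid. The
printed low-variation composition in the source material does not parse to
a consistent 25-scan table, so the default low profile is a documented
approximation of its stated character — concentrated on IR2/IR4 at 80–90%
current, i.e. scans barely distinguishable from the originals — and both
profiles are plain matrices the user can replace.

Observers are Thurstonian: perceived quality is
`scale * q + bias` plus fresh Gaussian noise at every look
(`sigma_compare` per side of a comparison, so
P(left wins) = &Phi;(scale·&Delta;q / (&radic;2·&sigma;)); `sigma_likert`
per rating, cut at four thresholds into scores 1–5). Fresh per-comparison
noise — rather than a fixed perceived value per scan — is deliberate: it
produces the intransitive choice patterns that sorting-based protocols
must tolerate in practice. The default panel of six observers shares
noise SDs of 0.5 (about half the latent SD of a composed dataset, i.e.
moderate difficulty) but differs in gain (0.9–1.1) and bias (±0.75),
emulating raters who systematically score lower or higher. The default
thresholds (−1.6, −0.7, 0.5, 1.4) span less than the latent range and
widen the middle intervals, reproducing the central-tendency bias of real
Likert raters; that coarseness is what the Likert arm of the study loses
information to.

What the simulation does *not* model: real observers' fatigue and learning
across a session, scan-specific difficulty (e.g. anatomy that is hard to
judge regardless of dose), correlated errors between observers, and any
pixel-level property. Passing tests therefore demonstrate that the
*pipeline and statistics* behave correctly under a plausible observer
model, not that any particular ICC magnitude will be observed with human
readers — which is why the acceptance checks assert directions
(PC > Likert; high variation > low variation), never the human-data ICC
magnitudes.

## The pipeline

`run_study()` wires the design together: generate the pool (30 patients),
drop 5 random patients (emulating artifact exclusions), compose both
datasets over the remaining 25, then have every observer rate each dataset
with both methods — one PC session and one Likert pass in independently
shuffled order. Interobserver matrices are 50 × k (PC ranks or Likert
scores); intraobserver matrices are 25 × 2 over the originals present in
both datasets, using raw full-session ranks (1–50) rather than re-ranked
1–25 values, matching how repeated-rank plots are conventionally drawn
(the alternative is one `intraobserver_matrix()` call away). Every child
seed descends from `master_seed` by a documented splitting scheme
(successive draws from a generator seeded with the master), so a study is
a pure function of its configuration. Dataset order is fixed high-then-low
by default with a configuration switch, since the original design's order
is not material for simulated observers.

Open design points resolved here: the washout interval between sessions is
meaningless for memoryless simulated observers and is not modeled; excluded
patients are dropped uniformly at random before composition rather than by
modeling breathing artifacts, which reproduces the 30 → 25 flow without
inventing an artifact model.

## Reporting

`rank_spread_table()` gives the per-scan five-number rank summary over
observers plus the median Likert score; boxplot whiskers are min/max
because outlier fences are unstable with six observers. The median over an
even panel is the usual mid-mean and the color scale bins it at 0.5 steps.
`repeated_rank_table()` tabulates the two session ranks per original scan;
because source descriptions disagree on whether the companion plot is
colored by mean or median Likert score, the emitted table carries both.
Confusion matrices are written as long-format CSV (one row per score pair
per observer pair) with heatmap figures faceted over pairs. Plots are
views; the CSVs are the record, and re-rendering the same study produces
byte-identical tables.

## Problem sizes used in the checks

The shipped tests exercise: exhaustive permutations up to n = 8 for the
sorting engine; 1000 Monte-Carlo matrices at n = 50, k = 6 for ICC
calibration; 100 replicate full studies (default configuration) for the
directional reliability comparison; and 30000-draw Monte-Carlo checks of
the closed-form choice and rating probabilities. These sizes give
comfortable statistical resolution for the assertions made (e.g. a
standard error of ~0.003 on a probability of 0.76) while keeping the suite
quick to run.

## Known limitations

* The engine assumes the oracle answers every query; there is no partial
  ranking, tie handling, or Bradley-Terry-style score estimation from
  incomplete designs.
* Only the absolute-agreement, two-way random ICC is provided — no
  consistency ICC, one-way models, or chance-corrected kappa-type indices.
* The ranking captures relative preference only; it cannot certify that a
  scan is diagnostically sufficient in absolute terms, which is the one
  task where a Likert threshold retains value.
* Simulated observers are memoryless and mutually independent; real
  observer panels are not.
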