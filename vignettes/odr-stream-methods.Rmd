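---
title: "Methods: outlier-filtered Hoeffding tree learning for data streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outlier-filtered Hoeffding tree learning for data streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biosignal and clinical data streams (EEG, EMG, glucose monitoring, lab
panels) arrive continuously, and their measurements are routinely perturbed
by transmission glitches, sensor faults and typographical errors. For an
incremental classifier this noise is a double hazard: corrupted instances
degrade the model when trained on, yet a *recurring* pattern of abnormal
records — a rare phenotype, an orphan disease — is precisely what a clinical
model should learn rather than discard. `odrstream` implements a stream
classifier that filters its own training data online and decides, per
window, whether detected outliers are noise (discard) or a coherent rare
group (retain and learn).

## The learner: an incremental Hoeffding tree

The classifier is a Hoeffding tree: a decision tree grown one instance at a
time, where each leaf keeps sufficient statistics (class counts, per-class
Gaussian mean/variance summaries for numeric attributes, value-class counts
for nominal ones) instead of the instances themselves. Every `grace`
instances a leaf compares its best candidate split (gain $G_1$, in bits,
normalized by $\log_2 k$ so the averaged quantity has unit range) against
the runner-up ($G_2$) using the Hoeffding bound

$$\varepsilon = \sqrt{\frac{R^2 \ln(1/\delta)}{2n}},$$

splitting when $G_1 - G_2 > \varepsilon$: with confidence $1-\delta$ the
observed advantage is then real, however little of the stream has been
seen.

Near-ties ($G_1 - G_2 \le \varepsilon$) are resolved *adaptively*: the
model tracks the running mean of every $\varepsilon$ computed at a split
attempt, and a tie is broken in favor of splitting once the current
$\varepsilon$ falls below that mean — the leaf has, relative to the
model's own history, waited long enough. A classical fixed threshold
(`tie_mode = "fixed"`, $\tau = 0.05$) is available for comparison. A tie
split additionally requires a strictly positive best gain, so a leaf with
no observed signal at all never splits. Equal best gains break toward the lowest attribute
index; all numeric splits are binary over `n_thresholds = 10` equally
spaced candidate cut points strictly inside the observed range; nominal
splits are multiway.

Defaults ($\delta = 10^{-7}$, `grace = 200`) follow the values commonly
recommended for Hoeffding tree implementations in stream-mining toolkits.
New leaves start with fresh (zeroed) statistics; for prediction only, they
inherit the branch class distribution estimated at split time, so the tree
does not momentarily predict arbitrarily after splitting. A missing value
at a split attribute follows the branch that has received the most
training traffic (deterministic majority branch). Leaf prediction is
majority vote by default; `leaf_mode = "nb_adaptive"` chooses per leaf
between majority and naive Bayes, whichever has been more accurate at that
leaf so far.

## The filter: quartile fences per sliding window

The stream is consumed in windows of `omega = 1000` instances (step
`m = omega` by default, i.e. a partition; the step is exposed because
overlapping windows are equally well defined). For each numeric attribute
of a window, the lower and upper quartiles $Q_1, Q_3$ are estimated by
linear interpolation of order statistics (the standard "type 7" inverse
empirical CDF), and an instance is flagged when a value lies strictly
outside the Tukey fences

$$[\,Q_1 - \beta\,\mathrm{IQR},\; Q_3 + \beta\,\mathrm{IQR}\,],
\qquad \mathrm{IQR} = Q_3 - Q_1 .$$

$\beta$ is the tolerance factor (default 3; the interesting range in
practice is 1–5). Boundary values are clean; missing values never violate
a fence; the class label is never consulted (no leakage). Under the
default `rule = "any"` one violated attribute flags the instance;
`rule = "fraction"` requires a fraction $> \tau$ of numeric attributes to
violate. An alternative `fence_dialect = "paper"` replaces the lower fence
by $Q_1 + \beta\,\mathrm{IQR}$; it exists purely for auditing an
alternative printed form of the rule — it inverts the lower fence's
meaning and is never a sensible default.

Quartiles need data: windows require at least 4 instances. A stream tail
shorter than the window length is emitted as its own short window when it
still has 4 uncovered instances, and appended to the previous window
otherwise.

## Noise or rare group: the disposition rule

Let $O$ be the outlier set of a window. If $|O| < \mathrm{LOF_{min}}$
(default 10 per 1000-instance window) the outliers are *noise*: they are
excluded from training and appended to the **misclassified database**. If
$|O| \ge \mathrm{LOF_{min}}$ (ties retain: they favor keeping data) the
set is a candidate rare group and faces the **re-learning check**: a deep
copy of the learner is trained on the group and evaluated on the window's
clean instances; with $\mathrm{Err_{re}} \ge \mathrm{Err_{cur}}$
(inclusive — a group that changes nothing has earned nothing) the group is
noise, otherwise the copy becomes the live learner.

When the check runs is governed by `group_policy`:

* `"relearn_first"` (default): the check runs immediately, *before* the
  group can touch the live model. Noise never enters training, which is
  what keeps trees compact on noisy streams.
* `"train_immediately"`: the group is trained into the live learner at
  once and is adjudicated later, only when the running error breaches
  `err_max = 1 - acc_min`. This is the policy under which a coherent
  *off-distribution* rare class can be learned at all: such a group cannot
  demonstrate improvement on clean-only evaluation data (training it
  typically changes no prediction on clean instances, an exact tie, hence
  "noise" under the default policy), so a deployment that expects
  meaningful rare groups should select this policy.

Both policies are faithful to different halves of the source procedure
(the per-window pseudocode versus the error-gated prose); exposing the
choice, with the compact-tree variant as default, was the package's call.
The evaluation slice for the check is the current window's clean
instances — the most recent clean data, seen identically by both the live
learner and the copy before the check.

## ODR-A and ODR-R: the accuracy-gated mode switch

While the running prequential accuracy is below `acc_min` (default 0.75;
accuracy bootstraps at 0, so the first windows always use fences) the
controller runs **ODR-A**, the active fence detector, and uses its output
to maintain the misclassified database. Once accuracy reaches `acc_min`
and a rule model exists, windows are filtered by **ODR-R**: a binary
Hoeffding tree (classes `normal`/`outlier`) trained on the database's
positives against a seeded reservoir sample of clean instances (cap
5000). The rule model is cheap to apply (no per-window quartile
computation) and embodies the "rules generated from the misclassified
database" idea.

Three engineering safeguards matter in practice and are deliberate design
choices:

* **Small-sample training.** The database holds orders of magnitude fewer
  rows than the stream, so the rule model is trained for several epochs
  (about 12,000 presentations total) with conservative *fixed*
  tie-breaking; adaptive tie-breaking on a hundred rows splits on noise.
* **Degeneracy guard.** A rule model that flags more than half a window is
  discarded on the spot and the window falls back to fences; the model is
  retrained from the database afterwards.
* **Database purity.** Positives contributed by rule-model flags (rather
  than by fences) are admitted to the database only if they violate fences
  computed from the cumulative clean reservoir. Without this check the
  rule model's false positives feed back into its own training set and
  precision collapses.

Wall-clock time spent in each mode is accumulated as `t_odr_a` and
`t_odr_r` and reported (never asserted: timing is hardware-bound).

## Evaluation

Evaluation is prequential (interleaved test-then-train): each clean
instance is first classified, the cumulative confusion matrix updated, and
only then trained on. Instances the filter removes are neither tested nor
trained — the reported accuracy is over the data the learner actually
accepted, which is the quantity the filtering is supposed to improve.
Reported metrics are accuracy, Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with the conventional qualitative bands
(half-open on their upper bounds: $\kappa \cdot 100 \le 20$ "Slight",
$(20,40]$ "Fair", $(40,60]$ "Moderate", $(60,80]$ "Substantial",
$(80,100]$ "Almost perfect"; negative $\kappa$ is "Slight"), and tree size
(total node count). With zero recorded tests accuracy is defined as 0 and
flagged; a degenerate matrix with $p_e = 1$ has $\kappa = 1$ if agreement
is perfect and 0 otherwise — the value one sees for one-class predictors.
A monitoring score `cost_balance()` (weighted sum of min-max-normalized
error, tree size and time) summarizes sweeps; it never influences
learning.

## The synthetic generator

`generate_stream()` emulates a labeled biosignal-like stream with known
ground truth: uniform(0,1) numeric attributes labeled by a random
decision-tree concept (thresholds drawn in (0.3, 0.7) so regions stay
populated; leaf classes assigned so every class appears). Uniform
marginals make the clean quartiles exact ($Q_1 = 0.25$, $Q_3 = 0.75$,
$\mathrm{IQR} = 0.5$), so corruption is calibrated analytically: point
noise replaces *one* random attribute of a corrupted instance with
$Q_3 + \text{magnitude} \cdot \mathrm{IQR}$ (or the mirrored value below
$Q_1$), keeping truth flags unambiguous, and optionally flips the label.
A rare group is a tight Gaussian cluster (sd 0.02) centered beyond the
fences on every attribute, with its own dedicated class.

Reference conditions, fixed once: 20,000 instances, 5 attributes, 2
classes, concept depth 3, 5% noise at magnitude 10 with label flips,
window length 1000. What the generator does *not* emulate: concept drift,
heavy-tailed clean marginals, correlated attributes, structured missing
data. Tests passing on these streams show the mechanism works as
specified; they do not certify performance on real clinical streams,
where fences on heavy-tailed attributes will flag more aggressively.

## Numerical choices and edge cases

* Quantiles: type-7 interpolation, verified against a brute-force oracle;
  alternatives (nearest order statistic) change fences by $O(1/n)$ and are
  not exposed.
* Strict fence comparisons; boundary values are clean.
* $|O| = \mathrm{LOF_{min}}$ retains; $\mathrm{Err_{re}} =
  \mathrm{Err_{cur}}$ rejects.
* `err_max` is derived as `1 - acc_min`: one knob, two printed identities.
* Constant attributes have zero IQR and collapsed fences; equal values are
  *not* flagged (strictness), so constant columns are inert.
* Gains are clipped at 0; single-class leaves never split; variance
  accumulators are clamped non-negative against cancellation.
* CSV type inference is all-or-nothing numeric; ambiguous columns become
  nominal. The class attribute is always nominal.
* Reports separate deterministic results from wall-clock timing; identical
  config and seed reproduce the results byte for byte.

## Problem sizes used by the test suite

The suite exercises full study conditions: 10-seed paired runs at 20,000
instances for the noisy-stream comparison, 10,000 for the clean no-harm
check and the $\beta$ sweep (corruption magnitude 2 there, so the sweep
actually discriminates between fences), 3,000-instance streams for the
re-learning scenarios (an immature learner trained on 150 instances, a
600-instance group, a 1000-instance held-out slice — chosen so that
in-concept training can demonstrate strict improvement), plus exact
oracle comparisons on 1000 random windows and 500 random contingency
tables.

## Known limitations

* Fences are univariate per attribute; correlated multivariate outliers
  inside all marginal fences are invisible (no Mahalanobis-type fences by
  design).
* The rule model inherits the Gaussian observer's weakness for bimodal
  attribute distributions; its recall depends on the database's coverage
  of corruption modes.
* No concept-drift adaptation: a drifting concept will look like a surge
  of misclassification, not trigger any forgetting.
* Accuracy is measured over accepted instances; a filter that discarded
  hard-but-clean data would flatter itself. The no-harm property (clean
  streams: within one accuracy point of the plain learner, every seed) is
  the guard against that failure mode.
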