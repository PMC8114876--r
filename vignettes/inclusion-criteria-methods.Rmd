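---
title: "Methods: tuning metrics, inclusion criteria, and robustness analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tuning metrics, inclusion criteria, and robustness analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`driftmetrics` studies a methodological question in calcium-imaging
neurophysiology: how do the *inclusion criteria* used to declare a neuron
"responsive" reshape the tuning properties reported for a population?  The
package simulates populations of visual-cortex neurons responding to a
drifting-grating protocol, computes the standard tuning metrics both plainly
and with split-half cross-validation, applies five published responsiveness
criteria, and quantifies how selection by response robustness (coefficient of
variation, CV) moves population summaries.

Everything operates on a *trial-response table*: one row per trial of one
cell, carrying the evoked mean and max dF/F over the 2 s stimulus window and
the baseline mean and SD over the preceding 1 s gray period.  Real recordings
exported in this tabular form can be analysed identically; the package does
not ingest raw imaging data (no ROI segmentation, neuropil subtraction, or
dF/F computation), nor session files from public archives.

# Stimulus protocol

The default `grating_protocol()` is a 2 s grating followed by a 1 s
mean-luminance gray period, eight drift directions at 45° spacing crossed
with temporal frequencies (TFs) of 1, 2, 4, 8 and 15 Hz at a single spatial
frequency of 0.04 cycles/degree, 15 trials per condition plus 15 blank
sweeps, sampled at 30 Hz.  All of these are configurable; invariants
(distinct directions in [0, 360), positive distinct TFs, at least two trials
per condition) are enforced at construction.  Blank sweeps are generated in
the same number as grating repeats for symmetry; the count is configurable.

# Generative model

Each synthetic cell is a separable tuning surface times noise:

* **Direction**: a von Mises lobe
  $\exp\{\kappa(\cos(\theta-\theta_p)-1)\}$ at the preferred direction
  $\theta_p$, plus a second lobe at $\theta_p + 180^\circ$ scaled by a
  *symmetry* parameter $s \in [0,1]$, normalised so the surface equals the
  cell's amplitude exactly at $\theta_p$.  $s = 1$ gives a purely
  orientation-tuned cell (true DSI 0); $s = 0$ a fully direction-selective
  one (true DSI 1).
* **Temporal frequency**: a Gaussian in $\log_2$ TF centred on the preferred
  TF with bandwidth in octaves.
* **Noise**: independent Gaussian fluctuation on every trace sample
  (`baseline_sd`) plus one Gaussian gain per trial on the evoked response
  (`noise_sd`).  dF/F can and does go negative, exactly as extracted dF/F
  does; this deliberately exercises the undefined/out-of-range edge cases of
  the ratio metrics below.

Default parameter distributions (all configurable in
`population_config()`): peak amplitudes log-normal with median 12% dF/F
(sd-log 0.6), per-trial gain SD uniform in [0.02, 0.10] dF/F, direction
concentration $\kappa$ uniform in [1.5, 4] and TF bandwidth uniform in
[1, 2] octaves — sharply tuned layer 2/3-like cells whose preferred grid
condition is identifiable from 15 trials at these noise levels.  A
configurable fraction of cells (default 30%) is fully unresponsive
(amplitude 0), and per-area octave shifts of the preferred-TF distribution
give the six default areas distinct TF preferences so that selection-induced
rank flips can be exercised.  The shift values are modelling choices, not
claims about the areas.  Preferred directions and TFs are sampled
continuously, so a small fraction of cells lies near the midpoint between
two grid conditions where the preferred *grid* condition is intrinsically
hard to identify; parameter-recovery results should be read with that in
mind.

What the generator does **not** emulate: calcium-indicator dynamics (rise
and decay kernels), the right skew of real dF/F noise, slow drift,
correlated noise across cells, eye movements or behavioural state.  Tests
passing on this generator therefore validate the *analysis pipeline*, not
any claim about biology: in particular, real dF/F noise is right-skewed,
which stabilises ratio metrics in ways symmetric Gaussian noise does not
(see "Numerical behaviour of ratio metrics" below).

A table is fully reproducible from its config seed; the pipeline derives
one sub-seed per stage from a master seed by a fixed affine scheme, so
stages can be re-run in isolation.

# Metrics

For each cell, condition means are the arithmetic average of the per-trial
evoked means.  The **preferred condition** is the argmax over the
direction x TF grid, with ties broken deterministically to the smallest
direction, then the smallest TF (testing requires a total order; ties are
measure-zero under noise).

* **DSI** $= (R_{pref} - R_{null})/(R_{pref} + R_{null})$, with $R_{null}$
  the mean response at the direction opposite the preferred one, at the
  preferred TF.  No clipping is applied; a zero denominator yields an
  undefined sentinel (`NA`).
* **Global OSI** $= |\sum_\theta R_\theta e^{2i\theta}| / \sum_\theta
  R_\theta$ over the eight direction responses at the preferred TF (the
  doubled angle folds opposite directions onto one orientation).  A
  nonpositive denominator is undefined.
* **CV** $=$ sample SD / mean of the per-trial responses at the preferred
  condition (denominator $n-1$; with 15 trials, divisor 14).  A nonpositive
  mean is undefined, and such cells rank *least* robust wherever a total
  order over CV is needed.
* **Preferred TF averaging** is always on the octave scale:
  $2^{\mathrm{mean}(\log_2 tf)}$, respecting the logarithmic spacing of the
  grid.  This applies to population means, inclusion curves, and per-cell
  averaging across cross-validation iterations alike.
* **Reliability** $= (R_{pref} - R_{blank}) / (\sigma_{pref} +
  \sigma_{blank})$, comparing the preferred response to the blank sweeps.
  A zero denominator gives $\pm\infty$ by the sign of the numerator.

**Cross-validation**: per iteration, each condition's trials are split into
a selection half (`floor(n/2)` trials) that identifies the preferred
condition and an estimation half that provides the metric values at that
condition; results are averaged over 50 iterations (per-cell preferred TF
on the octave scale; the preferred direction is reported as the modal
selection-half preference, since directions are circular and cannot be
averaged).  Undefined iterations are dropped per metric with counts
reported.  One random permutation per iteration is shared across conditions
and cells: trials are exchangeable under the noise model, so this costs
nothing statistically, and it makes each cell's result independent of which
other cells share the table.  Cross-validation consequently requires a
balanced table (equal trials per condition), which the protocol guarantees.

The **cross-validated CV** (`cv_crossval`) is the SD across iterations of
the estimation-half preferred response divided by its mean across
iterations.  It measures the stability of the cross-validated response
estimate and shrinks roughly as $1/\sqrt{n/2}$ with the trial count $n$.
The plain CV is deliberately *not* used in trial-count sweeps: at small $n$
the argmax selection inflates the preferred-condition mean (the denominator),
so the plain subsample CV *rises* with trial count — an artefact of
selection, not of response stability.  The sweep reports both
(`mean_cv` cross-validated, `mean_cv_plain` plain) so the contrast is
visible.

# Inclusion criteria

The five published criteria are applied to the trial table exactly as
operationalised below; thresholds are strict inequalities and dF/F is a
fraction internally (0.10 = 10%; rendering as percent is
presentation-only).

1. Mean evoked response at the preferred condition > 10% dF/F.
2. In at least 50% of preferred-condition trials, the evoked response
   exceeds both (a) the trial's baseline mean + 3 x baseline SD and (b) 5%
   dF/F.  The baseline is the per-trial 1 s gray period preceding the
   grating — the only within-protocol window available; and "trials" are
   read as trials of the preferred condition, since the criterion concerns
   responsiveness at the best stimulus.
3. Paired t test between preferred-condition responses and blank-sweep
   responses at level $\alpha/n$ with $\alpha = 0.05$ and $n = 40$, the
   number of grating conditions in this protocol.  Pairs are formed by
   trial index and truncated to the shorter list; degenerate pairings
   (zero-variance differences) count as arbitrarily significant when the
   mean difference is nonzero and as null otherwise.  Note that because the
   *tested* condition is itself the argmax over the grid, the realised
   false-positive rate of this criterion on pure-noise cells is far above
   $\alpha/n$ — close to $\alpha$ in order of magnitude — a selection
   effect inherent to the published procedure, not an implementation
   artefact.  The package's tests verify both facts: a *fixed* condition
   passes at the corrected nominal level, and the criterion as published
   passes at the higher selection-inflated rate.
4. Some condition's mean response > 6% dF/F *and* reliability > 1, with
   $\sigma_{blank}$ the SD across blank sweeps and the denominator grouping
   $(\sigma_{pref} + \sigma_{blank})$ taken literally.
5. Maximum dF/F during the stimulus window of *any* grating trial > 4%.
   The 4% threshold follows the methods text of the source study
   descriptions; a 5% variant appears elsewhere in the same literature, and
   the threshold is trivially changed at the call site if desired.  Note a
   maximum over hundreds of trials makes this criterion extremely permissive
   under per-sample noise — simulated pure-noise populations pass almost
   surely.

`criteria_overlap()` reports per-criterion counts/percentages and all
$2^5$ intersection-region counts (the regions of a five-set Venn diagram).

# Robustness analyses

* **Inclusion curves**: cells of one area are ranked by ascending CV
  (undefined CVs last, ties by cell id); for each percentage $p$ the
  $\lceil p/100 \cdot n \rceil$ lowest-CV cells are summarised (octave-scale
  mean for TF; SEM in octaves for TF, linear otherwise).  The curve at 100%
  equals the unconditional area mean exactly.  The displayed grid starts at
  5%.
* **Deciles**: top/bottom deciles use ceiling counts.  Histograms exclude
  undefined values and report the excluded count.
* **CV-matched selection**: the $N$ lowest-CV cells whose mean CV is
  closest to a target, found by exhaustive search over all ranking prefixes
  — prefix means increase monotonically from the minimum CV to the
  whole-area mean, so the achieved mean is within one prefix step of the
  optimum.  Undefined-CV cells cannot contribute to a mean CV and are
  excluded; out-of-range targets clamp to the nearest endpoint with a
  warning.
* **Mann–Whitney comparisons**: two-sided test of the 10% most-robust cells
  against the *entire* population of the area (decile included, as the
  comparison is usually reported), with a Bonferroni threshold of
  $0.05/\text{n areas}$.  Completely tied groups give the maximal $p = 1$;
  groups with fewer than two defined values give an undefined sentinel.
* **Criterion vs CV-matched correlation**: for every (criterion, area)
  pair, the mean metric of criterion-selected cells and of the CV-matched
  population, correlated (Pearson) across pairs per metric.  Constant
  columns give an undefined sentinel.

# Numerical behaviour of ratio metrics

DSI, OSI and CV are ratios whose denominators can approach zero under
symmetric noise.  The package's policy, uniformly: exact-zero (or, where
specified, nonpositive) denominators are *undefined sentinels*, excluded
from population summaries with excluded counts logged; near-zero
denominators produce large or out-of-range values that are *kept* — they
are real outputs of the published definitions, not errors.  Consequently
population *means* of plain DSI over noise-dominated cells are heavy-tailed
(a near-zero denominator puts a Cauchy-like tail on the mean), and medians
are the stable summary for distribution-shift statements.  This tail is a
property of applying ratio metrics to symmetric zero-mean noise; real dF/F
distributions are right-skewed, which keeps denominators positive and means
stable.

Other numerical choices: argmax ties resolve lexicographically (smallest
direction, then TF); the stimulus/baseline windows use half-open sample
indexing so they tile the trace exactly; sample SDs use denominator
$n - 1$ throughout; cross-validation with an odd trial count puts
`floor(n/2)` trials in the selection half; subsampling `n` of `n` available
trials is the identity (no RNG consumed), so it reduces exactly to plain
cross-validation.

# Problem sizes

The shipped tests and the acceptance script size their simulations to run
on a laptop in a few minutes while keeping Monte-Carlo error well inside
the asserted margins: 10,000 pure-noise cells for the false-positive rate
of the blank-sweep t-test criterion, ~2,200 high-SNR cells for
preferred-condition recovery,
900 cells (six areas) for the criteria/robustness analyses, and 300
responsive cells for the 4–14 trial-count sweep at 50 cross-validation
iterations.  All are ordinary function arguments; larger runs only change
the config.

# Known limitations

* The simulator's Gaussian noise is symmetric; see above for why that makes
  plain-DSI population means heavy-tailed in ways real data is not.
* Criteria operate on the trial-table abstraction only; differences in the
  original studies' acquisition (indicator, anesthesia, stimulus length)
  are out of scope by design — the point of the analysis is to isolate the
  criteria themselves.
* Only one spatial frequency is modelled (as in the protocol); no
  tuning-curve fitting is performed, only grid-argmax preferences.
* Cross-validated metrics require balanced designs; unbalanced real exports
  must be rebalanced (e.g. truncated to the minimum trial count) upstream.
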