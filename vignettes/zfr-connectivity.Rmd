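---
title: "Onset detection and point-process connectivity with the zero-frequency resonator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Onset detection and point-process connectivity with the zero-frequency resonator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(zfrfc)
```

## The problem

Task fMRI analysis usually requires the experimental paradigm: the general
linear model regresses every voxel on the stimulus timing. When the timing
is unknown or unreliable — clinical populations, habituation, self-paced
behaviour — one would still like to know *when* each voxel responded and
which voxels responded *together*. `zfrfc` implements a point-process
approach: estimate the temporal onsets of BOLD events directly from each
voxel time course, then build functional connectivity from those discrete
events rather than from the full time series.

The forward model is the standard linear one,

$$ m[n] = s[n] * h[n] + \varepsilon[n], $$

where $s[n]$ is a sparse train of neuronal impulses, $h[n]$ the canonical
haemodynamic response function (HRF), and $\varepsilon[n]$ acquisition
noise. The impulse train is what we want back; an ideal impulse has equal
energy at all frequencies, including zero frequency, whereas the HRF and
wide-band noise do not. Filtering the course with a resonator whose double
pole sits at zero frequency therefore preserves event timing while
suppressing nearly everything else.

## The detector

The zero-frequency resonator is the recurrence

$$ y[n] = m[n] + 2\,y[n-1] - y[n-2], \qquad y[-1] = y[-2] = 0, $$

i.e. a cumulative sum applied twice (`zfr_filter()`). Its output grows
polynomially; the event information lives in local fluctuations, extracted
by subtracting a sliding mean over $2N_1 + 1$ samples
(`remove_local_mean()`):

$$ z[n] = y[n] - \frac{1}{2N_1+1}\sum_{k=-N_1}^{N_1} y[n-k]. $$

Positive zero-crossings of $z$ — sign changes from negative to
non-negative — mark the onsets (`positive_zero_crossings()`).

`detect_onsets()` composes these stages with two additional, deliberately
documented ingredients:

* **Input differencing** (`diff_order`, default 2). Applied to the raw
  course, the integrate-twice-then-demean cascade has a one-signed impulse
  response: an isolated haemodynamic bump produces a *negative* excursion
  of $z$ that returns to zero only one full window after the event, so the
  positive crossing would mark the response *offset*, some $N_1$ samples
  (tens of seconds) late. Zero-frequency filtering practice in speech,
  where this filter family originates, differences the input first for
  exactly this reason. With two differencing passes the cascade reduces
  algebraically to subtracting the local mean from the course itself, and
  the positive crossing lands on the rising edge of the response — about
  one TR after the neuronal impulse, which is the delay the haemodynamics
  impose in any case. Setting `diff_order = 0` recovers the literal
  cascade.
* **A salience guard** (`min_excursion`, default 1.5). Every crossing
  starts a non-negative run of $z$; the run's area measures how much
  evoked energy follows the crossing. Crossings whose run area falls below
  `min_excursion` standard deviations of $z$ are discarded. This removes
  two classes of spurious onsets: the shallow rebound at the offset of
  each response (an artefact of the finite window) and noise-born
  crossings. The default was fixed during development on simulated courses
  (400 samples, TR 2 s, 20 events, Gaussian noise at 0.2 of peak
  amplitude) as the value balancing missed events against false
  detections; `min_excursion = 0` disables the guard. Because the guard is
  relative to the scale of $z$, detection remains invariant to gain and
  offset changes of the course.

The window half-length $N_1$ is the one genuinely data-dependent
parameter: too short produces spurious onsets, too long misses events. The
package defaults to 15 samples for event-related and simulated data and
documents 11 as the usual block-design choice, with the parameter exposed
everywhere.

The baseline for comparison (`detector = "threshold"`) z-scores the course
and marks upward crossings of 1 — the conventional point-process rule. A
contiguous supra-threshold plateau yields one onset; we read "crossing the
threshold" as the upward crossing rather than every supra-threshold
sample, which is the reading that favours the baseline.

```{r single-impulse}
hrf <- canonical_hrf(tr = 2)
bold <- synthesize_bold(50, hrf, n_time = 150)
detect_onsets(bold, "zfr", n1 = 15)
```

## Connectivity from events

Two metrics are built on the detected onsets.

**Conditional rate** (`conditional_rate()`): the fraction of seed onsets
matched by a target onset within `max_delay` samples (default 2, i.e. 2 TR
at the usual 2 s). Matching is greedy, earliest-first and one-to-one, so
the rate is guaranteed to lie in $[0, 1]$; a many-to-one variant sits
behind `one_to_one = FALSE` for sensitivity analysis. Voxel-to-voxel
matching accepts delays only; when the seed is an external stimulus
reference the convention is $\pm 2$ samples (`allow_advance = TRUE`),
since the haemodynamic lag of the reference can run either way after
convolution. An onset-free seed leaves the rate undefined (`NA`), never 0,
so undefined cells drop out of group averages instead of biasing them.

**HSNR correlation** (`hsnr_correlation()`): around each seed onset
$n_c$ the signal-to-noise ratio is highest; the window
$[n_c - 2,\, n_c + w - 3]$ with $w = 6$ samples captures it. Pearson
correlation is computed between each seed window and the same temporal
window of the target, and the scores are averaged (unweighted) over
windows. Overlapping windows are kept separate, so a cluster of onsets
up-weights its epoch — documented behaviour; a length-weighted mean sits
behind a flag. Windows shorter than 3 samples or with zero variance are
skipped. The metric uses well under half of the time points yet tracks
full-length correlation (`pearson_fc()`) for co-activated pairs.

`roi_connectivity()` assembles these into matrices; `seed_map()` produces
voxel-wise maps, reusing the seed's HSNR windows for every target as the
definition requires. Maps are post-processed the conventional way:
`minmax_normalize()` to $[0,1]$, `top_fraction_threshold()` keeping the
top 20 % of defined voxels (ties at the cutoff all included, so the result
does not depend on sort order), and `cluster_filter()` removing connected
components below 16 voxels (8 for the 2-D synthetic grids). We read
"connected with at least *k* active neighborhood voxels" as the standard
cluster-extent rule — minimum connected-component size under the full
neighbourhood (8-connectivity in 2-D, 26 in 3-D) — with the per-voxel
neighbour-count reading available behind `rule = "neighbor_count"` and the
orthogonal neighbourhood behind `connectivity = "orthogonal"`.

## The synthetic generator

Every stage is validated against ground truth from the simulation module:

* `simulate_impulse_train()`: each sample is an event with probability
  0.07 — the sparse-event regime of auditory-style paradigms.
* `canonical_hrf()`: SPM-convention double gamma (peak delay 6 s,
  undershoot delay 16 s, unit dispersions, undershoot ratio 6, 32 s
  support), scaled to unit peak. Sampled at the TR; convolution is exact
  (shifted-kernel sums), because an FFT route leaves $10^{-16}$-scale
  residue in exactly-zero stretches that a double integrator happily
  amplifies into spurious crossings.
* `noise_spec()`: white Gaussian (`sigma` in signal units) or Rician —
  the magnitude of a complex Gaussian perturbation, the correct model for
  MRI magnitude images. The contrast-to-noise ratio is defined as peak
  clean amplitude above baseline divided by noise sigma; the definition is
  configurable because conventions differ.
* `simulate_phantom()`: a 100 × 100 voxel slice, 150 time points at TR
  2 s, two disk components (radius 20 voxels, centred left and right) each
  carrying an independent event train, a tissue baseline of 10, and Rician
  noise at CNR between 0.65 and 1. Inter-subject variability is emulated
  by seeded jitter of each component's centre and radius. Disk (hard-edge)
  profiles are the default so the ground-truth mask is unambiguous;
  Gaussian-tapered blobs are available.

What the generator does *not* emulate: scanner drift, physiological
(cardiac/respiratory) noise, motion, spatial autocorrelation of the noise,
and 3-D geometry beyond stacked slices. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
performance on acquired scans; in particular the white-noise conditions
flatter the threshold baseline, whose real weakness is structured
low-frequency noise.

## Evaluation protocol

`classify_detections()` matches detections to stimuli within a *right-
sided* window $[s, s + 2\,\mathrm{TR}]$ — the BOLD response always lags
the stimulus — by the same greedy one-to-one rule, and tallies TP/FP/FN/TN
over all samples, from which `sensitivity()` ($TP/(TP+FN)$) and
`specificity()` ($TN/(TN+FP)$) follow. Because events are sparse,
specificity systematically exceeds sensitivity. `jaccard()` quantifies
mask overlap; `split_scores()` contrasts co-activation with
non-co-activation score distributions. `detector_benchmark()` wraps the
Monte-Carlo loop:

```{r benchmark}
bm <- detector_benchmark(n_runs = 20, seed = 1)
glance(bm)
```

At these development conditions both detectors sit near a common
sensitivity ceiling set by event merging — two impulses closer than the
response rise produce a single crossing for either method — so their mean
sensitivities are close, while the resonator's specificity advantage is
consistent. The separation grows with the noise level, where the
threshold rule degrades quickly.

The phantom pipeline ties everything together: simulate 5 subjects,
compute each component's conditional-rate map against its stimulus
function, average the maps across subjects (the group-analysis
convention; averaging also smooths the discreteness of rates built from
roughly ten events), normalize, threshold, cluster-filter, and score the
recovered mask against the ground-truth component by Jaccard overlap. At
CNR 1 this recovers both components with Jaccard above 0.4 (typically
near 0.8); sizes were chosen so the run completes in about a minute on
one CPU. The vignette-scale version in the test suite uses a 40 × 40
grid with 3 subjects.

## Numerical choices and degenerate inputs

* Zero-crossing tie rule: $z[n] = 0$ counts as non-negative, so a touch
  from below registers at the first non-negative sample.
* After filtering, $|z|$ below $10^{-9}$ of its peak is snapped to zero:
  exactly-flat stretches of noiseless courses otherwise accumulate
  floating-point residue that fabricates crossings.
* The resonator errors out beyond $|y| = 10^{300}$ rather than silently
  overflowing.
* Boundary handling of the local mean: windows are clipped at the series
  ends and the mean taken over available samples; nothing is trimmed
  (fMRI courses are short), but onsets inside the first or last $N_1$
  samples carry a `boundary` flag.
* Zero-variance targets, onset-free seeds, and empty HSNR region sets
  yield `NA` (with a warning where interactive use is likely), never a
  silent 0; group averaging requires all subjects by default
  (`min_count`).
* Time is 0-based: `time_s = sample_index * tr`, matching the on-disk TSV
  convention.
* All randomness flows through explicit seeds in local RNG scopes; fixed
  seed means bit-identical output, and the CLI records config, seed and
  package version in a JSON sidecar next to every artifact.

## Known limitations

$N_1$ is chosen empirically, not adaptively; onsets are reported at sample
resolution (no sub-TR interpolation); the salience guard assumes the
course is long enough for $\mathrm{sd}(z)$ to estimate a scale; statistical
significance of connectivity values is out of scope, as is any
preprocessing (realignment, normalization, smoothing) — inputs are assumed
preprocessed, with the customary first three volumes discarded
(`discard_initial`).
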