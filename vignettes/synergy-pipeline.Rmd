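---
title: "Methods: muscle synergies, envelope complexity and spinal maps from BMCA sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle synergies, envelope complexity and spinal maps from BMCA sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergykit)
```

## The problem

During a brain motor control assessment (BMCA), a participant performs six
cued voluntary leg movements — bilateral, left and right hip
flexion/extension and ankle dorsi/plantarflexion — three trials each, while
surface EMG is recorded from ten lower-limb muscles (iliopsoas, rectus
femoris, tibialis anterior, extensor hallucis longus and gastrocnemius on
each side) at 600 Hz. For participants with spinal cord injury the protocol
is run twice per visit, with and without epidural spinal cord stimulation,
giving 36 trials; healthy controls contribute 18.

`synergykit` quantifies neuromuscular control in such sessions along three
axes:

1. **Complexity** of each muscle's activation envelope, via the Higuchi
   fractal dimension (HFD). Smooth, well-patterned activation approaches
   dimension 1; unstructured, noise-like activity approaches 2.
2. **Spinal motor output**: a rostro-caudal map of putative alpha
   motor-neuron pool activity over segments L1–S1, obtained by averaging
   muscle envelopes with myotomal-chart weights.
3. **Muscle synergies**: non-negative matrix factorization (NNMF) of the
   envelope matrix `E ≈ W A`, with model order chosen as the smallest k
   whose reconstruction explains 85% of variance, plus cosine-similarity
   matching of synergies across participants and a nonparametric group
   statistics battery.

No public recording accompanies this method, so the package carries a
protocol-faithful synthetic session generator with planted synergy
structure; every downstream stage is validated against that ground truth.

## Preprocessing chain

Each channel is band-pass filtered with a Butterworth design of total
order 6 from 10 Hz to 300 Hz. At 600 Hz sampling the printed upper edge
sits exactly at Nyquist, where a digital band-pass is degenerate, so the
applied edge is capped at 0.99 Nyquist (297 Hz); the passband response is
otherwise unchanged (50 Hz passes within 0.005%). Filtering is
forward–backward (zero phase) so envelope features are not delayed; we pad
by one second of odd-reflected signal before each pass, which drives the
DC leakage of the combined operation below 1e-6. A causal single-pass mode
is available.

Channels adjacent to the stimulation electrode (both iliopsoas channels by
default) carry stimulus artifacts — brief periodic pulses at the
stimulation rate — and are additionally run through a kernel-5 median
filter ("5th order" read as five samples), which removes isolated spikes
narrower than half the kernel while leaving the oscillatory EMG carrier
largely intact.

Instantaneous power is summarized as the RMS envelope over 100 ms
non-overlapping windows (60 samples at 600 Hz; a trailing partial window
is dropped). Trials are cut out of the envelope using the event
timestamps — stored as 0-based half-open `[start, end)` raw-sample
intervals, the unambiguous form of the two-tone cue annotations — keeping
only fully covered RMS windows, and are time-normalized to exactly 7000
points by linear interpolation on a uniform grid including both
endpoints. Linear interpolation is the simplest scheme consistent with
plain "interpolation", and it is exact on affine segments.

Amplitude normalization has two scopes. The default,
`per_muscle_session`, divides each muscle by its maximum over all trials
of the same condition in the session, so each muscle's session maximum is
1; this matches normalizing to the largest activity seen in a visit, the
only option when participants cannot produce a maximum voluntary
contraction. The `per_trial` scope min–max scales each muscle within each
trial. The two readings coexist in the source method description; we
default to the session-wise one and expose the other. Finally the three
repetitions of each movement/condition are ensemble-averaged into one
10 × 7000 envelope matrix.

## Higuchi fractal dimension

For a series `E(1..N)`, lag `k` and offset `m ≤ k`, the normalized length
of the subsampled sequence is

    L_m(k) = (1/k) * [ Σ_i |E(m+ik) − E(m+(i−1)k)| ] * (N−1) / (⌊(N−m)/k⌋ k)

and `L_k` is the mean over the k offsets. The HFD is the least-squares
slope of `ln L_k` against `ln(1/k)` — the "slope of the best fit", not a
pointwise ratio, which would be ill-defined at k = 1 and unstable
elsewhere. Lags with non-positive or non-finite `L_k` are excluded; if
fewer than two usable lags remain the series is reported as degenerate
(`NA` in tables) rather than given a number.

Two choices are ours to make and matter:

* **Input series.** HFD is computed on the time-normalized 7000-point
  trial envelopes (then averaged over the three trials), so values are
  comparable across trials of different durations.
* **Largest lag.** `k_max = 512`. The envelope is interpolated to 7000
  points from roughly 60 native RMS samples, so scales below the knot
  spacing (~117 samples) are piecewise linear and contribute slope ≈ 1
  regardless of the underlying roughness. Lags must span the knot scale
  for envelope-level noise to register: at `k_max = 64` noisy and smooth
  envelopes are nearly indistinguishable (measured HFD 1.06 vs 1.01),
  while at 512 they separate cleanly (1.52 vs 1.02). The analytic limits
  are unaffected: a linear ramp gives 1.000 exactly, white noise at
  N = 7000 averages 2.00, and Brownian motion 1.52 (theory: 2 − H = 1.5).

HFD is invariant to positive amplitude scaling (the log–log slope is
unchanged) and non-decreasing in added white-noise amplitude; both are
enforced as property tests.

## Spinal motor-output maps

Segment `j`'s estimated drive at sample `s` is the chart-weighted average

    S[j, s] = Σ_i k_ij E[i, s] / n_j

over the m = 10 muscles, with `n_j` the count of muscles loading segment
`j`. The operation is linear and non-negativity preserving, and is checked
against a literal double-loop oracle at 1e-12. The package ships a
**synthetic default chart** (`myotomal_chart_synthetic.csv`) assembled
from published Sharrard-derived innervation tables for these ten muscles
over L1–S1; it is an implementation default meant to keep the mapping
exercisable, not a clinical reference, and any user CSV with weights in
[0, 1] covering the montage is accepted. Charts naming segments outside
L1–S1 are rejected. Maps are computed from ensemble-averaged envelopes; by
linearity, averaging before or after mapping is equivalent.

## Synergy model and order selection

The synergy model is `E ≈ W A` with non-negative loadings (muscles × k)
and activations (k × time). `nnmf()` minimizes the Frobenius residual by
the classic multiplicative updates, whose objective is non-increasing —
asserted per iteration in tests via the residual trace. Initial factors
are uniform draws scaled by `mean(E)`; zero rows or columns of `E` are
lifted by machine epsilon so the updates stay well defined. One hundred
random restarts guard against local optima: restarts are screened at a
coarse tolerance (relative improvement 1e-4, ≤ 100 iterations) and only
the lowest-residual restart is refined to the full tolerance (1e-6, up to
1000 iterations), the usual economy in replicated NMF; ties go to the
earlier restart. Factor scale/permutation indeterminacy is fixed by
normalizing `W` columns to unit maximum (scale absorbed into `A`), and all
equality testing of factorizations is up to column permutation and
positive rescaling.

The variance-accounted-for curve reports

    R²_k = 1 − SSE_k / SST,   SST = Σ (E − mean(E))²

the conventional centered definition. The printed variant that normalizes
by the variance of the *reconstruction* is available as
`r2_method = "literal"` for comparison; it can exceed 1 and need not be
monotone, which is why it is not the default. The selected order is the
smallest k in 1..10 with `R²_k ≥ 0.85`; if no k qualifies the maximum is
returned with an explicit `threshold_met = FALSE` flag. Each candidate
rank uses a deterministic sub-seed, so the whole fit is reproducible from
one seed.

`synergy_fit()` wraps scan + selection + final fit into a classed model
object with `print`, `summary`, `coef` (the loadings), `fitted`,
`residuals`, `predict` (non-negative projection of new envelopes onto the
fitted loadings) and `plot` methods.

Synergies are extracted per (movement, condition) ensemble — matching the
stated 10 × 7000 analysis matrix — not on concatenated conditions.

## Matching and group statistics

Across participants, the template is the set whose synergies have the
highest summed optimal-assignment cosine similarity to everyone else's
(sum aggregation; equivalent to the mean for equal cohort sizes, ties to
the lowest index). Matching itself maximizes total cosine similarity over
one-to-one assignments, solved exactly (k ≤ 10, branch-and-bound over
permutations) and verified against exhaustive search. Activation
coefficients are compared by zero-lag correlation — mean-centered and
norm-scaled so values land in [−1, 1]. Sets with different selected k are
not padded; they are re-extracted at a common k before comparison.

The statistics battery mirrors the study design: Lilliefors
(composite KS) normality screening; paired Wilcoxon signed-rank for stim
vs no-stim (pairing unit: participant × session, per muscle and
movement; zero differences discarded; exact p for ≤ 25 nonzero pairs);
Mann–Whitney U for control vs stim (exact for small tie-free samples,
tie-corrected normal approximation otherwise); Bonferroni family-wise
threshold `alpha/m` with a one-significant-figure display convention
(0.05 over 67 tests prints as 0.0007); and a Welch-based TOST equivalence
test for R² values, with a default margin of 0.05 absolute R² (not stated
in the source method; chosen as a conservative "practically equal
explained variance" band and configurable). The family size m defaults to
the number of comparisons actually run, since the composition of the
original 67-test family is not derivable from the published tables. Exact
p-values are verified against sign-pattern / labeling enumeration, and
both rank tests are calibration-tested under the null (type-I error
within [0.03, 0.08] at nominal 0.05 over 200 replicates).

## The synthetic session generator

The generator is the package's study-condition bed, not a tuning knob.
Defaults: 4 synergies, envelope noise 5% of clean RMS, 6 s trials (the
protocol does not state a duration; 6 s is a realistic cued
flexion–extension span), symmetric loadings, no artifact unless
configured, seed-deterministic end to end.

* **Loadings**: non-negative columns with distinct dominant muscle groups,
  unit norm, pairwise cosine ≤ 0.8 (redrawn deterministically until the
  bound holds).
* **Activations**: raised-cosine bursts with disjoint supports staggered
  across the trial, with movement-specific gains — smooth, localized,
  non-negative drive. After assembly the generator equalizes each
  synergy's energy share *in the normalized-envelope domain* (a short
  fixed-point rescaling): amplitude normalization reweights muscle rows,
  and without this step a planted component can end up carrying an
  arbitrarily small share of the analyzed variance, making the planted
  order unidentifiable at the VAF threshold — i.e. not truly planted.
* **Raw signal**: the clean envelope `W A` amplitude-modulates a
  band-limited (10–250 Hz) broadband carrier whose RMS is normalized per
  100 ms window, so the preprocessing chain has realistic work to do and
  the planted envelope is recoverable to correlation > 0.99 in active
  channels. Envelope noise is drawn per 100 ms block so the RMS stage
  inherits it directly. A small sensor-noise floor keeps silent channels
  nonzero.
* **No-stim SCI condition**: noise-only envelopes — absent volitional
  drive, reproducing the high-complexity, high-dimensionality regime that
  motivates the stimulation contrast.
* **Artifact model**: periodic biphasic pulses (28–44 Hz, configurable
  width/amplitude) added to the iliopsoas channels under stimulation,
  exercising the median-filter path.

What the generator does **not** emulate: motor-unit physiology, volume
conduction and electrode crosstalk, burst timing variability across
trials, nonstationary noise, or movement artifacts. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
the stated noise model — not that it would resolve every ambiguity of
clinical recordings.

## Problem sizes used in validation

The shipped tests and the acceptance script run: full-protocol sessions
(18/36 trials at 6 s, or shorter trials where only shapes are under
test); planted-order recovery over seeded sessions with k cycling through
2–4 at the full 100-restart VAF scan over k = 1..10; a 15-session
synthetic SCI cohort for the paired complexity contrast; 200-replicate
null calibrations of both rank tests; and 100/50-seed averages for the
white-noise/Brownian HFD limits. These sizes were chosen to make each
claim statistically meaningful while keeping a complete run in the tens
of minutes on a single core.

## Known limitations

* The default myotomal chart is a synthetic stand-in; segment-level
  conclusions require the user's own validated chart.
* VAF-threshold order selection is sensitive to the normalization scope:
  session-wise scaling changes the row weighting of `E` and hence the
  effective basis (the planted basis must be compared in normalized
  units, see `truth_basis()`).
* The literal printed R² variant is provided but not recommended.
* Whole trials are segmented; flexion/extension sub-phases are not
  separated because the tone annotations do not identify them.
* HFD values depend on `k_max` and on the 7000-point interpolation; they
  are comparable within this pipeline's conventions, not across papers
  with different conventions.
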