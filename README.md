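# synergykit

Quantitative analysis of multi-channel surface EMG (sEMG) from brain motor
control assessment (BMCA) sessions — the standardized protocol of cued
voluntary leg movements used to track recovery of motor control, e.g.
under epidural spinal cord stimulation after spinal cord injury (SCI).

Ten lower-limb muscles (bilateral iliopsoas, rectus femoris, tibialis
anterior, extensor hallucis longus, gastrocnemius) are recorded at 600 Hz
over 6 movements × 3 trials per condition (18 trials for controls, 36 for
SCI participants tested with and without stimulation). From these
recordings the package computes three complementary descriptions of
neuromuscular control:

* **Envelope complexity** — the Higuchi fractal dimension (HFD) of each
  muscle's RMS envelope. For a series `E(1..N)` the average normalized
  curve length at lag k,
  `L_k = (1/k) Σ_m (1/k)[Σ_i |E(m+ik) − E(m+(i−1)k)|]·(N−1)/(⌊(N−m)/k⌋k)`,
  scales as `k^(−HFD)`; the dimension is the slope of `ln L_k` vs
  `ln(1/k)`. Smooth, patterned activation → HFD near 1; noise-like
  activity → near 2.
* **Spinal motor-output maps** — estimated alpha motor-neuron pool drive
  per lumbosacral segment, `S_js = Σ_i k_ij E_is / n_j`, using a
  configurable myotomal chart (muscles × segments L1–S1).
* **Muscle synergies** — non-negative matrix factorization `E ≈ W A`
  (multiplicative updates, 100 random restarts), with the synergy count
  selected as the smallest k whose reconstruction reaches R² ≥ 0.85 over
  k = 1..10; synergies are matched across participants by
  optimal-assignment cosine similarity
  `R = Wᵀa·Wb/(‖Wa‖‖Wb‖)` and activation coefficients by zero-lag
  correlation.

A nonparametric statistics battery (Lilliefors normality, paired Wilcoxon
signed-rank for stim vs no-stim, Mann–Whitney U for control vs SCI,
Bonferroni family-wise correction, TOST equivalence on R² values) mirrors
the study design. Because no public recording accompanies the method, a
protocol-faithful synthetic session generator with planted synergy
structure (`synthesize_session()`) backs all validation.

The preprocessing chain: order-6 Butterworth band-pass 10–300 Hz
(zero-phase; upper edge capped just below Nyquist), kernel-5 median filter
on stimulation-artifact channels, 100 ms non-overlapping RMS windows,
trial segmentation from event timestamps, time normalization to 7000
points, amplitude normalization, ensemble averaging.

## Worked example

```r
library(synergykit)

sim <- synthesize_session(generator_config(n_synergies = 3, seed = 7),
                          "control")
sim$session
#> BMCA session record
#>   participant SYN-7, session 1, group control
#>   10 channels x 70500 samples @ 600 Hz (117.5 s)
#>   18 events, conditions: control

pp  <- preprocess_session(sim$session)
fit <- synergy_fit(pp$ensembles[["BL-Hip|control"]], k_range = 1:6,
                   n_restarts = 100, seed = 7)
fit
#> Muscle synergy model (NNMF)
#>   movement: BL-Hip  condition: control
#>   10 muscles x 7000 timepoints, k = 3 synergies
#>   R^2 = 0.9937 (threshold 0.85), Frobenius residual 4.855
round(fit$r2_curve, 3)
#>     1     2     3     4     5     6
#> 0.365 0.697 0.994 1.000 1.000 1.000
```

The VAF curve crosses the 85% threshold exactly at the planted order
(k = 3), and the recovered loadings match the planted basis (expressed in
normalized-envelope units) almost perfectly:

```r
m <- match_and_reorder(coef(fit), truth_basis(sim$truth))
round(m$similarities, 3)
#> [1] 0.992 0.996 0.984
```

Complexity tables and the corrected threshold used when reporting many
cells:

```r
head(complexity_table(pp), 3)
#>   muscle movement condition      hfd n_trials
#> 1  L-EHL BL-Ankle   control 1.024798        3
#> 2    L-G BL-Ankle   control 1.037705        3
#> 3   L-IL BL-Ankle   control 1.069682        3
bonferroni_alpha(0.05, 67)$display
#> [1] 7e-04
```

Smooth, synergy-driven envelopes sit near HFD ≈ 1; noise-only
("no volitional drive") envelopes in SCI no-stim conditions come out far
higher, which is what the paired signed-rank battery detects.

`run_full_analysis()` chains every stage over a list of sessions and can
serialize all tables (TSV + JSON manifest) to an output directory.

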