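# mwbreast

Simulation and analysis of transmission-based microwave breast imaging,
built around the question: can the **contralateral asymmetry** of
breast-average relative permittivity separate cancer patients from healthy
participants?

Microwave imaging exploits the dielectric contrast of tissues: relative
permittivity εr tracks water content, so fat is low, fibroglandular tissue
high, and tumors higher still. The simulated instrument holds the breast
between two planar antenna arrays (247 transmitters, 240 receivers, imaging
area ≈ 21 cm × 16 cm) and sweeps 0.1–8 GHz through more than 2000
transmitter–receiver paths. For each path, the spectrum is transformed to
the time domain with an inverse chirp Z-transform, the envelope peak is
compared to an equal-length air reference, and the arrival-time difference
Δt over path length L inverts to a path-average permittivity

    εr = (1 + c·Δt / L)²,    L = √(d² + offset²),

which is painted onto a disk footprint on the mid-plane image. Images are
segmented (2-means breast mask; fat/gland tissue split; fixed threshold
regions R1 ≤ 8 < R2 ≤ 13 < R3 ≤ 18 < R4) and summarized per breast. The
detection statistic is the per-view contralateral ratio
ρ = max(ε̄_L, ε̄_R) / min(ε̄_L, ε̄_R); clinically, the CC-view group means
are about **1.05 for healthy participants and 1.15 for cancer patients**.

Because no clinical raw data are public, the package includes a calibrated
synthetic-cohort generator (bilateral four-view phantoms, density
categories A–D, healthy glandular asymmetry, unilateral multiplicative
tumor inclusions) and reproduces the analysis end to end on synthetic
cohorts of the study's size (20 healthy, 14 cancer).

## Worked example

```r
library(mwbreast)

grid    <- grid_spec(pixel_mm = 4)                     # 53 x 40 mid-plane grid
subject <- generate_subject("S1", "cancer", density = "C", grid = grid,
                            seed = 42L, tumor_contrast = 1.0)
ctx     <- scan_context(grid, snr_db = 30)             # array, sweep, footprints
result  <- analyze_subject(subject, ctx, seed = 1L)    # forward -> recon -> segment
result$summary
```

```
 subject_id  group density view_type      rho       delta true_rho true_delta
         S1 cancer       C        CC 1.010793 -0.01073511 1.053913 0.05249753
         S1 cancer       C       MLO 1.058231  0.05658390 1.066765 0.06460807
```

`rho` is the contralateral ratio recovered from the reconstructed images and
`true_rho` the same ratio on the phantom ground truth; single-subject
reconstructions carry a few percent of noise (here the CC ratio comes out
low), while cohort means recover the injected group means to well within
±0.03. `result$scans` holds the per-view panel (breast average, plate
separation, breast-area ratio):

```
 view side  eps_bar     d_mm area_ratio true_eps
  LCC    L 10.72567 55.38192  0.3226415 12.26516
  RCC    R 10.84143 55.38192  0.3056604 11.63774
 LMLO    L 11.16742 55.38192  0.2509434 12.30138
 RMLO    R 10.55291 55.38192  0.2452830 11.53148
```

The full study lives under `analysis/` as numbered drivers writing to
`results/`:

1. `01_simulate_cohort.R` — calibrates the generator so the ground-truth
   mean CC ratios equal 1.05 (healthy) and 1.15 (cancer), and writes the
   cohort ground truth.
2. `02_reconstruct_segment.R` — images and segments all 136 scans
   (4 views × 34 subjects) at 30 dB SNR.
3. `03_cohort_stats.R` — ratio tables, one-way and two-way (Type-II)
   ANOVA, and pooled t-tests. On the default seeds it prints
   `Recovered CC means: healthy 1.047, cancer 1.154 (clinical: 1.05, 1.15)`
   with the healthy/cancer CC difference significant
   (`t = -4.35, p = 0.00013`).

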