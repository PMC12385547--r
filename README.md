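# spinaldti

Simulation and reliability analysis of high-resolution **axial spinal-cord
diffusion tensor imaging** (sDTI) at the C2 level.

Tract-specific DTI of the cervical cord — pyramidal tracts (PT), dorsal
columns (DC), anterior horns (AH) — can only enter clinical use if its
metrics are reproducible across repeat scans and scanners. Raw data for
such protocols are rarely public, so this package provides the entire
chain as a tested, reproducible artifact for methods researchers:

1. **Phantom generator** — a single 5 mm axial slice (128×128 at
   0.78×0.78 mm²): elliptical cord with a gray-matter butterfly inside a
   bright CSF ring, per-region diffusion tensors (known ground truth),
   Rician noise, breathing-like anterior–posterior motion, six
   diffusion-encoding directions e1 = (1,0,1) … e6 = (−1,1,0) at
   b = 750 s/mm² plus b0, 32 repetitions; and a cohort layer
   (participants × scanners × sessions) with explicit variance
   components so the true ICC is known by construction.
2. **Post-processing** — cropping to the intra-spinal space,
   motion correction from midsagittal intensity profiles, repetition
   averaging, exact log-linear tensor fit
   (`S = S0·exp(−b·ĝᵀDĝ)`), FA/MD/AD/RD maps
   (`MD = (λ1+λ2+λ3)/3`, `AD = λ1`, `RD = (λ2+λ3)/2`,
   `FA = √(3/2)·√Σ(λi−λ̄)²/√Σλi²`), interpolation to 0.2×0.2 mm².
3. **ROI extraction** — automated cord ellipse from image moments,
   600-point angular FA profile, posterior-horn exit angles, six 1.05 mm
   circular tract ROIs (left/right PT, DC, AH), per-region means.
4. **Reliability battery** — paired t-tests, paired Cohen's d with
   effect-size bands, Bland–Altman analysis (LOA = D ± 1.96·SD),
   within-participant CV with <10% / 10–20% / >20% bands, and single and
   average ICC from two-way ANOVA mean squares in both consistency and
   absolute-agreement forms with F-based 95% CIs and Cicchetti/Koo
   classification.

## Worked example

```r
library(spinaldti)

# a noise-free session with known ground truth
ph  <- generate_phantom(phantom_spec(noise_sigma = 0, motion_model = "none",
                                     n_repetitions = 1))
res <- process_stack(ph$stack)   # crop -> motion-correct -> average ->
                                 # tensor fit -> interpolate -> ROIs
res$roi$metrics$per_region
```

```
   region metric value
   AH     FA     0.349
   DC     FA     0.856
   PT     FA     0.820
   AH     RD     0.850   (10^-3 mm^2/s)
   DC     RD     0.345
   PT     RD     0.410
   AH     AD     1.500
   DC     AD     2.660
   PT     AD     2.570
   ...
```

The extracted FA equals the construction truth (DC 0.856, PT 0.820,
AH 0.349) to within 0.01 — the phantom is the oracle for the full chain.
The battery itself reproduces published n = 16 summary arithmetic, e.g.
mean 0.603, SD 0.023, n = 16 → 95% CI (0.591, 0.615), and
D = −0.003 ± 0.023 → LOA (−0.048, 0.042), both exact at 3-decimal
report rounding.

A full simulated study runs end to end in ~2 minutes:

```r
man <- run_full(run_config(phantom = phantom_spec(n_repetitions = 32),
                           cohort  = cohort_spec(n_participants = 16),
                           seed = 1))
round_reliability_table(man$report)   # Tables-style report, one row per
                                      # comparison x metric x region
```

## Analysis workflow

Numbered drivers under `analysis/` narrate the study and write their
outputs to `results/analysis/`:

| script | stage |
|---|---|
| `01_simulate.R` | cohort + example session (NIfTI / bvals / bvecs) |
| `02_preprocess.R` | crop, motion correction (shifts CSV), averaging |
| `03_fit_tensors.R` | tensor fit, metric maps, interpolation |
| `04_extract_rois.R` | ellipse, exit angles, ROI geometry, region means |
| `05_reliability.R` | full 16×2×2 study + reliability table + BA plots |
| `06_validate_tables.R` | worked-example validation of printed tables |

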