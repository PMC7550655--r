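# tumorQMRI

Quantitative MRI analysis of tumor treatment response in preclinical
(xenograft) studies: segmented bi-exponential **IVIM** fitting of
multi-b-value diffusion MRI, voxelwise **R2\* relaxometry** from multi-echo
gradient-echo decay, caliper **tumor volumetrics and inhibition rates**, and
the longitudinal **group statistics** used in such studies (one-way ANOVA —
from raw samples or directly from printed mean ± SD cells —
Student–Newman–Keuls post hoc, Kolmogorov–Smirnov normality screening,
Pearson correlation with strength labels). A synthetic phantom and
study-table generator with Rician noise makes the whole pipeline testable
without scanner data.

It is written for imaging scientists and analysts who need a transparent,
scriptable reimplementation of the vendor-workstation processing chain
behind published IVIM/BOLD tumor-response studies.

## The models

Intravoxel incoherent motion separates tissue water diffusion from
capillary pseudo-diffusion via a bi-exponential decay over the diffusion
weighting b:

    SI(b) = S0 [ (1 - f) exp(-b D) + f exp(-b D*) ]

with D the true diffusion coefficient (mm²/s), D* ≫ D the pseudo-diffusion
coefficient, and f the perfusion fraction. The estimator is the standard
*segmented* method: D by log-linear least squares over the high-b segment
(b > 200 s/mm², where pseudo-diffusion is negligible), then f and D* by
box-constrained nonlinear least squares with D frozen and the scale S0
profiled out in closed form.

R2\* relaxometry fits ln SI(TE) = ln S0 − R2\*·TE by least squares over a
multi-echo train; R2\* (1/s) rises with deoxyhemoglobin and serves as a
hypoxia surrogate. Tumor volume uses the caliper formula V = a²b/2, and the
inhibition rate is (V_control − V_treated)/V_control × 100%.

Default protocols are the reference study's 13 b-values (0–1500 s/mm²) and
16 echo times (3.4–92.1 ms). The study's printed summary tables (4
treatment groups × 4 time points, n = 8) ship as checksummed plain-text
fixtures and drive both the synthetic study generator and the reproduction
harness.

## Worked example

Fit one noisy tumor voxel simulated at the baseline tissue parameters
(D = 0.556×10⁻³ mm²/s, D* = 8.53×10⁻³ mm²/s, f = 16.75%), b = 0 SNR 50:

```r
library(tumorQMRI)
prot   <- defaultDiffusionProtocol()
truth  <- ivimParams(S0 = 1000, D = 0.556e-3, Dstar = 8.53e-3, f = 0.1675)
signal <- addNoise(ivimSignal(truth, prot), noiseSpec("rician", 20, seed = 42L))
fitIvimVoxel(signal, prot)
#> IVIMFitResult (converged): boundary 200 s/mm^2, 6 low-b + 6 high-b points, rss 5140
#> IVIMParams: S0 = 1020, D = 0.6012 x 1e-3 mm^2/s, D* = 16.31 x 1e-3 mm^2/s, f = 12.7%
```

D comes back within 8% of truth, f within a few points, and D* — always
the unstable IVIM parameter — within a factor of two; at map level the ROI
means tighten to a fraction of a percent (see the methods vignette for the
precision budget).

Re-analyse a printed table row from its summary cells alone (here the
strongest R2\* treatment response, group D over time):

```r
anovaFromSummary(data.frame(mean = c(24.74, 21.41, 19.64, 17.30),
                            sd   = c(0.65, 0.81, 0.72, 0.84), n = 8))
#> One-way ANOVA: F(3, 28) = 136.6, p = 8.049e-17
```

which matches the published F = 136.315 to 0.2%. And the week-3 inhibition
rates recomputed from the packaged volume table:

```r
subset(reproduceTables(), statistic == "inhibition_rate")
#>          statistic quantity group recomputed printed      rel_dev pass
#> 25 inhibition_rate   volume     B   23.79304    23.8 0.0002925579 TRUE
#> 26 inhibition_rate   volume     C   27.13983    27.1 0.0014699108 TRUE
#> 27 inhibition_rate   volume     D   47.35526    47.4 0.0009438686 TRUE
```

i.e. 23.8%, 27.1% and 47.4% at the printed precision: the free drug at
4 mg/kg inhibits least, and the nanoparticle formulation at the same dose
roughly doubles the effect.

## Command line

A thin wrapper over the exported functions lives at `inst/cli/qmri.R`:

```sh
Rscript inst/cli/qmri.R simulate-phantom --seed 3 --out-prefix ph/
Rscript inst/cli/qmri.R fit-ivim --in ph/ivim.nii.gz --mask ph/mask.nii.gz \
        --protocol ph/protocol.json --out-prefix maps/
Rscript inst/cli/qmri.R study-stats --in study/study.csv --quantity D --by timepoint --group D
Rscript inst/cli/qmri.R reproduce-tables
```

Volumes are NIfTI-1 (`.nii`/`.nii.gz`), tables CSV, protocol sidecars JSON;
every stochastic subcommand requires `--seed` and logs a run manifest.
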