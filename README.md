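# redoxscreen

Label-free metabolic imaging analysis for screening iPSC-derived
cardiomyocytes maturing on hydrogel substrates.

Cardiomyocytes shift from glycolytic to oxidative metabolism as they
differentiate and mature, and two autofluorescence readouts track that
shift without any label: the **optical redox ratio (ORR)** from widefield
NAD(P)H / FAD intensity imaging, and **NAD(P)H fluorescence lifetimes**
from TCSPC FLIM. `redoxscreen` implements both analysis chains as tested,
reusable R code, plus a synthetic-data generator with known ground truth
so the whole pipeline can be validated end to end on a laptop.

## What it computes

**Widefield ORR per field of view.** Rolling-ball illumination correction
(grayscale opening with a disc, in compiled code), Otsu cell masking,
mean cell intensity of both raw channels, gel background from three
cell-free regions, and the background-normalized redox ratio

```
I_N = I_cell,NAD(P)H / I_bg,NAD(P)H     I_F = I_cell,FAD / I_bg,FAD
ORR = I_N / (I_N + I_F)
```

Normalizing each channel to its own gel background cancels lamp drift,
exposure changes and substrate autofluorescence; ORR is invariant to
per-channel global gain and lies in (0, 1).

**Pixelwise biexponential FLIM.** Photon-count decays are fitted to

```
I(t) = A * [ a1 * exp(-t/tau1) + a2 * exp(-t/tau2) ] (x) IRF + C
```

with 3x3 spatial binning, a >1000-photon criterion, bounded
Levenberg-Marquardt on a Poisson likelihood objective, IRF shift
alignment, and the mean lifetime `tau_m = a1*tau1 + a2*tau2` (short
component = free NAD(P)H, long = protein-bound).

**Screen statistics.** Per-formulation / per-group ORR trajectories over
imaging days, day-vs-day percent change, and Welch's unequal-variance
t-test (implemented from the closed-form formulas) for efficiency-group
separation.

**Synthetic data.** Gaussian IRFs, Poisson decay cubes, vignetted
two-channel fields with elliptical cells and shot + read noise, and whole
longitudinal plates driven by per-group ORR trajectories — all
deterministic functions of (parameters, seed), with ground truth attached.

## Worked example

```r
library(redoxscreen)

# a two-group screen: high- vs low-efficiency cultures on 2 formulations,
# 3 replicate gels, imaged on days 6, 8, 10, 16
days <- c(6L, 8L, 10L, 16L)
forms <- data.frame(formulation = c("7C-3I 2", "10C 4"),
                    stiffness_kpa = c(10, 4),
                    group = c("high", "low"))
traj_hi <- default_orr_trajectory(days)          # rises to day 10, falls by 16
traj_lo <- traj_hi - 0.05                        # low-efficiency offset
des <- plate_design(forms, days,
                    groups = list(high = traj_hi, low = traj_lo),
                    replicates = 3, seed = 7)
plate <- simulate_plate(des)
recs <- process_plate(plate)                     # full widefield workflow
tab <- aggregate_screen(recs, des)

compare_groups(tab, day = 6, group_a = "high", group_b = "low")
#>   group_a group_b day    mean_a    mean_b mean_difference percent_change
#> 1    high     low   6 0.5570528 0.5043293     -0.05272344      -9.464713
#>          t       df    p_value n_a n_b
#> 1 4.026018 3.969984 0.01602344   3   3

percent_change(tab, group = "high", day_a = 6, day_b = 16)$percent_change
#> [1] -6.536086
```

The Welch test separates the two efficiency groups at the
cardiac-progenitor stage (difference −0.053 ORR, p = 0.016 with n = 3
gels per side), and the high-efficiency group's ORR drops by ~6.5% from
day 6 to the differentiation timepoint, consistent with the simulated
trajectory (0.55 → 0.52 encodes −5.45%) within the replicate jitter of
three gels.

A FLIM example:

```r
irf <- make_irf(fwhm = 240)                       # 240 ps FWHM, 256 bins/12.5 ns
truth <- decay_ground_truth(tau1 = 400, tau2 = 2500, a1 = 0.7,
                            photons_target = 150)
cube <- simulate_decay_cube(truth, irf, shape = c(32, 32), seed = 1)
fit <- fit_cube(cube, irf, photon_threshold = 1000)
fit
#> FLIM fit result: 32 x 32 pixels, 900 valid fits
#>   median tau1 407 ps, tau2 2510 ps, a1 0.705, tau_m 1035 ps, chi2r 0.955
```

Median recovered lifetimes land within a few percent of the simulated
truth (400 / 2500 ps, a1 = 0.7, true tau_m = 1030 ps) at ~1350 photons
per binned pixel.

A thin command-line interface over the same functions is installed at
`inst/cli/redoxscreen.R` (subcommands `simulate-plate`, `simulate-decay`,
`flim-fit`, `ori-run`, `report-run`).

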