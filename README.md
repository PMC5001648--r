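# opmbeam

Simulation toolkit for quantifying what **on-scalp MEG sensor arrays**
(optically-pumped magnetometers and kin, ~4 mm from the scalp) gain over a
conventional cryogenic **SQUID helmet** (inner coils ≥ 1.7 cm away), aimed
at MEG methodologists and sensor-array designers.

The package builds a synthetic head (scalp, folded cortical surface with
one surface-normal current dipole per vertex, fiducials), constructs the
arrays under comparison (a 275-channel radial axial-gradiometer helmet, a
scalp-projected magnetometer array, proportional EEG-layout variants with
81/329/1293 channels), computes dipole lead fields with the Sarvas
conducting-sphere formula under a multiple local sphere model, simulates
recordings `m = l q + e` with Gaussian dipole time courses and white
sensor noise, and reconstructs sources with a linearly constrained
minimum-variance (LCMV) beamformer

```
w_j = (C + mu Sigma)^-1 l_j / (l_j' (C + mu Sigma)^-1 l_j),   q_hat_j = w_j' m,
```

where `C` is the demeaned sample data covariance, `Sigma = sigma_e^2 I`
and `mu = 0.001`. On top of that it drives five experiments:

1. **Sensitivity maps** — per-vertex Frobenius norm `f_j = ||l_j||` of the
   lead field and the gain ratio `f_OPM / f_SQ` (equal noise floors).
2. **Reconstruction accuracy** — Pearson `r(q_j, q_hat_j)` per vertex.
3. **Brain-noise rejection** — five interfering dipoles per target
   (proximity shells or deep-source configuration) and the leakage
   `r(q_int_k, q_hat_j)`.
4. **Forward-model error** — perturbations `delta_l` confined to the
   hyperplane orthogonal to `l` with exactly calibrated fractional error
   `||delta_l||/||l||`, applied to the weights only.
5. **Spatial resolution** — two temporally orthogonal dipoles;
   reconstruction leakage `|r(q_hat_k, q_hat_n)|` versus separation and
   the minimum separation at which it drops below `1/sqrt(2)`.

See `vignettes/opm-beamformer-simulations.Rmd` for the model details,
parameter defaults, the synthetic-head design and its limitations.

## Worked example

```r
library(opmbeam)

head  <- build_synthetic_head(cortex_vertex_target = 5000,
                              scalp_vertex_target = 1500)
study <- build_study(head = head, squid_args = list(n_channels = 120))
study
#> opm_study: 4902 dipoles; arrays: squid (120 ch), opm (120 ch)

src <- study$sources
j <- which.min(src$depth)   # shallowest dipole
channel_snr(study$leadfields$squid[, j], 5e-9, 50e-15)  # helmet:   0.59
channel_snr(study$leadfields$opm[, j],   5e-9, 50e-15)  # on-scalp: 2.76

vs  <- with_seed(1, sample(nrow(src$positions), 25))
tbl <- run_recon_accuracy(study, vs, n_samples = 20000, seed = 42)
r   <- tbl[tbl$metric == "r_recon", ]
aggregate(value ~ array, r, function(v) round(c(mean = mean(v), min = min(v)), 3))
#>   array value.mean value.min
#> 1   opm      0.960     0.683
#> 2 squid      0.836     0.416
```

The shallowest dipole is ~4.7x more visible to the on-scalp array, and
across 25 random cortical dipoles the mean reconstruction correlation
rises from 0.84 (helmet) to 0.96 (on-scalp) at identical source and noise
settings — the proximity advantage the package exists to quantify. (This
example uses a reduced 120-channel study so it runs in under a minute;
defaults reproduce the full 275-channel, 21,318-dipole configuration.)

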