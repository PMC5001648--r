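---
title: "Simulating on-scalp versus helmet MEG arrays with LCMV beamformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating on-scalp versus helmet MEG arrays with LCMV beamformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

MEG sensors measure femtotesla-scale fields, and signal falls roughly with
the inverse square of the source-to-sensor distance. Cryogenic SQUID
helmets keep pickup coils >= 1.7 cm from the scalp; room-temperature
magnetometers (e.g. optically-pumped magnetometers, OPMs) can sit ~4 mm
away. `opmbeam` quantifies what that proximity buys — and what it costs —
through five simulation experiments: lead-field norm (SNR) gain maps,
single-dipole beamformer reconstruction accuracy, rejection of interfering
brain sources, sensitivity to forward-model error, and two-source spatial
resolution as a function of channel count.

# Models and procedures

## Forward model

Sources are current dipoles at cortical-surface vertices, oriented along
the outward surface normal. Fields are computed with the closed-form
Sarvas solution for a dipole in a homogeneous conducting sphere, under a
*multiple local sphere* model: for every channel a sphere is fitted (by
algebraic least squares) to the scalp vertices within 9 cm of that
channel's inner coil, and the channel's response is always evaluated in
its own sphere. Channels are point coils projected on their sensitive
axis; axial gradiometers subtract two coaxial coils 5 cm apart. Radial
dipoles are externally silent in a sphere, and the radial field component
equals the free-space dipole field's — both identities are exercised in
the test suite.

Two containment conventions were possible for sources versus fitted
spheres. Patch-fitted spheres on a non-spherical head have radii of
7–12 cm centred near the local curvature centre, so distant (e.g.
contralateral) sources unavoidably fall outside *individual* channels'
spheres; erroring on that would make every whole-cortex lead field
impossible. The implementation therefore errors only when a source lies
outside **every** channel's sphere (outside the conductor model
altogether), the standard multiple-local-sphere practice.

## Beamformer

The LCMV spatial filter is `w = (C + mu * Sigma)^-1 l / (l^T (C + mu *
Sigma)^-1 l)`, with `C` the demeaned sample data covariance, `Sigma` the
sensor-noise model and `mu = 0.001` (deliberately minimal regularisation,
maximising spatial resolution). `Sigma` is taken as `sigma_e^2 * I` with
`sigma_e` the known simulated noise standard deviation; the regulariser is
three orders of magnitude below the signal covariance diagonal, so any
reasonable diagonal choice is immaterial (it is configurable). Solves use
a Cholesky factorisation, never an explicit inverse, with an eigenvalue
pseudo-inverse fallback for rank-deficient covariances (e.g. noise-free
simulations). Reconstruction accuracy is the *signed* Pearson correlation
between the true and reconstructed source time courses; leakage metrics
use |r|.

Because reconstructions are linear in the data, every correlation the
experiments report is an exact function of demeaned sample second
moments. The experiment drivers therefore compute correlations in the
moment domain without materialising channel-by-sample matrices; the
equivalence with explicit `reconstruct_source()` time courses is
unit-tested to 1e-10.

## Simulated recordings

`m = sum_s l_s q_s + e`, with Gaussian white dipole time courses
(`sigma_q = 5 nAm`) and i.i.d. Gaussian sensor noise (50 fT for
single-dipole and interference experiments, 35 fT for two-source
resolution experiments). The reference recording is 600 s at 600 Hz
(N = 360,000); N is a first-class parameter and the scaled run sizes are
listed below. Sensor noise is drawn by a seeded compiled generator
(xoshiro256++ feeding a 128-layer ziggurat) because the experiments
consume ~1e10 deviates; its calibration (sd, kurtosis, tail mass,
autocorrelation) is unit-tested. Sources use R's RNG. Everything derives
from one master seed through labelled child streams, so every experiment
table is bit-reproducible.

## Forward-model error

Errors are injected only into the lead field used for the weights; the
data always use the true lead field. The perturbation `delta_l = xi * (r -
l (l^T l)^-1 l^T r)` confines a Gaussian random vector to the hyperplane
orthogonal to `l`, so `|l_hat|^2 = |l|^2 + |delta_l|^2` exactly, and `xi`
is calibrated in closed form so the fractional error `|delta_l|/|l|` hits
each of 20 targets spanning 0–0.5 exactly. Each (vertex, fraction) is
averaged over random-direction realisations whose seeds derive from
(master seed, vertex, fraction index, realisation index); the random
vector is redrawn per realisation and per fraction.

## Two-source experiments

Pairs of temporally orthogonal dipoles are simulated at controlled
Euclidean separations (2 mm bins up to 60 mm, rejection-sampled pair
locations), and the leakage `|r(q_hat_k, q_hat_n)|` is compared with the
resolvability criterion `1/sqrt(2)` (50% shared variance). The
minimum-separation map escalates through each seed vertex's neighbours in
distance order until the criterion is met. For that map the default is
the *population-covariance limit* of the 600-s recordings: at N =
360,000 the sample covariance is within a fraction of a percent of its
expectation, and in the limit all two-source metrics reduce to closed 2x2
algebra over the lead-field Gram matrix (`two_source_population_metrics`,
unit-tested against both the generic Cholesky path and long sampled
recordings). A sampled mode (`n_samples = <finite>`) is available.

# The synthetic head

No real anatomy ships with the package; the generator emulates the study
conditions:

* **Scalp**: an ellipsoid matching the reference adult head extents
  (21.3 cm anterior-posterior, 14.6 cm left-right) exactly at the axis
  poles. The superior-inferior extent is free; default 0.18 m.
  Surfaces are geodesic subdivisions of an octahedron (so the axis poles
  are mesh vertices); optional smooth bumps emulate non-sphericity, and
  meshes can also be imported (ASCII PLY/OFF/STL).
* **Cortex**: a closed surface offset 1.5 cm inward (an average adult
  scalp-to-cortex distance) with 21,318 vertices for the reference target
  of 21,401. Crucially, the surface carries deterministic band-limited
  radial undulations (amplitude 6 mm, soft-bounded; angular frequencies
  10–22, i.e. ~2–5 cm wavelengths). A perfectly smooth offset surface
  would make every surface-normal dipole nearly radial — hence nearly
  silent in a spherical conductor — which would suppress the very
  quantities under study; the undulations restore realistic orientation
  diversity (median tilt ~30 degrees from radial). The folding amplitude
  was fixed once so that the default configuration's per-dipole channel
  SNRs span roughly 0-3 for the helmet and 0-24 for the on-scalp array
  at 5 nAm / 50 fT, the regime this comparison targets, and is not
  revisited. With the folding disabled the surfaces have analytic
  ellipsoid normals (exactly radial in sphere mode).
* **Arrays**: 275 radial axial gradiometers (5 cm baseline) on a helmet
  surface dilated from the scalp, placed by greedy farthest-point
  sampling; the head rests against the back of the helmet (posterior gap
  1.7 cm, anterior ~3 cm, via a 6.5 mm posterior shift). A 29-channel
  reference magnetometer array sits >= 15 cm out, with an optional
  least-squares balancing scheme that nulls uniform fields and uniform
  field gradients (a documented stand-in for recording-derived
  third-order gradiometer coefficients; off by default since no
  environmental interference is simulated). The on-scalp array projects
  each helmet channel to the nearest scalp vertex, 4 mm out along the
  local normal, radial-axis magnetometers for beamforming (gradiometer
  mode exists for the like-for-like SNR comparison). EEG-layout variants
  (10-10/10-5/10-2.5) use a proportional polar construction with ring
  counts fixed to the published system sizes (81/329/1293).
* **Helmet coverage**: sensors are restricted to above a cut plane
  5 cm below the fiducial plane. A shallower cut (e.g. 2 cm) would leave
  about a third of the closed surrogate cortex with no coverage at all
  and sensor-to-source distances near 9 cm, well beyond the 6 cm upper
  bound of the study's depth classes; 5 cm approximates real whole-head
  helmet coverage (max distance to the nearest on-scalp sensor ~7 cm).

What the surrogate does **not** reproduce: true sulcal geometry (folding
here is smooth and band-limited, with no sharp fundi, no through-sulcus
near-touching banks), the exact CTF coil layout, skull conductivity
structure (the sphere conductor model needs none), correlated or
environmental noise, and the specific
depth *distribution* of a real cortex. Quantities tied to fine geometry
(absolute minimum-separation values, exact bin positions of resolution
crossings) therefore carry surrogate-level uncertainty even when the
pipeline is exact; the test suite pins the physics identities exactly and
the replication-level quantities within generous bands.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sigma_q` | 5e-9 | A m | dipole amplitude std of all simulated sources |
| `sigma_e` | 50e-15 / 35e-15 | T | sensor noise std (single-dipole / two-source experiments) |
| `mu` | 0.001 | — | diagonal-loading factor on `Sigma`; minimal on purpose |
| `min_standoff` | 0.017 | m | helmet dewar constraint |
| `standoff` (on-scalp) | 0.004 | m | scalp-to-OPM distance |
| `baseline` | 0.05 | m | axial gradiometer baseline |
| `patch_radius` | 0.09 | m | scalp patch for per-channel sphere fits |
| `n_samples` | 360000 | — | recording length (600 s x 600 Hz) |

# Numerical choices

* Sphere fits: algebraic least squares (linear, exact on spheres); whole
  scalp used when a patch has < 50 vertices.
* Sarvas denominator guarded at 1e-30; evaluation errors rather than
  returning garbage near the singularity.
* Cholesky solves; symmetric averaging of covariances; pseudo-inverse
  fallback warns.
* Resolvability interpolation: the resolution summary reports the first
  bin *midpoint* under threshold; the crossover of forward-error curves
  is linearly interpolated between fraction grid points.
* Ties in farthest-point sampling and azimuth cropping resolve by fixed
  deterministic ordering; all meshes are bit-reproducible given
  parameters and seed.
* Interferer shells follow the 6-mm ladder 0–6, …, 24–30 mm (the last
  shell read as 24–30 mm, consistent with the 0–3 cm bound).

# Scaled run sizes

Full-scale defaults reproduce the reference procedure (21,401-vertex
cortex, N = 360,000, 100 repeats per bin, 100 locations x 20 fractions x
5 realisations). The bundled acceptance script uses desk-scale sizes
chosen so each stage's estimator noise is well below the tolerances of
interest: 200 vertices at N = 30,000 for reconstruction accuracy; 30 bins
x 10 repeats at N = 60,000 for resolution curves; 300 seed vertices in
the population-covariance limit for minimum-separation maps; 50 deep
vertices x 20 fractions x 3 realisations at N = 20,000 for the
forward-error sweep. The test suite uses smaller fixtures still (60
channels, ~5,000-vertex cortex) for everything except the identities that
cost nothing at full scale.

# Known limitations

* Only the radial field component is sensed; tangential-axis measurements
  and volume-current contributions to them are out of scope.
* No orientation optimisation in the beamformer (orientations are known
  from the source space by construction).
* The minimum-separation map reports means over resolved seeds; seeds
  with no resolvable partner within 60 mm (deep, low-SNR regions of the
  surrogate, mostly for the helmet array) are flagged unresolved and
  excluded, which can bias the helmet mean optimistic relative to a
  folded cortex.
* The balancing scheme is physically sensible but is not the
  recording-derived third-order coefficient set of a real system; it
  defaults off.
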