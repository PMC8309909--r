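---
title: "How ecgshift models electrode-shift distortion of the ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ecgshift models electrode-shift distortion of the ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgshift)
```

Wearable ECG devices move the measurement electrodes away from the
Einthoven/Mason–Likar reference placement, and the recorded waveform changes
with them.  `ecgshift` quantifies that change along two parallel routes: a
forward biophysical model (an excitable heart in a passive volume conductor,
sampled at displaced electrode montages) and a synthetic volunteer cohort
(parametric ECG records with calibrated position-dependent distortion and
motion artifacts).  Both feed the same comparison stack: ensemble-average
(EA) beats, normalized segment coefficients, dynamic time warping (DTW),
signal-to-noise ratio (SNR) and percentage difference/similarity.  This
vignette explains the models, the conventions, and the numerical choices,
and states what the package's tests do and do not demonstrate.

## The forward model

### Volume conductor

The trunk is an elliptic cylinder (34 × 60 × 22 cm by default) voxelized at
40 × 48 × 24 cells, with an outer fat sheath, a muscle layer, a bony spine
column, two ellipsoidal lungs, and a two-chamber spherical heart.  Every
voxel carries one tissue label and the passive conductivity of that tissue
(mS/m): heart 50, blood 700, lungs 40, muscle 200, fat 40, bone 6, trunk
200.  Electric potential in the passive tissue obeys the Laplace equation
$\nabla \cdot (-\sigma_0 \nabla V) = 0$ with zero normal current through the
torso surface (the body is electrically insulated) and $V = V_e$ on the
cardiac wall, where $V_e$ is the extracellular potential of the heart
model.  The right-leg electrode defines the potential reference
($V_{GND} = 0$).

The discrete operator uses harmonic-mean face conductivities and is
factorized once per geometry; electrode potentials are then obtained through
precomputed lead-field weight vectors (one adjoint solve per electrode
site), so sampling costs one small matrix–vector product per time step.  A
property test checks the solver against the closed-form potential of a
dipole at the center of an insulated homogeneous sphere (agreement within
5% away from the source), and charge conservation across the cardiac wall
holds at solver tolerance.

### Heart model

Cardiac tissue is split into seven subdomains — sinoatrial node (SAN),
atria (ATR), atrioventricular node (AVN), His bundle (HIS), bundle branches
(BNL), Purkinje fibers (PKJ) and ventricles (VTR) — arranged as an atrial
cap and a ventricular body separated by an insulating fibrous ring that
only the AVN bridges.  Each subdomain follows a modified FitzHugh–Nagumo
membrane model.  Writing $v = (V_m - B)/A$ for the normalized excursion
($B$ the resting potential, $A$ the amplitude scale):

$$\frac{dv}{dt} = k\left[c_1\, v (v - a)(1 - v) - c_2\, u\, r\right],
\qquad
\frac{du}{dt} = k e \left[v - d u - b\right],$$

with $r = v$ for working tissue (the recovery current carries a
$(V_m - B)$ factor) and, for the pacemaker node, an ungated recovery
current in membrane-potential units and a cubic gain that absorbs the rate
constant: $dv/dt = c_1 v(v-a)(1-v) - k c_2 u / A$.  With the published
per-subdomain parameters, rest is stable wherever $a > 0$ and unstable for
the node's $a = -0.6$: the SAN self-oscillates with a period of 0.92 s
(about 65 bpm), and atrial/ventricular cells are excitable with action
potentials peaking near +53 mV.  One point deserves emphasis: the node's
steady-state orbit spans about 1.9 × its amplitude scale $A$ — a relaxation
oscillator necessarily sweeps both outer branches of its cubic — so tests
freeze the measured band (1.5–2.2 A) rather than a narrower nominal one.

### Conduction on a centimetre grid

The published conductivities cannot serve directly as diffusion
coefficients on ~1 cm voxels: a FitzHugh–Nagumo depolarization front is a
fraction of a millimetre wide, so voxel-scale propagation is *grid-limited*
(each cell fires a finite time after its neighbour).  The package therefore
treats conduction as a calibrated numerical model with three documented
ingredients:

* a global `diffusion_scale` converting face conductivity to a
  voxel-coupling rate, with the couplings scaling as $1/h$ rather than
  $1/h^2$ — in the grid-limited regime this keeps tissue *activation times*
  invariant when the grid is refined;
* per-subdomain conduction gains (default: AVN × 16, SAN × 3, others × 1) —
  without the AVN gain the slow nodal conductivity blocks outright at this
  resolution, and the SAN gain overcomes the source–sink mismatch between
  the small node and the atrial load;
* a per-subdomain membrane (surface-to-volume) scale dividing the diffusion
  term, as in heterogeneous-capacitance monodomain models (SAN 12, AVN 6,
  others 1): it protects the pacemaker from being silenced by the tissue it
  drives, and produces the atrioventricular delay.

Under refinement the rhythm is preserved to a few percent, while the R-peak
amplitude — set by the spatial sharpness of the depolarization front —
still changes by roughly 25% between the default grid and its doubling.
Amplitude-sensitive conclusions should therefore be drawn from *normalized*
coefficients and from *relative* distance trends, which is what the
analyses here do.

### Electrode layout

The reference montage follows the Mason–Likar torso placement, from two
anthropometric distances: `Wh`, between the clavipectoral triangles
(28.8 cm mean), and `Wv`, from the sternal angle to the umbilical region
(43.2 cm mean).  Displaced positions 1–6 step by `f·Wh` horizontally and
`f·Wv` vertically with `f = 0.125` (3.6 and 5.4 cm at the mean
anthropometry).  The published study does not dimension the displaced
montage, so the package fixes a convention: the measurement-point path
steps from the LA reference toward the midline and downward, and the
montage converges on the mid-chest — LA steps down-and-inward, LL
up-and-inward, and RA horizontally toward the midline.  A symmetric
convergence (RA mirroring LA) was rejected because LA and RA then coincide
exactly at position 4 whenever `f = 0.125`, degenerating lead D1; the
adopted montage keeps every electrode on the trunk at all positions and
makes the lead vectors rotate and shorten progressively, which is what
produces the monotone distance-versus-position trend on all six lead × side
series.

## The synthetic cohort

No public recordings exist for this protocol, so the package generates a
synthetic stand-in cohort whose *population* statistics are anchored to the
published tables: 20 subjects, 250 Hz, 5 min rest + 5 min walking, segment
coefficients drawn from zero-truncated normals at the published means and
SDs, heart rates N(72, 8) bpm (a resting young-adult population), log-normal
RR jitter with 3% coefficient of variation, and subject amplitude scales
N(1.5, 0.2) mV (the published summary mentions typical 1.5 mV signals).
Each subject owns one R-peak train shared by all of their records, so
position-to-position differences reflect distortion, not rhythm.

### Beat template and coefficient semantics

Beats are raised-cosine ($\sin^2$) lobes: P and T positive lobes, and a
biphasic QRS (R lobe up, S lobe down, the R lobe occupying 60% of the QRS
duration).  The eight coefficients follow the segment-coefficient model
$S_0(t) = a_j S_j(d_j t + t_j) + c_j$: amplitudes `aP`, `aQRS`, `aT` in
µV per mV of the normalizer, durations `dP`, `dQRS`, `dT` and gaps `tP`
(P offset to QRS onset), `tQRS` (QRS offset to T onset) in ms per s of beat
period.  The amplitude normalizer is the **per-lead peak-to-peak amplitude
of the baseline-removed EA beat**.  This convention was chosen after the
obvious alternative — normalizing by a cross-lead maximum — proved
self-inconsistent: it forces the largest per-side `aQRS` to be identically
1000, which the published cohort values (max ≈ 750) contradict.  Under the
peak-to-peak convention `aQRS` is the share of the excursion carried by the
R wave and the S trough carries the complement `aS = 1000 − aQRS`; the
renderer is linear in the full amplitude set (`aP`, `aQRS`, `aS`, `aT`), so
scaling that set scales the record exactly and the normalized coefficients
are scale-invariant.

### Position distortion

Displacement distorts records through two mechanisms.  First, the
coefficients drift: multiplicative amplitude/duration gains and additive
timing shifts that grow quadratically from zero at the reference to their
maxima at position 6 (defaults: −8% `aP`, −4% `aQRS`, −6% `aT`, +2–4%
durations, +8–12 ms/s timings).  Second — and carrying most of the DTW
distance — a *beat-locked morphing wave* is added: an integer number of
sinusoid cycles per beat (2/3/4 cycles for D1/D2/D3, sign flipped on the
back), vanishing at the beat edges so records stay continuous.  A smooth
additive component is the only distortion that plausibly reaches the
published distances: time warps absorb pure timing/duration changes almost
freely, and amplitude gains alone would need implausible factors to move
the mean-absolute path difference by hundreds of µV.

The 36 morphing amplitudes (6 lead-sides × 6 positions) were calibrated
once, by running the full generation → EA → DTW pipeline on a
mean-coefficient subject and iteratively scaling each amplitude until the
distances matched the published distance-by-position table; the fitted
values (1.2 µV–1.4 mV) are frozen in the default configuration.  A linear
growth law in the position index was considered and rejected: the published
distances are strongly convex in the index (e.g. 1.0 µV at position 1
versus 48.6 µV at position 2 on D2 front), which no single linear gain can
reproduce within ±50% per cell.

### Motion artifacts

Walking records receive a three-component additive artifact: baseline
wander (three sinusoids at 0.1–0.8 Hz), EMG-like band-limited noise
(15–45 Hz), and sparse smooth biphasic transients at Poisson times.  The
mixture is scaled so the clean-versus-contaminated SNR equals a per-subject
target (N(8, 3) dB), with per-position log-normal factors (CV 0.2) drawn
per subject, making artifact severity subject-variable and
position-insensitive on average.  The published walking tables are
reproduced only qualitatively: the DTW variation magnitudes (about 13–38%)
match, but the SNR-by-position profile differs, because the SNR between a
displaced and a reference record also counts the placement distortion as
"noise", which grows with the position index here.

## The analysis stack

* **R-peak detection** — band-pass 5–25 Hz, squared derivative, 120 ms
  moving-window integration, adaptive threshold, 200 ms refractory, with
  the fiducial refined to the extreme absolute band-passed deflection
  (polarity-agnostic).  On clean synthetic records detection lands within
  one sample of ground truth.
* **Baseline removal** — two-stage running median (200/600 ms) followed by
  subtraction of a zero-phase 0.5 Hz low-pass of the residual.  Offsets are
  removed to numerical precision, 0.3 Hz wander is suppressed by >20 dB,
  and away from the record edges a zero-mean beat train passes with <2%
  deviation.
* **Ensemble average** — beats windowed to one median RR (40% before / 60%
  after the fiducial), rhythm outliers beyond ±25% of the median RR
  dropped, pointwise mean and SD envelope.
* **Delineation** — each wave's support is estimated from its 50%-of-peak
  crossings doubled outward, which is exact for raised-cosine lobes and
  degrades gracefully under noise; a wave below 5% of the R amplitude is
  reported missing (`NA`), never zero.  On the forward model's leads the P
  wave (below that floor) and the T wave (a repolarization plateau rather
  than a distinct lobe) are legitimately flagged missing.
* **DTW** — squared-difference distance matrix, the standard
  three-neighbour cumulative recurrence, and backtracking from $(m, n)$
  toward the adjacent predecessor of lowest cost with ties preferring the
  diagonal and then the vertical step (a fixed, documented rule; the
  source procedure names no tie-break).  The scalar distance is the mean
  absolute difference between the path-aligned signals, in µV — the
  first-power statistic that carries voltage units.  Note that the optimal
  warp can partially absorb a constant offset on structured signals; only
  on featureless signals is an offset reported verbatim.
* **SNR, difference, similarity, variation** —
  $SNR = 10\log_{10}(\sum x_r^2 / \sum (x_p - x_r)^2)$ dB;
  $\%Diff = |E_1-E_2| / \tfrac{1}{2}(E_1+E_2) \times 100$;
  $\%Sim = 100 - \%Diff$; variation = DTW distance over the reference
  peak-to-peak amplitude, in percent.

## Study orchestration and problem sizes

`run_model_study()` runs one 4.8 s simulation (0.1 ms reaction step,
250 Hz output), drops the first second as start-up, segments all positions
with the reference-position fiducials (every series shares the simulation
time base), and emits the model coefficient table, the DTW
distance-by-position table and its Spearman trend.  `run_synthetic_cohort()`
is a pure function of (configuration, seed) and emits the cohort
coefficient means/SDs, distance, SNR and variation tables, plus per-subject
recovered-versus-true coefficient errors.  The bundled analyses use 60 s
records for parameter recovery and 25–60 s records in the test suite; the
full 5-minute protocol durations remain the configuration defaults.
Headline scalars — the mean front-versus-back percentage difference of the
cohort coefficient table (≈4.94%) and the mean of the published per-lead
model-versus-volunteer similarities (87.9%) — are computed by
`front_back_difference()` and `reference_similarity()` from the published
tables, which the package ships as data.

For the model-versus-cohort similarity the aggregation is Eq-level per
coefficient and averaged per lead; applied to the published mean tables
this does *not* recover the published per-lead similarity values, which
evidently were computed from per-volunteer waveform-level data that is not
public — the package therefore also provides a record-level similarity
pathway (`waveform_similarity()`), and neither is claimed to be the
original procedure.

## Known limitations

* The volume conductor is a stylized trunk: no ribs beyond a spine column,
  no anisotropy (the source conductivities are themselves isotropic
  averages), and a two-sphere heart.  Absolute surface amplitudes are
  arbitrary-scale; only normalized and relative quantities are meaningful.
* Grid-limited conduction means wavefront *shape* does not converge under
  refinement (R amplitude drifts ~25% per doubling) even though timing
  does.
* The synthetic cohort reproduces published *population tables*, not real
  physiology: young healthy males at rest, no pathology, no respiration,
  no electrode-impedance physics in the artifact model.  Passing
  parameter-recovery tests shows the analysis stack is consistent with the
  generator's conventions; it cannot certify performance on real
  ambulatory recordings.
* The distortion model is calibrated to distance *tables*; it does not
  claim the displaced waveforms match any real displaced-lead morphology
  beyond the distance ordering and magnitudes.
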