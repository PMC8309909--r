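# ecgshift

Wearable ECG devices move the measurement electrodes away from the
Einthoven/Mason–Likar placement, and the recorded waveform changes with
them — enough, at large displacements, to matter for diagnosis. `ecgshift`
is an R package for quantifying that distortion. It provides:

* a **forward model**: a simplified bidomain FitzHugh–Nagumo heart
  (sinoatrial node through ventricles, seven labeled subdomains) embedded
  in a voxelized passive volume conductor (trunk, muscle, fat, bone,
  lungs, blood), solved with an insulated-torso Laplace equation and
  sampled as bipolar limb leads D1 = V(LA)−V(RA), D2 = V(LL)−V(RA),
  D3 = V(LL)−V(LA) at a reference montage and six displaced montages on
  the front and back of the trunk;
* a **synthetic volunteer cohort**: parametric ECG records built from the
  segment-coefficient model `S0(t) = a_j S_j(d_j t + t_j) + c_j`
  (amplitudes `aP, aQRS, aT` in µV/mV; durations/timings
  `dP, dQRS, dT, tP, tQRS` in ms/s), drawn around published cohort
  statistics, with calibrated position-dependent distortion and an additive
  motion-artifact model for walking epochs;
* a **comparison stack**: ensemble-average (EA) beats aligned at the
  R-peak fiducial, normalized segment-coefficient extraction, dynamic time
  warping with the cumulative-cost recurrence
  `C(x,y) = D(x,y) + min{C(x,y−1), C(x−1,y−1), C(x−1,y)}` and
  lowest-cost backtracking, `SNR = 10·log10(Σx_r² / Σ(x_p−x_r)²)` dB, and
  the percentage difference/similarity pair
  `%Diff = |E1−E2| / ½(E1+E2) × 100`, `%Sim = 100 − %Diff`.

The central empirical questions it answers: how fast does waveform
distortion grow as the montage leaves the reference position (monotonically,
on every lead and side), how close are front and back recordings of the
same lead (≈5% mean coefficient difference), and how faithfully can the
segment coefficients be recovered end-to-end (within a few percent on a
clean cohort).

## Worked example

```r
library(ecgshift)

geom <- build_torso_geometry()
lay  <- place_electrodes(geom, Wh = 28.8, Wv = 43.2, f = 0.125)
print(lay)

front_back_difference(reference_coefficients("volunteers"))
mean(reference_similarity())

st <- run_synthetic_cohort(seed = 1, n_subjects = 4, positions = c(1, 3, 6),
                           conditions = "rest", rest_s = 40)
round(st$dtw_mean, 1)
round(apply(st$recovery, 1, median), 2)
```

```
electrode_layout: Wh = 28.8 cm, Wv = 43.2 cm, f = 0.125
per-step displacement: 3.60 cm horizontal, 5.40 cm vertical
44 electrode sites over 7 positions x front/back

[1] 4.944653      # mean front-vs-back % difference of the cohort table
[1] 87.9          # mean per-lead model-vs-volunteer similarity, %

        pos1 pos2  pos3 pos4 pos5  pos6
D1front  4.6  NaN 198.8  NaN  NaN 242.1
D1back   7.1  NaN 138.5  NaN  NaN 190.1
D2front  0.7  NaN 142.3  NaN  NaN 279.3
D2back   0.4  NaN 128.5  NaN  NaN 308.2
D3front  0.8  NaN 204.3  NaN  NaN 445.8
D3back   0.5  NaN 173.4  NaN  NaN 427.7

  aP aQRS   aT   dP dQRS   dT   tP tQRS
0.76 0.39 0.51 0.58 1.65 0.55 1.64 1.79
```

The layout confirms the per-step montage displacement implied by the mean
anthropometry (3.6 cm horizontal, 5.4 cm vertical). The DTW table shows the
ensemble-average beat at displaced positions drifting away from the
reference beat — fractions of a µV to a few µV at position 1, hundreds of
µV by position 6 (columns not requested are `NaN`). The last row reports
the median relative error of each segment coefficient recovered end-to-end
(generation → baseline removal → R-peak detection → ensemble average →
delineation) against the generator's ground truth: all under 2%.

The forward model runs the same analysis on simulated physiology:

```r
study <- run_model_study()     # ~20 s: one 4.8 s simulation, all montages
study$spearman                 # distance-vs-position trend per lead x side
```

All six series have strongly positive Spearman correlation: distortion
grows with displacement in the model exactly as in the cohort.

See `vignette("electrode-shift-methods")` for the model equations,
conventions (amplitude normalization, montage geometry, DTW tie-breaking),
calibration procedure, and known limitations.

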