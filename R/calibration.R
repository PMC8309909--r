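# Calibrated amplitudes (mV) of the beat-locked morphing wave that realizes
# the position-dependent waveform distortion, per lead-side row and
# displaced position 1-6.  Fitted once against the published
# distance-by-position table by running the full generation + ensemble-
# average + DTW pipeline on the default cohort settings; see the methods
# vignette for the procedure.
.default_morph_mV <- local({
  m <- rbind(
    D1front = c(0.0125, 0.2480, 0.6931, 0.7993, 0.8530, 0.7834),
    D1back  = c(0.0239, 0.2599, 0.5828, 0.6935, 0.7977, 0.7161),
    D2front = c(0.0015, 0.2146, 0.6020, 0.6585, 0.9059, 1.0870),
    D2back  = c(0.0012, 0.2005, 0.4752, 0.7048, 1.0547, 1.2720),
    D3front = c(0.0024, 0.3197, 0.6979, 1.1433, 1.2864, 1.3849),
    D3back  = c(0.0012, 0.1746, 0.5244, 0.6662, 1.0004, 1.1738)
  )
  colnames(m) <- paste0("pos", 1:6)
  m
})
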