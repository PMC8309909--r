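# Shared fixtures: a small, fast torso geometry, and a brute-force DTW
# oracle that enumerates every monotone warp path.

small_geometry_config <- function() {
  cfg <- torso_geometry_config(resolution = c(32L, 36L, 20L))
  cfg
}

small_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_torso_geometry(small_geometry_config())
    cache
  }
})

# one short forward simulation on the small grid, shared across tests
small_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- small_geometry()
      lay <- place_electrodes(g)
      cache <<- run_simulation(g, lay, duration = 3.2)
    }
    cache
  }
})

# exhaustive minimum cumulative cost over all monotone paths from (1,1) to
# (m,n); plain recursion, independent of the dynamic program it checks
dtw_brute_force <- function(s1, s2) {
  D <- outer(s1, s2, function(a, b) (a - b)^2)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(D[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    D[i, j] + best
  }
  rec(length(s1), length(s2))
}

# a clean 1 s raised-cosine beat sampled at fs, for delineation tests
mean_subject_beat <- function(fs = 250) {
  cfg <- cohort_config()
  co <- reference_coefficients("volunteers")[, "D2front"]
  rec <- synth_record(co, position = 0, hr = 60, duration = 10, cfg = cfg,
                      r_times = seq(0.5, 9.5, by = 1))
  list(record = rec, coeffs = co)
}
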