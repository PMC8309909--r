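test_that("the passive solve matches the analytic dipole-in-a-sphere field", {
  # homogeneous insulated sphere with a physical dipole on its axis: the
  # interior potential away from the source is A cos(theta) (1/r^2 + 2r/R^3)
  n <- 40; R <- 10; h <- 2 * R * 1.1 / n
  cs <- seq(-R * 1.1 + h / 2, R * 1.1 - h / 2, length.out = n)
  X <- array(rep(cs, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cs, each = n), times = n), c(n, n, n))
  Z <- array(rep(cs, each = n * n), c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  dom <- r <= R
  geom <- structure(
    list(dims = c(n, n, n), spacing = rep(h, 3), domain = dom,
         sigma0 = array(ifelse(dom, 200, NA), c(n, n, n)),
         centers = list(x = cs, y = cs, z = cs)),
    class = "torso_geometry")
  pos <- which(dom & (X^2 + (Y - 1.5)^2 + Z^2) <= 1)
  neg <- which(dom & (X^2 + (Y + 1.5)^2 + Z^2) <= 1)
  V <- laplace_solve(geom, c(pos, neg),
                     c(rep(1, length(pos)), rep(-1, length(neg))))
  set.seed(77)
  sel <- sample(which(dom & r > 5 & r < 8.5 & abs(Y) / r > 0.35), 200)
  shape <- (Y[sel] / r[sel]) * (1 / r[sel]^2 + 2 * r[sel] / R^3)
  amp <- sum(V[sel] * shape) / sum(shape^2)   # effective dipole moment
  rel <- abs(V[sel] - amp * shape) / max(abs(amp * shape))
  expect_lt(max(rel), 0.05)
})

test_that("no net current crosses the cardiac wall of the insulated trunk", {
  sim <- small_simulation()
  flux <- net_boundary_current(sim)
  # conservation: what the heart pushes into the trunk returns elsewhere
  scale <- max(abs(sim$Ve_heart)) * max(abs(sim$conductor$B))
  expect_lt(max(abs(flux)) / scale, 1e-9)
})

test_that("the Einthoven identity holds to machine precision on every sample", {
  leads <- extract_leads(small_simulation())
  expect_lt(max(abs(leads$D1 + leads$D3 - leads$D2)), 1e-12)
  # all potentials equal gives identically zero leads
  sim0 <- small_simulation()
  p <- sim0$potentials
  sim0$potentials[] <- 1.23
  l0 <- extract_leads(sim0)
  expect_true(all(l0$D1 == 0 & l0$D2 == 0 & l0$D3 == 0))
  sim0$potentials <- p
})

test_that("non-pacemaker tissue stays at rest until the wave arrives", {
  sim <- small_simulation()
  sub <- sim$heart$subdomain
  # the ventricles see only the implicit-diffusion tail of the distant
  # nodal activity before the wave arrives: a small fraction of a mV
  early <- sim$Ve_heart[sim$times < 0.04, sub == "VTR", drop = FALSE]
  expect_lt(max(abs(early)), 0.5)
  # and the uniform rest state is an exact reaction equilibrium
  for (sd in c("ATR", "AVN", "HIS", "BNL", "PKJ", "VTR")) {
    p <- cell_params(sd)
    expect_equal(ionic_current(p$B, 0, p), 0)
    expect_equal(recovery_rate(p$B, 0, p), 0)
  }
})

test_that("pacemaker period is insensitive to the passive conductivities", {
  period_of <- function(overrides) {
    cfg <- small_geometry_config()
    cfg$conductivities <- overrides
    g <- build_torso_geometry(cfg)
    sim <- run_simulation(g, place_electrodes(g), duration = 2.6)
    san <- rowMeans(sim$Ve_heart[, sim$heart$subdomain == "SAN", drop = FALSE])
    mid <- mean(range(san))
    ups <- sim$times[which(diff(san > mid) == 1)]
    mean(diff(ups))
  }
  p1 <- period_of(NULL)
  p2 <- period_of(list(TORSO = 400, LUNG = 80, BLOOD = 350))
  expect_lt(abs(p1 - p2) / p1, 0.01)
})

test_that("each pacemaker cycle yields one sharp deflection and a slower wave", {
  sim <- small_simulation()
  leads <- extract_leads(sim)
  d2 <- leads[leads$position == 0 & leads$side == "front", ]
  keep <- d2$time > 0.2   # drop the initial nodal start-up transient
  rec <- remove_baseline(ecg_record(d2$D2[keep], sim$fs))
  # pacemaker cycles counted from the nodal potential itself
  san <- rowMeans(sim$Ve_heart[keep, sim$heart$subdomain == "SAN", drop = FALSE])
  cycles <- sum(diff(san > mean(range(san))) == 1)
  peaks <- detect_r_peaks(rec)
  peaks <- peaks[peaks > round(0.12 * sim$fs)]
  expect_lte(abs(length(peaks) - cycles), 1)
  # after the sharp deflection a slower, wider wave follows
  p <- peaks[1]
  x <- rec$samples
  r_amp <- abs(x[p])
  after <- x[(p + round(0.08 * sim$fs)):min(length(x), p + round(0.5 * sim$fs))]
  expect_gt(max(abs(after)), 0.1 * r_amp)
  dwell <- sum(abs(after) > 0.5 * max(abs(after)))
  qrs_width <- sum(abs(x[(p - 25):(p + 25)]) > 0.5 * r_amp)
  expect_gt(dwell, qrs_width)
})

test_that("simulation validates its sampling configuration", {
  g <- small_geometry()
  lay <- place_electrodes(g)
  expect_error(run_simulation(g, lay, dt = 3e-4, fs = 250), "integer number")
})

test_that("refining the grid preserves the rhythm and the order of magnitude", {
  run_at <- function(res) {
    g <- build_torso_geometry(torso_geometry_config(res))
    sim <- run_simulation(g, place_electrodes(g), duration = 2.0)
    leads <- extract_leads(sim)
    d2 <- leads[leads$position == 0 & leads$side == "front" & leads$time > 0.8, "D2"]
    san <- rowMeans(sim$Ve_heart[, sim$heart$subdomain == "SAN", drop = FALSE])
    ups <- sim$times[which(diff(san > mean(range(san))) == 1)]
    list(amp = max(abs(remove_baseline(ecg_record(d2, 250))$samples)),
         period = mean(diff(ups)))
  }
  a <- run_at(c(32L, 36L, 20L))
  b <- run_at(c(64L, 72L, 40L))
  # the activation-time-preserving couplings keep the rhythm fixed under
  # refinement; the wall dipole (R amplitude) converges more slowly because
  # finer grids sharpen the depolarization front
  expect_lt(abs(a$period - b$period) / a$period, 0.05)
  expect_lt(abs(a$amp - b$amp) / a$amp, 0.40)
})
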