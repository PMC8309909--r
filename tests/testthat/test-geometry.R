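test_that("every trunk voxel carries exactly one label and its conductivity", {
  g <- small_geometry()
  n_domain <- sum(g$domain)
  expect_equal(sum(table(g$labels[g$domain])), n_domain)
  expect_false(anyNA(g$labels[g$domain]))
  expect_true(all(is.na(g$labels[!g$domain])))
  # passive conductivities match the published tissue values
  lab <- g$labels[g$domain]
  sig <- g$sigma0[g$domain]
  expect_true(all(sig[lab == "BLOOD"] == 700))
  expect_true(all(sig[lab == "BONE"] == 6))
  expect_true(all(sig[lab == "LUNG"] == 40))
  expect_true(all(sig[lab == "TORSO"] == 200))
  expect_true(all(sig[lab == "MUSCLE"] == 200))
  expect_true(all(sig[lab == "FAT"] == 40))
  expect_true(all(sig[lab %in% c("SAN", "ATR", "AVN", "HIS",
                                 "BNL", "PKJ", "VTR")] == 50))
})

test_that("removing every organ leaves a homogeneous trunk", {
  cfg <- small_geometry_config()
  cfg$layers <- list(fat_cm = 0, muscle_cm = 0)
  cfg$spine$radius <- 0
  cfg$lungs$semi <- c(0, 0, 0)
  cfg$heart$radius <- 0
  g <- build_torso_geometry(cfg)
  expect_true(all(g$labels[g$domain] == "TORSO"))
  expect_true(all(g$sigma0[g$domain] == 200))
})

test_that("subdomain volume fractions are stable under grid refinement", {
  f1 <- subdomain_fractions(build_torso_geometry(torso_geometry_config(c(32L, 36L, 20L))))
  f2 <- subdomain_fractions(build_torso_geometry(torso_geometry_config(c(64L, 72L, 40L))))
  frac <- function(f, labs) sum(f$fraction[f$label %in% labs])
  # tissues that span many voxels converge tightly
  for (labs in list("TORSO", "MUSCLE", "FAT", "LUNG", "BONE")) {
    a <- frac(f1, labs); b <- frac(f2, labs)
    expect_lt(abs(a - b) / a, 0.05)
  }
  # the thin cardiac wall and its cavities are only a few voxels across at
  # the coarse resolution; their fractions converge more slowly
  heart <- c("SAN", "ATR", "AVN", "HIS", "BNL", "PKJ", "VTR")
  for (labs in list("BLOOD", heart)) {
    a <- frac(f1, labs); b <- frac(f2, labs)
    expect_lt(abs(a - b) / a, 0.15)
  }
})

test_that("the heart is one connected component with the node on the atria", {
  g <- small_geometry()
  expect_equal(heart_components(g), 1L)
  d <- g$dims
  san <- which(array(g$labels == "SAN", dim = d))
  expect_gt(length(san), 0)
  atr <- array(g$labels == "ATR", dim = d)
  atr[is.na(atr)] <- FALSE
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  touches <- any(vapply(strides, function(s)
    any(atr[pmax(1L, pmin(prod(d), san + s))]), logical(1)))
  expect_true(touches)
})

test_that("geometry rejects bad configurations", {
  cfg <- small_geometry_config()
  cfg$resolution <- c(8L, 28L, 16L)
  expect_error(build_torso_geometry(cfg), "at least 16")
  cfg <- small_geometry_config()
  cfg$conductivities <- list(PLASMA = 1)
  expect_error(build_torso_geometry(cfg), "unknown subdomain")
})

test_that("electrode steps equal the configured fractions of the anthropometry", {
  g <- small_geometry()
  lay <- place_electrodes(g, Wh = 28.8, Wv = 43.2, f = 0.125)
  expect_identical(unname(lay$step_cm), c(3.6, 5.4))
  # the measurement-point path advances one step per index
  steps <- diff(lay$points)
  expect_equal(unname(steps[, 1]), rep(-3.6, 6))
  expect_equal(unname(steps[, 2]), rep(-5.4, 6))
})

test_that("distance from the reference point grows with the position index", {
  lay <- place_electrodes(small_geometry())
  d <- sqrt(rowSums(sweep(lay$points, 2, lay$points[1, ])^2))
  expect_true(all(diff(d) > 0))
  # and per-electrode displacement grows too
  el <- lay$electrodes
  for (role in c("LA", "RA", "LL")) {
    e <- el[el$role == role & el$side == "front", ]
    e <- e[order(e$position), ]
    dd <- sqrt((e$x - e$x[1])^2 + (e$y - e$y[1])^2)
    expect_true(all(diff(dd) >= 0))
  }
})

test_that("zero step fraction collapses all positions onto the reference", {
  lay <- place_electrodes(small_geometry(), f = 0)
  expect_true(all(abs(sweep(lay$points, 2, lay$points[1, ])) < 1e-12))
})

test_that("electrode displacement is scale-equivariant in the anthropometry", {
  g <- small_geometry()
  l1 <- place_electrodes(g, Wh = 14.4, Wv = 21.6)
  l2 <- place_electrodes(g, Wh = 28.8, Wv = 43.2)
  d1 <- sweep(l1$points, 2, l1$points[1, ])
  d2 <- sweep(l2$points, 2, l2$points[1, ])
  expect_equal(d2, 2 * d1)
})

test_that("electrodes land on surface voxels and bad points are named", {
  g <- small_geometry()
  lay <- place_electrodes(g)
  el <- lay$electrodes
  lin <- el$ix + (el$iy - 1) * g$dims[1] + (el$iz - 1) * g$dims[1] * g$dims[2]
  expect_true(all(g$surface[lin]))
  front <- el$side == "front"
  expect_true(all(g$centers$z[el$iz[front]] >= 0))
  expect_true(all(g$centers$z[el$iz[!front]] < 0))
  expect_error(place_electrodes(g, Wv = 70), "outside|below")
})

test_that("geometry config round-trips through YAML and export writes text", {
  cfg <- small_geometry_config()
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(resolution = c(24L, 28L, 16L),
                        layers = list(fat_cm = 0.5, muscle_cm = 1.2)), tmp)
  got <- read_geometry_config(tmp)
  expect_equal(got$layers$fat_cm, 0.5)
  expect_equal(got$trunk$semi_x, cfg$trunk$semi_x)

  out <- tempfile(fileext = ".csv")
  write_geometry(small_geometry(), out)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".json")))
  df <- utils::read.csv(out)
  expect_equal(nrow(df), sum(small_geometry()$domain))
})
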