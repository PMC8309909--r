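#' @useDynLib ecgshift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# face list between voxels of `mask`, with conductivity-weighted couplings
# g = scale * harmonic_mean(sigma_i, sigma_j) / h_axis^power  (1/s per unit
# of the scale constant).  power = 2 discretizes the continuum Laplacian
# (passive conductor); power = 1 is the activation-time-preserving coupling
# used for the heart's reaction-diffusion graph, whose wavefronts are
# grid-limited at these resolutions (crossing time stays invariant when the
# grid is refined).  Returns data frame of (i, j, g) with i, j linear voxel
# indices.
.grid_faces <- function(dims, spacing, sigma, mask, scale = 1, power = 2) {
  out <- vector("list", 3)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  lin <- array(seq_len(prod(dims)), dim = dims)
  for (ax in 1:3) {
    sel <- slice.index(lin, ax) < dims[ax]
    i <- lin[sel]
    j <- i + strides[ax]
    ok <- mask[i] & mask[j]
    i <- i[ok]; j <- j[ok]
    sh <- 2 / (1 / sigma[i] + 1 / sigma[j])
    out[[ax]] <- data.frame(i = i, j = j, g = scale * sh / spacing[ax]^power)
  }
  do.call(rbind, out)
}

# assemble the (positive-definite) discrete operator -div(sigma grad .) over
# `cells`, with Dirichlet coupling to `dirichlet_cells`; returns A (n x n
# sparse), B (n x nd sparse, entries -g) and the index maps
.assemble_operator <- function(dims, spacing, sigma, cells, dirichlet_cells,
                               scale = 1) {
  mask <- logical(prod(dims))
  mask[cells] <- TRUE
  mask[dirichlet_cells] <- TRUE
  faces <- .grid_faces(dims, spacing, sigma, mask, scale)
  is_dir <- logical(prod(dims)); is_dir[dirichlet_cells] <- TRUE
  row_of <- integer(prod(dims)); row_of[cells] <- seq_along(cells)
  col_of <- integer(prod(dims)); col_of[dirichlet_cells] <- seq_along(dirichlet_cells)

  fi_dir <- is_dir[faces$i]; fj_dir <- is_dir[faces$j]
  both_free <- !fi_dir & !fj_dir
  mixed <- xor(fi_dir, fj_dir)
  n <- length(cells)

  ti <- tj <- tv <- list()
  f <- faces[both_free, ]
  if (nrow(f)) {
    ti <- list(row_of[f$i], row_of[f$j], row_of[f$i], row_of[f$j])
    tj <- list(row_of[f$j], row_of[f$i], row_of[f$i], row_of[f$j])
    tv <- list(-f$g, -f$g, f$g, f$g)
  }
  A_extra_i <- A_extra_v <- numeric(0)
  Bi <- Bj <- Bv <- numeric(0)
  fm <- faces[mixed, ]
  if (nrow(fm)) {
    free <- ifelse(is_dir[fm$i], fm$j, fm$i)
    dir <- ifelse(is_dir[fm$i], fm$i, fm$j)
    A_extra_i <- row_of[free]
    A_extra_v <- fm$g
    Bi <- row_of[free]; Bj <- col_of[dir]; Bv <- -fm$g
  }
  A <- Matrix::sparseMatrix(
    i = c(unlist(ti), A_extra_i),
    j = c(unlist(tj), A_extra_i),
    x = c(unlist(tv), A_extra_v),
    dims = c(n, n)
  )
  B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bv,
                            dims = c(n, length(dirichlet_cells)))
  list(A = A, B = B, cells = cells, dirichlet = dirichlet_cells)
}

#' Solve the passive Laplace problem on the volume conductor
#'
#' Solves \eqn{\nabla \cdot (-\sigma_0 \nabla V) = 0} over the passive
#' voxels of the trunk with prescribed (Dirichlet) potentials on a given
#' voxel set and zero normal current through the torso surface (the trunk is
#' electrically insulated).
#'
#' @param geometry a `torso_geometry`.
#' @param dirichlet integer vector of linear voxel indices carrying
#'   prescribed potentials.
#' @param values numeric vector of prescribed potentials (mV), same length.
#' @return a 3-D array of potentials (mV) over the trunk (`NA` outside).
#' @export
laplace_solve <- function(geometry, dirichlet, values) {
  stopifnot(length(dirichlet) == length(values))
  domain_idx <- which(geometry$domain)
  free <- setdiff(domain_idx, dirichlet)
  op <- .assemble_operator(geometry$dims, geometry$spacing,
                           as.vector(geometry$sigma0), free, dirichlet)
  rhs <- -op$B %*% values
  V <- Matrix::solve(op$A, rhs)
  out <- array(NA_real_, geometry$dims)
  out[free] <- as.vector(V)
  out[dirichlet] <- values
  out
}

# Per-subdomain numerical conduction gains.  On a centimetre-scale voxel
# grid the published conductivities cannot be used verbatim as diffusion
# coefficients: a wavefront a fraction of a millimetre wide cannot be
# represented, and couplings proportional to sigma alone either block (slow
# tissue) or sweep the wall in one step (fast tissue).  These gains place
# each tissue's voxel-to-voxel coupling rate in the regime that reproduces
# the activation sequence (fast atrial spread, slow atrioventricular
# conduction, rapid Purkinje spread, then the ventricular wall).
.conduction_gain <- c(SAN = 3.0, ATR = 1.0, AVN = 16.0, HIS = 1.0,
                      BNL = 1.0, PKJ = 1.0, VTR = 1.0)

# Per-subdomain membrane (surface-to-volume) scaling of the diffusion term:
# the monodomain update reads dVm/dt = (1/Cm) div(sigma grad Vm) - i_ion,
# with Cm = 1 for working myocardium.  Nodal cells are small with a high
# effective capacitance: a large value protects the sinoatrial pacemaker
# from being silenced by the atrial load, and slows the atrioventricular
# relay so the P-QRS delay emerges.
.membrane_scale <- c(SAN = 12, ATR = 1, AVN = 6, HIS = 1,
                     BNL = 1, PKJ = 1, VTR = 1)

#' Run the bidomain heart / volume-conductor simulation
#'
#' Integrates the modified FitzHugh-Nagumo reaction-diffusion system over
#' the heart voxels (operator splitting: explicit reaction, semi-implicit
#' diffusion), couples the heart to the passive trunk through the
#' extracellular potential on the cardiac wall (V = Ve), and samples the
#' surface potentials at the electrode sites at rate `fs`.  The passive
#' Laplace problem is pre-factorized once and electrode potentials are
#' obtained through precomputed lead-field weight vectors, so sampling is a
#' matrix-vector product per time sample.
#'
#' Outside the heart the intracellular conductivity is zero, so the coupled
#' system reduces to the membrane reaction-diffusion inside the heart plus
#' one elliptic solve for the trunk potential with the cardiac wall as
#' source and the torso surface insulated.  The right-leg electrode is the
#' potential reference (subtracted on sampling).
#'
#' @param geometry a `torso_geometry`.
#' @param layout an `electrode_layout` from [place_electrodes()].
#' @param duration simulated time, s (should cover at least one pacemaker
#'   cycle, about 0.92 s).
#' @param dt reaction time step, s.
#' @param fs output sampling rate, Hz.
#' @param diffusion_scale global conversion from face conductivity (mS/m)
#'   to voxel coupling rate, in cm/s per (mS/m) (the couplings scale as
#'   1/h, which keeps tissue activation times invariant under grid
#'   refinement); per-tissue conduction gains multiply it.
#' @param conduction_gain named per-subdomain multipliers of
#'   `diffusion_scale` (see Details in the package vignette).
#' @param membrane_scale named per-subdomain membrane capacitance scalings
#'   dividing the diffusion term (nodal tissue is given a high value; see
#'   the package vignette).
#' @return an object of class `heart_simulation`: `times` (s), `potentials`
#'   (samples x electrode-voxel matrix, mV, unreferenced), `Ve_heart`
#'   (samples x heart-voxel extracellular potentials), `heart` (voxel
#'   bookkeeping), `layout`, `fs`, and solver diagnostics.
#' @export
run_simulation <- function(geometry, layout,
                           duration = 3, dt = 1e-4, fs = 250,
                           diffusion_scale = 170,
                           conduction_gain = .conduction_gain,
                           membrane_scale = .membrane_scale) {
  stopifnot(inherits(geometry, "torso_geometry"),
            inherits(layout, "electrode_layout"))
  every <- round(1 / (fs * dt))
  if (abs(every - 1 / (fs * dt)) > 1e-9)
    stop("1/(fs*dt) must be an integer number of steps")

  d <- geometry$dims
  lab <- geometry$labels
  heart_idx <- which(array(lab %in% .heart_labels, dim = d))
  if (!length(heart_idx)) stop("geometry has no heart voxels")
  sub <- lab[heart_idx]
  P <- .cell_param_table[, sub, drop = FALSE]
  a <- P["a", ]; b <- P["b", ]; c1 <- P["c1", ]; c2 <- P["c2", ]
  dpar <- P["d", ]; e <- P["e", ]; k <- P["k", ]
  Aamp <- P["A", ]; B <- P["B", ]
  is_san <- sub == "SAN"
  if (dt * max((k * c1)[!is_san]) > 1.5)
    warning("reaction step dt is large for the stiffest tissue; ",
            "consider reducing dt")

  # heart diffusion operator on Vm (effective conductivity sigma_e sigma_i /
  # (sigma_e + sigma_i), scaled by the numerical conduction gains)
  sig_eff <- array(0, d)
  se <- P["sigma_e", ]; si <- P["sigma_i", ]
  gain <- .conduction_gain
  gain[names(conduction_gain)] <- conduction_gain
  sig_eff[heart_idx] <- (se * si / (se + si)) * gain[sub]
  mask_h <- logical(prod(d)); mask_h[heart_idx] <- TRUE
  mask_arr <- array(mask_h, d)
  faces_h <- .grid_faces(d, geometry$spacing, as.vector(sig_eff), mask_arr,
                         scale = diffusion_scale, power = 1)
  row_of <- integer(prod(d)); row_of[heart_idx] <- seq_along(heart_idx)
  nh <- length(heart_idx)
  Lh <- Matrix::sparseMatrix(
    i = c(row_of[faces_h$i], row_of[faces_h$j], row_of[faces_h$i], row_of[faces_h$j]),
    j = c(row_of[faces_h$j], row_of[faces_h$i], row_of[faces_h$i], row_of[faces_h$j]),
    x = c(-faces_h$g, -faces_h$g, faces_h$g, faces_h$g),
    dims = c(nh, nh)
  )
  cm <- .membrane_scale
  cm[names(membrane_scale)] <- membrane_scale
  cmv <- cm[sub]
  M <- Matrix::Diagonal(nh) + dt * Matrix::Diagonal(nh, 1 / cmv) %*% Lh
  Mfac <- Matrix::lu(M)

  # passive conductor and electrode lead fields
  domain_idx <- which(geometry$domain)
  free <- setdiff(domain_idx, heart_idx)
  op <- .assemble_operator(d, geometry$spacing, as.vector(geometry$sigma0),
                           free, heart_idx)
  Afac <- Matrix::Cholesky(methods::as(op$A, "symmetricMatrix"), LDL = FALSE)
  el <- layout$electrodes
  el_lin <- el$ix + (el$iy - 1L) * d[1] + (el$iz - 1L) * d[1] * d[2]
  uniq <- unique(el_lin)
  free_row <- integer(prod(d)); free_row[free] <- seq_along(free)
  if (any(free_row[uniq] == 0L))
    stop("an electrode voxel is not a passive conductor cell")
  E <- Matrix::sparseMatrix(i = free_row[uniq], j = seq_along(uniq),
                            x = 1, dims = c(length(free), length(uniq)))
  Z <- Matrix::solve(Afac, E)               # lead-field adjoints
  W <- -Matrix::t(op$B) %*% Z               # heart-voxel weights per electrode
  W <- as.matrix(W)

  # state from the published initial conditions
  v <- (P["Vi0", ] - P["Ve0", ] - B) / Aamp
  u <- P["u0", ]

  nsteps <- round(duration / dt)
  nsamp <- floor(nsteps / every)
  pots <- matrix(NA_real_, nsamp, length(uniq))
  Ve_hist <- matrix(NA_real_, nsamp, nh)
  times <- (seq_len(nsamp) * every) * dt
  kc2A <- k * c2 / Aamp
  kc2 <- k * c2
  ke <- k * e
  s <- 0L
  for (step in seq_len(nsteps)) {
    cubic <- v * (v - a) * (1 - v)
    dv <- ifelse(is_san, c1 * cubic - kc2A * u, k * c1 * cubic - kc2 * u * v)
    u <- u + dt * ke * (v - dpar * u - b)
    v <- v + dt * dv
    Vm <- B + Aamp * v
    Vm <- as.vector(Matrix::solve(Mfac, Vm))
    v <- (Vm - B) / Aamp
    if (!all(is.finite(v)))
      stop(sprintf("simulation diverged at t = %.4f s", step * dt))
    if (step %% every == 0L) {
      s <- s + 1L
      Ve <- -(Aamp * v) / 2   # extracellular deviation on the cardiac wall
      Ve_hist[s, ] <- Ve
      pots[s, ] <- crossprod(W, Ve)
    }
  }
  colnames(pots) <- paste0("vox", uniq)

  structure(
    list(times = times, potentials = pots, Ve_heart = Ve_hist,
         heart = list(idx = heart_idx, subdomain = sub),
         electrode_voxels = uniq, layout = layout, fs = fs, dt = dt,
         duration = duration, geometry_dims = d,
         conductor = list(A = op$A, B = op$B, free = free)),
    class = "heart_simulation"
  )
}

#' @export
print.heart_simulation <- function(x, ...) {
  cat(sprintf("heart_simulation: %.2f s at %g Hz, %d heart voxels, %d electrode sites\n",
              x$duration, x$fs, length(x$heart$idx), length(x$electrode_voxels)))
  invisible(x)
}

#' Net current crossing the cardiac wall into the trunk
#'
#' With the torso surface insulated, charge conservation requires that the
#' net current the heart injects into the passive conductor is zero at every
#' instant (what flows out of one part of the wall returns through another).
#' This recomputes the full trunk potential at the requested samples and
#' sums the discrete wall fluxes; values should sit at the linear-solver
#' tolerance.
#'
#' @param sim a `heart_simulation`.
#' @param samples indices of output samples to check (default: five spread
#'   over the run).
#' @return numeric vector of net wall currents (arbitrary units), one per
#'   checked sample.
#' @export
net_boundary_current <- function(sim, samples = NULL) {
  if (is.null(samples))
    samples <- unique(round(seq(1, length(sim$times), length.out = 5)))
  A <- sim$conductor$A; B <- sim$conductor$B
  vapply(samples, function(s) {
    Ve <- sim$Ve_heart[s, ]
    V <- as.vector(Matrix::solve(A, -B %*% Ve))
    # row sums of [A B] vanish for interior cells, so the total residual
    # equals the net flux through the Dirichlet wall
    sum(A %*% V + B %*% Ve)
  }, numeric(1))
}

#' Form the bipolar limb leads from sampled surface potentials
#'
#' Builds D1 = VLA - VRA, D2 = VLL - VRA and D3 = VLL - VLA for every
#' measurement position and side, after referencing every electrode to the
#' right-leg potential (VGND = 0).  The Einthoven identity D1 + D3 = D2
#' holds exactly by construction.
#'
#' @param sim a `heart_simulation`.
#' @param layout the `electrode_layout` used for the run (defaults to the
#'   one stored in `sim`).
#' @return a long data frame with columns `time`, `position`, `side`,
#'   `VLA`, `VRA`, `VLL` (RL-referenced, mV) and `D1`, `D2`, `D3` (mV).
#' @export
extract_leads <- function(sim, layout = sim$layout) {
  el <- layout$electrodes
  d <- sim$geometry_dims
  el$lin <- el$ix + (el$iy - 1L) * d[1] + (el$iz - 1L) * d[1] * d[2]
  col_of <- match(el$lin, sim$electrode_voxels)
  if (any(is.na(col_of))) stop("electrode sample missing from simulation")
  out <- list()
  for (side in unique(el$side)) {
    rl <- el$lin[el$role == "RL" & el$side == side]
    vref <- sim$potentials[, match(rl, sim$electrode_voxels)]
    for (pos in 0:6) {
      pick <- function(role) {
        lin <- el$lin[el$role == role & el$side == side &
                        !is.na(el$position) & el$position == pos]
        sim$potentials[, match(lin, sim$electrode_voxels)] - vref
      }
      VLA <- pick("LA"); VRA <- pick("RA"); VLL <- pick("LL")
      out[[length(out) + 1L]] <- data.frame(
        time = sim$times, position = pos, side = side,
        VLA = VLA, VRA = VRA, VLL = VLL,
        D1 = VLA - VRA, D2 = VLL - VRA, D3 = VLL - VLA)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fs") <- sim$fs
  res
}
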