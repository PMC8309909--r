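#' Default torso-geometry configuration
#'
#' The volume conductor is a simplified upper trunk: an elliptic cylinder of
#' trunk tissue with an outer fat sheath and a muscle layer, a bony spine
#' column, two ellipsoidal lungs, and a two-chamber spherical heart whose
#' wall is split into an atrial cap and a ventricular body separated by an
#' insulating atrioventricular ring.  The cardiac conduction system is laid
#' down as labeled clusters along the activation path: sinoatrial node (SAN)
#' in the atrial wall, atrioventricular node (AVN) bridging the ring, His
#' bundle (HIS) and bundle branches (BNL) descending through the cavity, and
#' a Purkinje layer (PKJ) lining the ventricular endocardium.
#'
#' All lengths are centimetres.  Axes: x points to the subject's left,
#' y cranially, z anteriorly; voxels are cell-centered with 0-based physical
#' origin at the torso's lower-right-posterior corner.
#'
#' @param resolution integer vector `c(nx, ny, nz)`; at least 16 per axis.
#' @return a nested list understood by [build_torso_geometry()].  Setting an
#'   organ's size fields to zero removes it (a config with every organ
#'   removed yields a homogeneous trunk).
#' @export
torso_geometry_config <- function(resolution = c(40L, 48L, 24L)) {
  list(
    resolution = as.integer(resolution),
    # trunk elliptic cylinder: semi-axes (cm) and height (cm)
    trunk = list(semi_x = 17, semi_z = 11, height = 60),
    layers = list(fat_cm = 1.0, muscle_cm = 1.2),
    spine = list(radius = 2.2, center_z = -8),
    lungs = list(center_x = 8.5, center_y = 40, center_z = -1,
                 semi = c(5.5, 12, 6.5)),
    heart = list(
      center = c(3, 35, 2.5), radius = 5.0,
      ventricular_wall = 2.0, atrial_wall = 1.6,
      ring_y_offset = 1.25, ring_halfwidth = 0.8,
      purkinje_cm = 1.0,
      # conduction-cluster centers as offsets from the heart center
      san = list(offset = c(-2.5, 3.8, 0), radius = 2.0),
      avn = list(offset = c(-1.0, 1.25, -2.0), radius = 1.4),
      his = list(radius = 0.9, length = 2.0),
      bnl = list(radius = 0.9, length = 1.8)
    ),
    conductivities = NULL  # named overrides of the published values, mS/m
  )
}

.geom_labels <- c("TORSO", "MUSCLE", "FAT", "BONE", "LUNG", "BLOOD",
                  "SAN", "ATR", "AVN", "HIS", "BNL", "PKJ", "VTR")
.heart_labels <- c("SAN", "ATR", "AVN", "HIS", "BNL", "PKJ", "VTR")

#' Build the voxelized torso volume conductor
#'
#' Rasterizes the configured anatomy onto a regular voxel grid, assigning
#' every in-trunk voxel exactly one subdomain label and the published
#' passive conductivity of that tissue.
#'
#' @param config a configuration list from [torso_geometry_config()] (or a
#'   YAML file read with [read_geometry_config()]).
#' @return an object of class `torso_geometry`: list with `dims`, `spacing`
#'   (cm per voxel along x/y/z), `labels` (3-D character array, `NA` outside
#'   the trunk), `sigma0` (3-D numeric array, mS/m), `domain` / `surface`
#'   (3-D logical arrays), `centers` (per-axis voxel-center coordinates, cm)
#'   and the `config` used.
#' @export
build_torso_geometry <- function(config = torso_geometry_config()) {
  res <- as.integer(config$resolution)
  if (length(res) != 3L || any(res < 16L))
    stop("grid resolution must be at least 16 voxels per axis")
  if (!is.null(config$conductivities)) {
    unknown <- setdiff(names(config$conductivities), names(.passive_conductivity))
    if (length(unknown))
      stop("unknown subdomain label(s) in conductivity config: ",
           paste(unknown, collapse = ", "))
  }
  tk <- config$trunk
  nx <- res[1]; ny <- res[2]; nz <- res[3]
  dx <- 2 * tk$semi_x / nx; dy <- tk$height / ny; dz <- 2 * tk$semi_z / nz
  xs <- -tk$semi_x + (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  zs <- -tk$semi_z + (seq_len(nz) - 0.5) * dz

  X <- array(rep(xs, times = ny * nz), dim = res)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = res)
  Z <- array(rep(zs, each = nx * ny), dim = res)

  rho <- sqrt((X / tk$semi_x)^2 + (Z / tk$semi_z)^2)
  domain <- rho <= 1

  lab <- array(NA_character_, dim = res)
  lab[domain] <- "TORSO"

  # concentric fat and muscle sheaths, thickness normalized by the smaller
  # trunk semi-axis so the printed thickness is honoured on the tight axis
  smin <- min(tk$semi_x, tk$semi_z)
  ly <- config$layers
  if (!is.null(ly) && ly$fat_cm > 0)
    lab[domain & rho > 1 - ly$fat_cm / smin] <- "FAT"
  if (!is.null(ly) && ly$muscle_cm > 0)
    lab[domain & rho <= 1 - ly$fat_cm / smin &
          rho > 1 - (ly$fat_cm + ly$muscle_cm) / smin] <- "MUSCLE"

  sp <- config$spine
  if (!is.null(sp) && sp$radius > 0)
    lab[domain & (X^2 + (Z - sp$center_z)^2) <= sp$radius^2] <- "BONE"

  lg <- config$lungs
  if (!is.null(lg) && all(lg$semi > 0)) {
    for (sgn in c(-1, 1)) {
      inl <- ((X - sgn * lg$center_x) / lg$semi[1])^2 +
        ((Y - lg$center_y) / lg$semi[2])^2 +
        ((Z - lg$center_z) / lg$semi[3])^2 <= 1
      lab[domain & inl] <- "LUNG"
    }
  }

  ht <- config$heart
  if (!is.null(ht) && ht$radius > 0) {
    hc <- ht$center
    r <- sqrt((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2)
    inside <- domain & r <= ht$radius
    y_ring <- hc[2] + ht$ring_y_offset
    wall <- ifelse(Y > y_ring, ht$atrial_wall, ht$ventricular_wall)
    shell <- inside & r > ht$radius - wall
    cavity <- inside & !shell
    lab[cavity] <- "BLOOD"
    lab[shell & Y > y_ring] <- "ATR"
    lab[shell & Y <= y_ring] <- "VTR"
    # Purkinje layer lines the ventricular endocardium
    pkj <- shell & Y <= y_ring & r <= ht$radius - ht$ventricular_wall + ht$purkinje_cm
    lab[pkj] <- "PKJ"
    # insulating atrioventricular ring (fibrous annulus) across the wall
    lab[shell & abs(Y - y_ring) <= ht$ring_halfwidth] <- "FAT"
    # conduction clusters override, painted proximal to distal; a cluster
    # whose sphere straddles voxel centers without containing one falls
    # back to the nearest eligible voxel so no cluster is ever empty
    .paint_sphere <- function(lab, ctr, rad, value, where = inside) {
      d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
      hit <- where & d2 <= rad^2
      if (!any(hit)) {
        d2[!where] <- Inf
        hit[which.min(d2)] <- TRUE
      }
      lab[hit] <- value
      lab
    }
    lab <- .paint_sphere(lab, hc + ht$san$offset, ht$san$radius, "SAN",
                         inside & r > ht$radius - wall)
    lab <- .paint_sphere(lab, hc + ht$avn$offset, ht$avn$radius, "AVN")
    av <- hc + ht$avn$offset
    his_y <- c(av[2] - ht$his$length, av[2])
    in_his <- inside & (X - av[1])^2 + (Z - av[3])^2 <= ht$his$radius^2 &
      Y >= his_y[1] & Y < his_y[2] & lab != "AVN"
    if (any(in_his)) lab[in_his] <- "HIS"
    else lab <- .paint_sphere(lab, c(av[1], mean(his_y), av[3]),
                              ht$his$radius, "HIS",
                              inside & lab != "AVN")
    bnl_y <- c(his_y[1] - ht$bnl$length, his_y[1])
    in_bnl <- inside & (X - av[1])^2 + (Z - av[3])^2 <= ht$bnl$radius^2 &
      Y >= bnl_y[1] & Y < bnl_y[2] & lab != "AVN" & lab != "HIS"
    if (any(in_bnl)) lab[in_bnl] <- "BNL"
    else lab <- .paint_sphere(lab, c(av[1], mean(bnl_y), av[3]),
                              ht$bnl$radius, "BNL",
                              inside & lab != "AVN" & lab != "HIS")
    if (!any(lab %in% .heart_labels))
      stop("heart region is empty at this resolution")
    # wall fragments that the grid detached from the conduction chain are
    # below resolution: absorb them into the trunk so the heart is one
    # connected, drivable component
    comp <- .component_ids(array(lab %in% .heart_labels, dim = res))
    keep <- comp[which(lab == "SAN")[1]]
    stray <- which(comp > 0 & comp != keep)
    if (length(stray)) lab[stray] <- "TORSO"
  }

  sigma <- .passive_conductivity
  if (!is.null(config$conductivities))
    sigma[names(config$conductivities)] <- unlist(config$conductivities)
  sig_of <- function(l) {
    out <- sigma[l]
    out[l %in% .heart_labels] <- sigma[["HEART"]]
    unname(out)
  }
  sigma0 <- array(NA_real_, dim = res)
  sigma0[domain] <- sig_of(lab[domain])

  surface <- .domain_surface(domain)

  structure(
    list(dims = res, spacing = c(dx, dy, dz), labels = lab, sigma0 = sigma0,
         domain = domain, surface = surface,
         centers = list(x = xs, y = ys, z = zs), config = config),
    class = "torso_geometry"
  )
}

# label connected components (6-connectivity) of a logical voxel mask;
# returns an integer vector over the full grid (0 outside the mask)
.component_ids <- function(mask) {
  d <- dim(mask)
  comp <- integer(prod(d))
  idx <- which(mask)
  cur <- 0L
  for (s in idx) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(c0, d)
      for (ax in 1:3) for (dir in c(-1L, 1L)) {
        nb <- cc; nb[ax] <- nb[ax] + dir
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[lin] && comp[lin] == 0L) {
          comp[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  comp
}

# voxels of the domain with at least one out-of-domain 6-neighbour
.domain_surface <- function(domain) {
  d <- dim(domain)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- domain
  nbr_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  domain & !nbr_all
}

#' @export
print.torso_geometry <- function(x, ...) {
  cat(sprintf("torso_geometry: %d x %d x %d voxels (%.2f x %.2f x %.2f cm)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(x$labels[x$domain])
  print(tab)
  invisible(x)
}

#' Per-subdomain voxel counts and volume fractions
#'
#' @param geometry a `torso_geometry`.
#' @return data frame with label, voxel count and fraction of the trunk
#'   volume.
#' @export
subdomain_fractions <- function(geometry) {
  tab <- table(geometry$labels[geometry$domain])
  data.frame(label = names(tab), voxels = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), row.names = NULL)
}

#' Connected-component check for the heart region
#'
#' Flood-fills the heart voxels under 6-connectivity.
#'
#' @param geometry a `torso_geometry`.
#' @return number of connected components among heart-labeled voxels.
#' @export
heart_components <- function(geometry) {
  mask <- array(geometry$labels %in% .heart_labels, dim = geometry$dims)
  if (!any(mask)) return(0L)
  max(.component_ids(mask))
}

#' Place the Einthoven/Mason-Likar electrodes and the displaced montages
#'
#' The reference montage (position 0) follows the Mason-Likar torso
#' placement: LA and RA below the left/right clavipectoral triangles,
#' separated horizontally by the inter-triangle distance `Wh`, and LL (with
#' the RL ground opposite) at the lower abdomen, `Wv` below the sternal
#' angle.  Measurement positions 1-6 displace the montage in steps of
#' `f * Wh` horizontally and `f * Wv` vertically: the montage converges
#' towards the mid-chest (LA steps towards the midline and downwards, LL
#' towards the midline and upwards, RA horizontally towards the midline),
#' so the lead vectors rotate and shorten progressively and every electrode
#' stays on the trunk at all seven positions, as a compact wearable patch
#' would be.  The same layout is mirrored on the back.
#'
#' @param geometry a `torso_geometry` (provides the surface to anchor to).
#' @param Wh horizontal anthropometric distance, cm (inter-clavipectoral).
#' @param Wv vertical anthropometric distance, cm (sternal angle to
#'   umbilicus).
#' @param f step fraction, default 0.125.
#' @return an object of class `electrode_layout`: `step_cm` (the per-step
#'   horizontal/vertical displacement), `points` (7 x 2 matrix of the
#'   measurement-point path, front; the back path mirrors it), and
#'   `electrodes`, a data frame with one row per electrode
#'   (position 0-6, side, role LA/RA/LL/RL, x/y continuous cm and the
#'   nearest surface voxel indices).
#' @export
place_electrodes <- function(geometry, Wh = 28.8, Wv = 43.2, f = 0.125) {
  stopifnot(Wh > 0, Wv > 0, f >= 0, f < 0.5)
  tk <- geometry$config$trunk
  y_sternal <- 0.88 * tk$height          # sternal angle height
  y_clav <- y_sternal + 0.03 * tk$height # clavipectoral line just above
  y_umb <- y_sternal - Wv
  if (y_umb < 0)
    stop("electrode LL falls below the trunk: Wv too large for this geometry")
  ref <- list(
    LA = c(+Wh / 2, y_clav),
    RA = c(-Wh / 2, y_clav),
    LL = c(+Wh / 4, y_umb),
    RL = c(-Wh / 4, y_umb)
  )
  step <- c(h = f * Wh, v = f * Wv)
  # convergence direction per electrode: towards midline, towards mid-height
  dirs <- list(LA = c(-1, -1), RA = c(+1, 0), LL = c(-1, +1))

  rows <- list()
  pts <- matrix(NA_real_, 7, 2, dimnames = list(paste0("pos", 0:6), c("x", "y")))
  for (k in 0:6) {
    pts[k + 1, ] <- ref$LA + k * step * dirs$LA
    for (side in c("front", "back")) {
      for (role in c("LA", "RA", "LL")) {
        xy <- ref[[role]] + k * step * dirs[[role]]
        if (side == "back") xy[1] <- -xy[1]  # mirror preserves handedness
        rows[[length(rows) + 1L]] <- data.frame(
          position = k, side = side, role = role, x = xy[1], y = xy[2])
      }
    }
  }
  for (side in c("front", "back")) {
    xy <- ref$RL
    if (side == "back") xy[1] <- -xy[1]
    rows[[length(rows) + 1L]] <- data.frame(
      position = NA_integer_, side = side, role = "RL", x = xy[1], y = xy[2])
  }
  el <- do.call(rbind, rows)

  vox <- .nearest_surface_voxel(geometry, el$x, el$y, el$side)
  el <- cbind(el, vox)

  structure(
    list(Wh = Wh, Wv = Wv, f = f, step_cm = step, points = pts,
         electrodes = el),
    class = "electrode_layout"
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("electrode_layout: Wh = %.1f cm, Wv = %.1f cm, f = %.3f\n",
              x$Wh, x$Wv, x$f))
  cat(sprintf("per-step displacement: %.2f cm horizontal, %.2f cm vertical\n",
              x$step_cm["h"], x$step_cm["v"]))
  cat(sprintf("%d electrode sites over 7 positions x front/back\n",
              nrow(x$electrodes)))
  invisible(x)
}

# map continuous (x, y, side) to nearest surface voxel on that side
.nearest_surface_voxel <- function(geometry, x, y, side) {
  d <- geometry$dims
  cs <- geometry$centers
  surf_idx <- which(geometry$surface)
  ci <- arrayInd(surf_idx, d)
  sx <- cs$x[ci[, 1]]; sy <- cs$y[ci[, 2]]; sz <- cs$z[ci[, 3]]
  is_front <- sz >= 0
  out <- matrix(NA_integer_, length(x), 3,
                dimnames = list(NULL, c("ix", "iy", "iz")))
  for (i in seq_along(x)) {
    if (y[i] < 0 || y[i] > max(cs$y) + geometry$spacing[2] ||
        abs(x[i]) > max(abs(cs$x)) + geometry$spacing[1])
      stop(sprintf("electrode point (%.1f, %.1f) falls outside the surface",
                   x[i], y[i]))
    sel <- if (side[i] == "front") is_front else !is_front
    dd <- (sx[sel] - x[i])^2 + (sy[sel] - y[i])^2
    j <- which(sel)[which.min(dd)]
    out[i, ] <- ci[j, ]
  }
  out
}

#' Read a geometry configuration from YAML
#'
#' @param path YAML file mirroring the structure of
#'   [torso_geometry_config()].
#' @return a configuration list.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- torso_geometry_config()
  utils::modifyList(base, cfg)
}

#' Export a geometry as a labeled-array text file plus JSON metadata
#'
#' Writes the label volume as a flat CSV (one row per in-trunk voxel) and a
#' JSON sidecar carrying grid shape, spacing and conductivities.
#'
#' @param geometry a `torso_geometry`.
#' @param path output CSV path; metadata is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  idx <- which(geometry$domain)
  ci <- arrayInd(idx, geometry$dims)
  df <- data.frame(ix = ci[, 1], iy = ci[, 2], iz = ci[, 3],
                   label = geometry$labels[idx],
                   sigma0 = geometry$sigma0[idx])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(dims = geometry$dims, spacing_cm = geometry$spacing,
               conductivities_mS_per_m = as.list(.passive_conductivity))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
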