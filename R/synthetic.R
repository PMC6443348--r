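# Synthetic vitreous-slab scenes: two spherical-cap menisci of different
# curvature and occupancy, barrel-shaped particles adsorbed with their
# damaged side toward the air, bulk particles in between, and subtomogram
# rendering with missing wedge and white noise.

#' Scene configuration
#'
#' Defaults describe the slab geometry this package is designed around: a
#' thin unsupported film bounded by a gently curved, densely populated
#' lower meniscus and a more strongly curved, sparse upper meniscus
#' (occupancy ratio 10:1), a damaged fraction of 0.9 among adsorbed
#' particles, von Mises-Fisher concentration kappa = 50 of the denatured
#' axis about the local air-side normal, and a missing wedge of 30 degrees
#' half-angle (tilt range +/-60 degrees). Curvature radii are
#' order-of-magnitude choices: no quantitative meniscus curvature is
#' available for real films, where it is likely stochastic.
#'
#' @param slab_thickness film thickness in Angstrom (center-to-center of
#'   the menisci at the field center).
#' @param field_size lateral (x, y) extent in Angstrom.
#' @param lower_curv_radius,upper_curv_radius spherical-cap radii in
#'   Angstrom (positive = bulging toward the air; `Inf` = flat).
#' @param n_lower,n_upper,n_bulk particle counts per region.
#' @param damaged_fraction fraction of adsorbed particles that are damaged,
#'   in `[0, 1]`.
#' @param kappa von Mises-Fisher concentration of the denatured axis about
#'   the air-side normal (>= 0; 0 = uniform; capped at 1e8).
#' @param snr signal-to-noise power ratio for rendered subtomograms
#'   (`Inf` = noise-free).
#' @param wedge_halfangle missing-wedge half-angle in degrees (30
#'   corresponds to a +/-60 degree tilt range).
#' @param seed integer seed; scenes are bit-reproducible from (config, seed).
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(slab_thickness = 1500, field_size = 4000,
                         lower_curv_radius = 30000, upper_curv_radius = 10000,
                         n_lower = 200, n_upper = 20, n_bulk = 20,
                         damaged_fraction = 0.9, kappa = 50, snr = 0.3,
                         wedge_halfangle = 30, seed = 1) {
  cfg <- list(slab_thickness = slab_thickness, field_size = field_size,
              lower_curv_radius = lower_curv_radius,
              upper_curv_radius = upper_curv_radius,
              n_lower = n_lower, n_upper = n_upper, n_bulk = n_bulk,
              damaged_fraction = damaged_fraction, kappa = kappa, snr = snr,
              wedge_halfangle = wedge_halfangle, seed = seed)
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    stopifnot(slab_thickness > 0, field_size > 0,
              n_lower >= 0, n_upper >= 0, n_bulk >= 0,
              damaged_fraction >= 0, damaged_fraction <= 1,
              kappa >= 0, snr > 0, wedge_halfangle >= 0,
              wedge_halfangle < 90)
    for (R in c(lower_curv_radius, upper_curv_radius)) {
      if (!is.infinite(R)) {
        rho_max <- field_size * sqrt(2) / 2
        if (R <= rho_max)
          stop("curvature radius must exceed the half field diagonal")
        sag <- R - sqrt(R^2 - rho_max^2)
        if (sag > slab_thickness / 2)
          stop(sprintf(
            "infeasible geometry: cap sagitta %.0f A exceeds half the slab thickness (%.0f A)",
            sag, slab_thickness / 2))
      }
    }
  })
  invisible(cfg)
}

#' Analytic meniscus height field
#'
#' Spherical-cap height of the configured meniscus over the field (caps
#' centered at `field_size / 2`): the lower surface sits near z = 0 and
#' bulges down toward the air below it, the upper surface near
#' z = `slab_thickness` and bulges up.
#'
#' @param cfg a [scene_config()].
#' @param side `"lower"` or `"upper"`.
#' @param xy M x 2 matrix or length-2 vector of planar positions (Angstrom).
#' @return numeric vector of heights z (Angstrom).
#' @export
meniscus_height <- function(cfg, side, xy) {
  xy <- rbind_xy(xy)
  rho2 <- (xy[, 1] - cfg$field_size / 2)^2 + (xy[, 2] - cfg$field_size / 2)^2
  if (side == "lower") {
    R <- cfg$lower_curv_radius
    if (is.infinite(R)) rep(0, nrow(xy)) else R - sqrt(R^2 - rho2)
  } else {
    R <- cfg$upper_curv_radius
    if (is.infinite(R)) rep(cfg$slab_thickness, nrow(xy))
    else cfg$slab_thickness - (R - sqrt(R^2 - rho2))
  }
}

#' Analytic air-side unit normal of a configured meniscus
#'
#' Exact (oracle) normals of the spherical-cap menisci, pointing into the
#' air: downward (-z-ish) for the lower meniscus, upward for the upper.
#'
#' @param cfg a [scene_config()].
#' @param side `"lower"` or `"upper"`.
#' @param xy M x 2 matrix or length-2 vector of planar positions (Angstrom).
#' @return M x 3 matrix of unit vectors.
#' @export
meniscus_normal <- function(cfg, side, xy) {
  xy <- rbind_xy(xy)
  dx <- xy[, 1] - cfg$field_size / 2
  dy <- xy[, 2] - cfg$field_size / 2
  R <- if (side == "lower") cfg$lower_curv_radius else cfg$upper_curv_radius
  if (is.infinite(R)) {
    n <- cbind(0 * dx, 0 * dy, 1)
  } else {
    # height field z = +/- (R - sqrt(R^2 - rho^2)); gradient = +/- rho / sqrt()
    s <- sqrt(R^2 - dx^2 - dy^2)
    if (side == "lower") {
      g <- cbind(dx / s, dy / s)        # dz/dx of the lower cap
    } else {
      g <- cbind(-dx / s, -dy / s)
    }
    n <- cbind(-g[, 1], -g[, 2], 1)
    n <- n / sqrt(rowSums(n^2))
  }
  if (side == "lower") n <- -n  # air below the lower meniscus
  n
}

# von Mises-Fisher sample on the unit sphere about mean direction mu.
rvmf <- function(n, mu, kappa) {
  mu <- unitize(mu)
  kappa <- min(kappa, 1e8)
  if (kappa == 0) {
    w <- runif(n, -1, 1)
  } else {
    u <- runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  theta <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local_v <- cbind(s * cos(theta), s * sin(theta), w)
  # rotate local +z onto mu
  if (all(abs(mu - c(0, 0, 1)) < 1e-12)) return(local_v)
  if (all(abs(mu - c(0, 0, -1)) < 1e-12)) return(local_v %*% diag(c(1, -1, -1)))
  ax <- unitize(c(-mu[2], mu[1], 0))  # axis = z x mu
  ang <- acos(clamp(mu[3], -1, 1))
  local_v %*% t(axis_angle_matrix(ax, ang))
}

axis_angle_matrix <- function(axis, angle) {
  axis <- unitize(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  K <- matrix(c(0, z, -y, -z, 0, x, y, -x, 0), 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Soft barrel phantom of an intact or damaged particle
#'
#' The intact phantom is a soft-edged barrel: an equatorial disk (the
#' "wheel") plus two polar domes along +z and -z, mirror- and axially
#' symmetric about the grid center. The damaged phantom is the same shape
#' with the +z dome removed and the adjacent upper third of the wheel
#' density attenuated by 50%, so its integrated density is between one half
#' and two thirds of the intact phantom (one third to one half of the
#' density missing). Densities are nonnegative; the construction is
#' deterministic.
#'
#' @param kind `"intact"` or `"damaged"`.
#' @param box cube edge in voxels (>= 32).
#' @param voxel_size Angstrom per voxel.
#' @return a [volume3d] with origin at 0.
#' @export
make_phantom <- function(kind = c("intact", "damaged"), box = 32,
                         voxel_size = 8) {
  kind <- match.arg(kind)
  if (box < 32) stop("box must be at least 32 voxels")
  c0 <- (box - 1) / 2
  ax <- (0:(box - 1)) - c0
  X <- array(ax, dim = c(box, box, box))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  soft <- function(t, tau = 1) 1 / (1 + exp(-t / tau))  # 1 inside, 0 outside
  rho <- sqrt(X^2 + Y^2)
  r_wheel <- 0.32 * box
  h_wheel <- 0.10 * box
  wheel <- soft(r_wheel - rho) * soft(h_wheel - abs(Z))
  r_dome <- 0.17 * box
  z_dome <- 0.26 * box
  dome_up <- soft(r_dome - sqrt(X^2 + Y^2 + (Z - z_dome)^2))
  dome_dn <- soft(r_dome - sqrt(X^2 + Y^2 + (Z + z_dome)^2))
  amp_dome <- 2.2
  dat <- wheel + amp_dome * (dome_up + dome_dn)
  if (kind == "damaged") {
    dat <- dat - amp_dome * dome_up
    atten <- Z > h_wheel / 3  # upper third of the wheel slab
    dat[atten] <- dat[atten] * 0.5
  }
  volume3d(dat, voxel_size = voxel_size, origin = c(0, 0, 0))
}

#' Simulate a vitreous-slab scene
#'
#' Places particles on the two spherical-cap menisci and in the bulk.
#' Adsorbed particles sit exactly on their meniscus; each draws a
#' denatured-side axis from a von Mises-Fisher distribution with mean equal
#' to the local air-side normal and concentration `kappa`, and is flagged
#' damaged with probability `damaged_fraction`. ZYZ Euler angles are
#' derived so that the rotation carries the phantom damage axis (+z) onto
#' the truth axis, with uniform in-plane spin; thus the particle equator
#' (its long axis) lies parallel to the local interface up to the vMF
#' noise. Bulk particles are positioned uniformly strictly between the
#' menisci with uniformly random orientation.
#'
#' @param cfg a [scene_config()].
#' @return object of class `scene`: list with `particles` (data.frame in
#'   the particle schema plus `damaged`, truth axis `axis_x/y/z` and
#'   analytic normal `normal_x/y/z` columns), `config`.
#' @export
simulate_scene <- function(cfg) {
  validate_scene_config(cfg)
  with_seed(cfg$seed, {
    place_surface <- function(n, side) {
      if (n == 0) return(NULL)
      xy <- cbind(runif(n, 0, cfg$field_size), runif(n, 0, cfg$field_size))
      z <- meniscus_height(cfg, side, xy)
      nrm <- meniscus_normal(cfg, side, xy)
      axis <- t(vapply(seq_len(n),
                       function(i) as.numeric(rvmf(1, nrm[i, ], cfg$kappa)),
                       numeric(3)))
      damaged <- runif(n) < cfg$damaged_fraction
      spin <- runif(n, 0, 360)
      data.frame(x = xy[, 1], y = xy[, 2], z = z,
                 rot = rad2deg(atan2(axis[, 2], axis[, 1])),
                 tilt = rad2deg(acos(clamp(axis[, 3], -1, 1))),
                 psi = spin,
                 meniscus = side, damaged = damaged,
                 axis_x = axis[, 1], axis_y = axis[, 2], axis_z = axis[, 3],
                 normal_x = nrm[, 1], normal_y = nrm[, 2], normal_z = nrm[, 3])
    }
    place_bulk <- function(n) {
      if (n == 0) return(NULL)
      xy <- cbind(runif(n, 0, cfg$field_size), runif(n, 0, cfg$field_size))
      zlo <- meniscus_height(cfg, "lower", xy)
      zhi <- meniscus_height(cfg, "upper", xy)
      margin <- 0.02 * cfg$slab_thickness
      z <- runif(n, zlo + margin, zhi - margin)
      rot <- runif(n, 0, 360)
      tilt <- rad2deg(acos(runif(n, -1, 1)))
      psi <- runif(n, 0, 360)
      axis <- t(vapply(seq_len(n), function(i)
        as.numeric(euler_to_matrix(c(rot[i], tilt[i], psi[i])) %*% c(0, 0, 1)),
        numeric(3)))
      data.frame(x = xy[, 1], y = xy[, 2], z = z,
                 rot = rot, tilt = tilt, psi = psi,
                 meniscus = "bulk", damaged = FALSE,
                 axis_x = axis[, 1], axis_y = axis[, 2], axis_z = axis[, 3],
                 normal_x = NA_real_, normal_y = NA_real_, normal_z = NA_real_)
    }
    parts <- rbind(place_surface(cfg$n_lower, "lower"),
                   place_surface(cfg$n_upper, "upper"),
                   place_bulk(cfg$n_bulk))
    parts <- cbind(data.frame(id = seq_len(nrow(parts))), parts,
                   data.frame(tomogram = "tomo1", class = NA))
    structure(list(particles = parts, config = cfg), class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  p <- x$particles
  cat(sprintf("<scene> %d particles (%d lower, %d upper, %d bulk), %d damaged\n",
              nrow(p), sum(p$meniscus == "lower"), sum(p$meniscus == "upper"),
              sum(p$meniscus == "bulk"), sum(p$damaged)))
  cat(sprintf("  slab %.0f A thick, field %.0f A, kappa = %.3g\n",
              x$config$slab_thickness, x$config$field_size, x$config$kappa))
  invisible(x)
}

#' Render subtomograms of a scene
#'
#' Per particle, the intact or damaged phantom is rotated by the particle's
#' Euler angles (trilinear interpolation), the missing wedge is optionally
#' zeroed in Fourier space (tilt axis y), and white Gaussian noise is added
#' at the configured signal-to-noise power ratio. Deterministic given
#' `seed`.
#'
#' @param scene a [simulate_scene()] result.
#' @param intact_phantom,damaged_phantom co-gridded [volume3d] phantoms.
#' @param snr signal-to-noise power ratio (default from the scene config;
#'   `Inf` = no noise).
#' @param wedge_halfangle missing-wedge half-angle in degrees (0 disables;
#'   default from the scene config).
#' @param seed integer noise seed (default the scene seed + 1).
#' @return a [subtomo_stack()] with particle ids matching the scene.
#' @export
render_subtomograms <- function(scene, intact_phantom, damaged_phantom,
                                snr = scene$config$snr,
                                wedge_halfangle = scene$config$wedge_halfangle,
                                seed = scene$config$seed + 1L) {
  stopifnot_same_grid(intact_phantom, damaged_phantom)
  d <- dim(intact_phantom$data)
  wmask <- if (wedge_halfangle > 0) wedge_mask(d, wedge_halfangle) else NULL
  p <- scene$particles
  with_seed(seed, {
    vols <- lapply(seq_len(nrow(p)), function(i) {
      ph <- if (isTRUE(p$damaged[i])) damaged_phantom else intact_phantom
      R <- euler_to_matrix(c(p$rot[i], p$tilt[i], p$psi[i]))
      dat <- array(cpp_rotate_vol(as.numeric(ph$data), as.integer(d), R), d)
      if (!is.null(wmask))
        dat <- Re(fft(fft(dat) * wmask, inverse = TRUE)) / prod(d)
      if (is.finite(snr)) {
        sig_pow <- mean(dat^2)
        dat <- dat + rnorm(prod(d), sd = sqrt(sig_pow / snr))
      }
      volume3d(dat, voxel_size = ph$voxel_size, origin = ph$origin)
    })
    subtomo_stack(vols, particle_ids = p$id)
  })
}

#' Export / re-import scene ground truth
#'
#' TSV (schema version 1) with one row per particle: position, Euler
#' angles, meniscus and damage labels, truth axis and the analytic
#' air-side normal at the particle. Re-import reproduces the numeric
#' columns exactly.
#'
#' @param scene a [simulate_scene()] result.
#' @param path output path.
#' @return `path` invisibly (`export_ground_truth`); a data.frame
#'   (`read_ground_truth`).
#' @export
export_ground_truth <- function(scene, path) {
  p <- scene$particles
  cols <- c("id", "x", "y", "z", "rot", "tilt", "psi", "tomogram", "meniscus",
            "damaged", "axis_x", "axis_y", "axis_z",
            "normal_x", "normal_y", "normal_z")
  num <- function(v) ifelse(is.na(v), "NA", fmt_num(v, 17))
  lines <- c("#ground_truth_schema\t1",
             paste(cols, collapse = "\t"),
             paste(p$id, num(p$x), num(p$y), num(p$z), num(p$rot),
                   num(p$tilt), num(p$psi), p$tomogram, p$meniscus,
                   p$damaged, num(p$axis_x), num(p$axis_y), num(p$axis_z),
                   num(p$normal_x), num(p$normal_y), num(p$normal_z),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#ground_truth_schema"))
    stop("not a ground-truth table (schema line missing)")
  read.table(text = lines[-1], header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}
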