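# Minimal subtomogram averaging: exhaustive rotation-grid alignment,
# gold-standard half-set averaging with FSC, multi-reference classification.

#' Near-uniform ZYZ rotation grid
#'
#' Rotation search grid with approximately uniform coverage: `tilt` sampled
#' at `angular_step` from 0 to 180 degrees, `rot` (azimuth of the rotated z
#' axis) sampled at each tilt ring so that arc spacing matches
#' `angular_step` (one value at the poles), `psi` (in-plane spin) at
#' `angular_step` over `[0, 360)`. Rows are sorted lexicographically by
#' `(rot, tilt, psi)`; alignment ties resolve to the earliest row, so equal
#' scores break to the lexicographically lowest angles.
#'
#' @param angular_step grid step in degrees (> 0).
#' @return data.frame with columns `rot`, `tilt`, `psi` (degrees).
#' @export
euler_grid <- function(angular_step) {
  if (!is.finite(angular_step) || angular_step <= 0)
    stop("`angular_step` must be > 0 degrees")
  tilts <- seq(0, 180, by = angular_step)
  if (tilts[length(tilts)] < 180) tilts <- c(tilts, 180)
  rows <- list()
  for (tilt in tilts) {
    st <- sin(deg2rad(tilt))
    n_az <- max(1L, as.integer(round(360 * st / angular_step)))
    rots <- if (n_az == 1L) 0 else seq(0, 360, length.out = n_az + 1)[seq_len(n_az)]
    psis <- seq(0, 360 - angular_step, by = angular_step)
    rows[[length(rows) + 1]] <- expand.grid(rot = rots, tilt = tilt, psi = psis)
  }
  g <- do.call(rbind, rows)
  g <- g[order(g$rot, g$tilt, g$psi), , drop = FALSE]
  rownames(g) <- NULL
  g
}

grid_rotmats <- function(grid) {
  t(vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(euler_to_matrix(c(grid$rot[i], grid$tilt[i], grid$psi[i])))
  }, numeric(9)))
}

#' Align one subtomogram against a reference
#'
#' Exhaustive search over the [euler_grid()] at `angular_step`; for each
#' candidate rotation the reference is rotated into the particle frame and
#' the best circular integer shift within `shift_max` voxels is found by
#' zero-mean normalized cross-correlation. Deterministic: ties break to the
#' lexicographically lowest `(rot, tilt, psi)`.
#'
#' @param vol particle [volume3d].
#' @param reference reference [volume3d], same box.
#' @param angular_step rotation grid step in degrees (default 15).
#' @param shift_max maximum translation searched, voxels (default 2).
#' @param lowpass optional low-pass resolution (Angstrom) applied to both
#'   volumes before scoring.
#' @param mask optional real-space [volume3d] mask multiplied onto the
#'   rotated reference and the particle before scoring.
#' @param wedge optional missing-wedge half-angle in degrees; when given,
#'   the rotated reference is reweighted in Fourier space by the particle's
#'   wedge mask before scoring (constrained correlation). Off by default.
#' @param rotations optional data.frame `(rot, tilt, psi)` overriding the
#'   search grid (used for local refinement around a prior).
#' @return list with `euler` (rot, tilt, psi, degrees), `shift` (voxels),
#'   `score` (normalized cross-correlation), `scores` (per candidate).
#' @export
align_particle <- function(vol, reference, angular_step = 15, shift_max = 2,
                           lowpass = NULL, mask = NULL, wedge = NULL,
                           rotations = NULL) {
  stopifnot_same_grid(vol, reference)
  if (!is.null(lowpass)) {
    vol <- bandpass_filter(vol, Inf, lowpass)
    reference <- bandpass_filter(reference, Inf, lowpass)
  }
  grid <- rotations %||% euler_grid(angular_step)
  rms <- grid_rotmats(grid)
  d <- dim(vol$data)
  vdat <- vol$data
  if (!is.null(mask)) {
    stopifnot_same_grid(vol, mask)
    vdat <- vdat * mask$data
  }
  if (is.null(wedge)) {
    res <- cpp_align(as.numeric(vdat), as.numeric(reference$data),
                     as.integer(d), rms, as.integer(shift_max),
                     if (is.null(mask)) NULL else as.numeric(mask$data))
  } else {
    wmask <- wedge_mask(d, wedge)
    best <- list(score = -2)
    scores <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      rot <- cpp_rotate_vol(as.numeric(reference$data), as.integer(d),
                            matrix(rms[r, ], 3, 3))
      rot <- Re(fft(fft(array(rot, d)) * wmask, inverse = TRUE)) / prod(d)
      if (!is.null(mask)) rot <- rot * mask$data
      one <- cpp_align(as.numeric(vdat), as.numeric(rot), as.integer(d),
                       matrix(as.numeric(diag(3)), 1, 9),
                       as.integer(shift_max), NULL)
      scores[r] <- one$score
      if (one$score > best$score + 1e-15)
        best <- list(idx = r, shift = one$shift, score = one$score)
    }
    res <- list(best_index = best$idx, shift = best$shift,
                score = best$score, scores = scores)
  }
  list(euler = as.numeric(grid[res$best_index, c("rot", "tilt", "psi")]),
       shift = as.integer(res$shift),
       score = res$score,
       scores = res$scores)
}

# Transform a particle into the reference frame given its alignment.
# Alignment model: particle(x) = (rotated reference)(x + shift), i.e. the
# particle is the rotated reference translated by -shift; undo the
# translation (translate by +shift), then the rotation.
align_back <- function(vol, euler, shift) {
  d <- dim(vol$data)
  dat <- cpp_shift_vol(as.numeric(vol$data), as.integer(d),
                       as.integer(shift))
  R <- euler_to_matrix(euler)
  dat <- cpp_rotate_vol(dat, as.integer(d), t(R))
  volume3d(array(dat, d), voxel_size = vol$voxel_size, origin = vol$origin)
}

average_volumes <- function(vols) {
  stopifnot(length(vols) >= 1)
  acc <- vols[[1]]$data
  for (i in seq_along(vols)[-1]) acc <- acc + vols[[i]]$data
  volume3d(acc / length(vols), voxel_size = vols[[1]]$voxel_size,
           origin = vols[[1]]$origin)
}

#' Build a subtomogram stack
#'
#' @param volumes list of co-gridded [volume3d] objects.
#' @param particle_ids parallel vector of unique ids (default sequential).
#' @return object of class `subtomo_stack`.
#' @export
subtomo_stack <- function(volumes, particle_ids = seq_along(volumes)) {
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]]$data)
  for (v in volumes) {
    stopifnot(inherits(v, "volume3d"))
    if (!identical(dim(v$data), d)) stop("stack volumes must share one box size")
  }
  if (anyDuplicated(particle_ids)) stop("particle ids must be unique")
  structure(list(volumes = volumes, particle_ids = particle_ids,
                 half_assignment = NULL),
            class = "subtomo_stack")
}

#' @export
print.subtomo_stack <- function(x, ...) {
  d <- dim(x$volumes[[1]]$data)
  cat(sprintf("<subtomo_stack> %d particles, box %d x %d x %d, %.4g A/voxel\n",
              length(x$volumes), d[1], d[2], d[3], x$volumes[[1]]$voxel_size))
  invisible(x)
}

#' Gold-standard half-set averaging
#'
#' Particles are split randomly into two halves; each half is refined fully
#' independently: the initial reference is the plain average of `n_seed`
#' randomly chosen (unaligned) particles of that half, then align-all /
#' average iterations follow. No symmetry is applied. The two final
#' half-maps and their FSC are returned, so the FSC is an unbiased
#' resolution estimate.
#'
#' @param stack a [subtomo_stack()] with at least `2 * n_seed` particles.
#' @param n_seed number of random seed particles for the initial reference
#'   (default 20).
#' @param iterations number of align/average iterations per half.
#' @param angular_step grid step in degrees; may be a vector (one entry per
#'   iteration) to refine the search over iterations.
#' @param shift_max translation search radius in voxels.
#' @param seed integer seed controlling the half split and seed-particle
#'   choice.
#' @param mask optional mask for the final FSC.
#' @return list with `half_a`, `half_b` ([volume3d]), `fsc` (`fsc_curve`),
#'   `alignments` (data.frame: particle_id, half, rot, tilt, psi, shifts,
#'   score), `halves` (the particle-id partition).
#' @export
gold_standard_average <- function(stack, n_seed = 20, iterations = 2,
                                  angular_step = 15, shift_max = 2,
                                  seed = 1, mask = NULL) {
  np <- length(stack$volumes)
  if (np < 2 * n_seed)
    stop(sprintf("stack too small: %d particles, need at least 2 * n_seed = %d",
                 np, 2 * n_seed))
  steps <- rep_len(angular_step, iterations)
  perm <- with_seed(seed, sample.int(np))
  half_idx <- list(A = sort(perm[seq_len(np %/% 2)]),
                   B = sort(perm[(np %/% 2 + 1):np]))
  seed_pick <- with_seed(seed + 1L, lapply(half_idx, function(ix)
    sort(sample(ix, n_seed))))
  refine_half <- function(ix, seeds) {
    ref <- average_volumes(stack$volumes[seeds])
    align <- NULL
    for (it in seq_len(iterations)) {
      align <- lapply(ix, function(i)
        align_particle(stack$volumes[[i]], ref, angular_step = steps[it],
                       shift_max = shift_max))
      ref <- average_volumes(mapply(function(i, al)
        align_back(stack$volumes[[i]], al$euler, al$shift),
        ix, align, SIMPLIFY = FALSE))
    }
    list(map = ref, align = align)
  }
  resA <- refine_half(half_idx$A, seed_pick$A)
  resB <- refine_half(half_idx$B, seed_pick$B)
  curve <- fsc(resA$map, resB$map, mask = mask)
  tab <- function(ix, res, half) {
    do.call(rbind, mapply(function(i, al) {
      data.frame(particle_id = stack$particle_ids[i], half = half,
                 rot = al$euler[1], tilt = al$euler[2], psi = al$euler[3],
                 shift_x = al$shift[1], shift_y = al$shift[2],
                 shift_z = al$shift[3], score = al$score)
    }, ix, res$align, SIMPLIFY = FALSE))
  }
  list(half_a = resA$map, half_b = resB$map, fsc = curve,
       alignments = rbind(tab(half_idx$A, resA, "A"),
                          tab(half_idx$B, resB, "B")),
       halves = list(A = stack$particle_ids[half_idx$A],
                     B = stack$particle_ids[half_idx$B]))
}

#' Multi-reference alignment and classification
#'
#' Each iteration aligns every particle against every class map, assigns it
#' to the best-scoring class, and recomputes the class averages from the
#' aligned members. Initial references are low-pass filtered to
#' `ref_lowpass` (50 Angstrom by default) to avoid reference bias. Stops
#' when assignments stabilize or at `iterations`. A class left empty keeps
#' its previous map and is flagged.
#'
#' When alignment priors are available (e.g. from a preceding consensus
#' refinement), pass them as `alignments` and the rotation search is
#' restricted to perturbations of each particle's prior orientation by up
#' to `angular_step` about each axis, which is both faster and the standard
#' practice for classification after alignment.
#'
#' @param stack a [subtomo_stack()].
#' @param references list of at least two co-gridded [volume3d] maps.
#' @param ref_lowpass low-pass resolution for the initial references
#'   (Angstrom, default 50).
#' @param iterations maximum iterations (default 5).
#' @param angular_step rotation grid step in degrees.
#' @param shift_max translation search radius in voxels.
#' @param seed integer seed (order-independent algorithm; kept for the
#'   determinism contract).
#' @param alignments optional data.frame with columns `rot`, `tilt`, `psi`
#'   (rows parallel to the stack): prior orientations around which a local
#'   search is performed.
#' @return object of class `class_model`: list with `class_maps`,
#'   `assignments` (integer class per particle, named by particle id),
#'   `occupancies` (fractions summing to 1), `scores`, `n_iterations`,
#'   `empty_flagged`.
#' @export
multi_reference_classify <- function(stack, references, ref_lowpass = 50,
                                     iterations = 5, angular_step = 15,
                                     shift_max = 2, seed = 1,
                                     alignments = NULL) {
  if (length(references) < 2) stop("need at least two references")
  for (r in references) stopifnot_same_grid(stack$volumes[[1]], r)
  np <- length(stack$volumes)
  class_maps <- lapply(references, bandpass_filter, low_res = Inf,
                       high_res = ref_lowpass)
  rot_sets <- NULL
  if (!is.null(alignments)) {
    stopifnot(nrow(alignments) == np)
    pert <- local_perturbations(angular_step)
    rot_sets <- lapply(seq_len(np), function(i) {
      R0 <- euler_to_matrix(c(alignments$rot[i], alignments$tilt[i],
                              alignments$psi[i]))
      g <- t(vapply(pert, function(P) matrix_to_euler(R0 %*% P), numeric(3)))
      data.frame(rot = g[, 1], tilt = g[, 2], psi = g[, 3])
    })
  }
  assign_prev <- rep(0L, np)
  assignment <- rep(1L, np)
  scores <- numeric(np)
  empty_flagged <- integer(0)
  it <- 0L
  aligned <- vector("list", np)
  while (it < iterations && !identical(assignment, assign_prev)) {
    it <- it + 1L
    assign_prev <- assignment
    for (i in seq_len(np)) {
      best <- list(score = -2)
      for (cl in seq_along(class_maps)) {
        al <- align_particle(stack$volumes[[i]], class_maps[[cl]],
                             angular_step = angular_step,
                             shift_max = shift_max,
                             rotations = if (is.null(rot_sets)) NULL
                                         else rot_sets[[i]])
        if (al$score > best$score + 1e-15) best <- c(al, list(class = cl))
      }
      assignment[i] <- best$class
      scores[i] <- best$score
      aligned[[i]] <- align_back(stack$volumes[[i]], best$euler, best$shift)
    }
    for (cl in seq_along(class_maps)) {
      members <- which(assignment == cl)
      if (length(members) == 0) {
        empty_flagged <- union(empty_flagged, cl)
      } else {
        class_maps[[cl]] <- average_volumes(aligned[members])
      }
    }
  }
  occ <- tabulate(assignment, nbins = length(class_maps)) / np
  structure(list(class_maps = class_maps,
                 assignments = stats::setNames(assignment, stack$particle_ids),
                 occupancies = occ,
                 scores = scores,
                 n_iterations = it,
                 empty_flagged = empty_flagged),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> %d classes, %d particles, %d iteration(s)\n",
              length(x$class_maps), length(x$assignments), x$n_iterations))
  cat("  occupancies:", paste(sprintf("%.3f", x$occupancies), collapse = " "),
      "\n")
  if (length(x$empty_flagged) > 0)
    cat("  empty classes retained:", paste(x$empty_flagged, collapse = " "), "\n")
  invisible(x)
}

# Small rotation perturbation set: identity plus +/- angular_step about each
# coordinate axis (7 candidates), used for local refinement around a prior.
local_perturbations <- function(angular_step) {
  a <- deg2rad(angular_step)
  axis_rot <- function(axis, ang) {
    c1 <- cos(ang); s1 <- sin(ang)
    switch(axis,
           x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3),
           y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3),
           z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3))
  }
  out <- list(diag(3))
  for (ax in c("x", "y", "z"))
    for (s in c(-1, 1))
      out[[length(out) + 1]] <- axis_rot(ax, s * a)
  out
}

#' Binary missing-wedge mask in Fourier space
#'
#' Tilt axis along y; the wedge of half-angle `halfangle` about the kz axis
#' (the region never sampled by a tilt range of +/-(90 - halfangle)
#' degrees) is zeroed. A tilt range of +/-60 degrees corresponds to a
#' 30-degree half-angle. The DC term and the tilt axis itself are kept.
#'
#' @param dim volume dimensions.
#' @param halfangle wedge half-angle in degrees.
#' @return array of 0/1 weights in unshifted FFT layout.
#' @export
wedge_mask <- function(dim, halfangle) {
  kx <- fft_index(dim[1]) / dim[1]
  kz <- fft_index(dim[3]) / dim[3]
  akx <- array(abs(kx), dim = dim)
  akz <- aperm(array(abs(kz), dim = dim[c(3, 2, 1)]), c(3, 2, 1))
  missing <- atan2(akx, akz) < deg2rad(halfangle) & (akx + akz > 0)
  array(as.numeric(!missing), dim = dim)
}
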