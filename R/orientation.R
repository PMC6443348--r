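# Per-particle denaturation directions and displacement angles against the
# interface normal.
#
# Euler convention used throughout the package: intrinsic ZYZ angles
# (rot, tilt, psi) in degrees, acting on column vectors, carrying
# reference-frame vectors into the tomogram frame:
#   R(rot, tilt, psi) = Rz(rot) %*% Ry(tilt) %*% Rz(psi).

#' ZYZ Euler angles to rotation matrix
#'
#' Intrinsic ZYZ convention, degrees; `R` carries reference-frame column
#' vectors into the tomogram frame. `euler_to_matrix(c(0, 180, 0))` maps
#' `(0,0,1)` to `(0,0,-1)`.
#'
#' @param euler length-3 numeric `(rot, tilt, psi)` in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(length(euler) == 3, all(is.finite(euler)))
  e <- deg2rad(euler)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(e[1]) %*% ry(e[2]) %*% rz(e[3])
}

#' Rotation matrix to ZYZ Euler angles
#'
#' Inverse of [euler_to_matrix()]. At the gimbal singularities (tilt 0 or
#' 180 degrees) `psi` is set to 0 and the full in-plane angle reported as
#' `rot`.
#'
#' @param R 3 x 3 rotation matrix.
#' @return length-3 numeric `(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(all(dim(R) == c(3, 3)))
  ct <- clamp(R[3, 3], -1, 1)
  tilt <- acos(ct)
  if (abs(abs(ct) - 1) < 1e-12) {
    rot <- if (ct > 0) atan2(R[2, 1], R[1, 1])
           else atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  rad2deg(c(rot, tilt, psi))
}

# Geodesic distance between two rotations, degrees.
rotation_angle_between <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  rad2deg(acos(clamp((tr - 1) / 2, -1, 1)))
}

#' Reference denaturation direction from intact and denatured averages
#'
#' The direction of the missing density in the reference frame: the unit
#' vector from the center of the intact map to the center of mass of the
#' clamped difference map (intact minus denatured). By construction of
#' subtomogram averaging the particle sits at the grid center, so the grid
#' center is used as the particle center by default; the density-weighted
#' center of the intact map is available via `center = "com"`.
#'
#' @param intact,denat co-gridded [volume3d] reference maps.
#' @param center `"grid"` (geometric grid center, default) or `"com"`.
#' @param threshold density threshold passed to [center_of_mass()].
#' @return unit 3-vector in the reference frame.
#' @export
reference_denaturation_vector <- function(intact, denat,
                                          center = c("grid", "com"),
                                          threshold = 0) {
  center <- match.arg(center)
  stopifnot_same_grid(intact, denat)
  dmap <- withCallingHandlers(
    difference_map(intact, denat, clamp_negative = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  if (all(dmap$data == 0))
    stop("maps identical: no missing density to orient")
  com <- center_of_mass(dmap, threshold = threshold)
  ctr <- if (center == "grid") grid_center(intact)
         else center_of_mass(intact, threshold = threshold)
  v <- com - ctr
  if (vnorm(v) < 0.25 * intact$voxel_size)
    stop(sprintf(
      "degenerate direction: missing-density center within %.3g A (0.25 voxel) of the particle center",
      0.25 * intact$voxel_size))
  unitize(v)
}

#' Rotate the reference denaturation direction into every particle
#'
#' Applies each particle's ZYZ orientation to the reference-frame direction
#' `p_ref`: `P_denat(tomogram) = R(rot, tilt, psi) %*% p_ref`.
#'
#' @param particles data.frame with columns `rot`, `tilt`, `psi` (degrees);
#'   the particle-table schema of [read_particles()].
#' @param p_ref unit 3-vector in the reference frame.
#' @return N x 3 matrix of unit vectors in the tomogram frame.
#' @export
particle_denaturation_vectors <- function(particles, p_ref) {
  stopifnot(all(c("rot", "tilt", "psi") %in% names(particles)))
  p_ref <- unitize(as.numeric(p_ref))
  out <- t(vapply(seq_len(nrow(particles)), function(i) {
    as.numeric(euler_to_matrix(c(particles$rot[i], particles$tilt[i],
                                 particles$psi[i])) %*% p_ref)
  }, numeric(3)))
  out / sqrt(rowSums(out^2))
}

#' Displacement angle of each particle against the interface normal
#'
#' For every non-bulk particle, the angle `delta = acos(P_denat . P_normal)`
#' in degrees between its denaturation direction and the air-side unit
#' normal of its fitted meniscus at the particle's (x, y). `delta = 0` means
#' the denatured side points exactly at the air; the range `[0, 180]` is
#' kept unfolded because toward versus away from the air is the question.
#' Bulk particles are excluded (with a message reporting the count), not
#' assigned to a nearest surface.
#'
#' @param particles data.frame with columns `id`, `x`, `y`, `tomogram`,
#'   `meniscus` (values `"upper"`, `"lower"` or `"bulk"`).
#' @param vectors N x 3 matrix of unit denaturation vectors, rows parallel
#'   to `particles`.
#' @param surfaces named list of [tps_surface][fit_surface] objects keyed
#'   `"<tomogram>/<meniscus>"` (see [surface_key()]).
#' @return data.frame with columns `id`, `tomogram`, `meniscus`, `delta`
#'   (degrees); attribute `n_bulk_excluded` carries the excluded count.
#' @export
displacement_angles <- function(particles, vectors, surfaces) {
  stopifnot(nrow(particles) == nrow(vectors))
  keep <- particles$meniscus != "bulk"
  n_bulk <- sum(!keep)
  if (n_bulk > 0)
    message(sprintf("excluding %d bulk particle(s) from the displacement-angle analysis",
                    n_bulk))
  p <- particles[keep, , drop = FALSE]
  v <- vectors[keep, , drop = FALSE]
  delta <- numeric(nrow(p))
  for (key in unique(surface_key(p$tomogram, p$meniscus))) {
    sel <- surface_key(p$tomogram, p$meniscus) == key
    surf <- surfaces[[key]]
    if (is.null(surf))
      stop(sprintf("no fitted surface for '%s'", key))
    nrm <- surface_normal(surf, cbind(p$x[sel], p$y[sel]))
    delta[sel] <- rad2deg(acos(clamp(rowSums(v[sel, , drop = FALSE] * nrm), -1, 1)))
  }
  out <- data.frame(id = p$id, tomogram = p$tomogram, meniscus = p$meniscus,
                    delta = delta)
  attr(out, "n_bulk_excluded") <- n_bulk
  out
}

#' Key used to look up the fitted surface of a (tomogram, meniscus) pair
#' @param tomogram,meniscus character vectors.
#' @return character vector `"<tomogram>/<meniscus>"`.
#' @export
surface_key <- function(tomogram, meniscus) paste(tomogram, meniscus, sep = "/")

#' Bin displacement angles at a fixed sampling step
#'
#' Fixed edges `0, 7.5, ..., 180` degrees (24 bins at the default step);
#' bins are left-closed, the last bin right-closed. The sine-corrected
#' density divides each count by `sin(bin center)`, the solid-angle weight;
#' under uniformly random directions the corrected profile is flat.
#'
#' @param deltas numeric vector of angles in `[0, 180]` degrees, or the
#'   data.frame produced by [displacement_angles()].
#' @param bin_width bin width in degrees; must divide 180 (default 7.5).
#' @return object of class `angle_distribution`: data.frame with
#'   `bin_start`, `bin_end`, `bin_center`, `count`, `sine_corrected`.
#' @export
angle_histogram <- function(deltas, bin_width = 7.5) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  if (length(deltas) == 0) stop("no angles to bin")
  if (any(!is.finite(deltas)) || any(deltas < 0) || any(deltas > 180))
    stop("all angles must be finite and within [0, 180] degrees")
  nb <- 180 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("`bin_width` must divide 180 degrees")
  nb <- as.integer(round(nb))
  idx <- pmin(floor(deltas / bin_width) + 1L, nb)  # right-close last bin
  counts <- tabulate(idx, nbins = nb)
  edges <- seq(0, 180, by = bin_width)
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  out <- data.frame(bin_start = edges[-(nb + 1)], bin_end = edges[-1],
                    bin_center = centers, count = counts,
                    sine_corrected = counts / sin(deg2rad(centers)))
  class(out) <- c("angle_distribution", "data.frame")
  attr(out, "n") <- length(deltas)
  out
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("<angle_distribution> %d angles in %d bins of %.3g deg\n",
              attr(x, "n"), nrow(x), x$bin_end[1] - x$bin_start[1]))
  cum <- cumsum(x$count) / sum(x$count)
  below30 <- sum(x$count[x$bin_end <= 30]) / sum(x$count)
  cat(sprintf("  fraction of angles below 30 deg: %.3f\n", below30))
  med_bin <- which(cum >= 0.5)[1]
  cat(sprintf("  median bin: [%g, %g) deg\n",
              x$bin_start[med_bin], x$bin_end[med_bin]))
  invisible(x)
}

#' @export
plot.angle_distribution <- function(x, corrected = FALSE, ...) {
  h <- if (corrected) x$sine_corrected else x$count
  barplot(h, names.arg = x$bin_center, xlab = "displacement angle (deg)",
          ylab = if (corrected) "sine-corrected density" else "count", ...)
  invisible(x)
}

#' Write an angle distribution as TSV
#' @param dist an `angle_distribution`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_histogram_tsv <- function(dist, path) {
  lines <- c("bin_start\tbin_end\tcount\tsine_corrected",
             paste(fmt_num(dist$bin_start), fmt_num(dist$bin_end),
                   fmt_num(dist$count), fmt_num(dist$sine_corrected),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BILD emission (plain-text graphics primitives readable by ChimeraX)

#' Write vectors or an angle distribution as a BILD file
#'
#' For a matrix of unit vectors with anchor positions, one `.arrow` record
#' is emitted per vector, from the anchor to `anchor + scale * vector`. For
#' an [angle_histogram()] result, a fan of arrows in the x-z plane is
#' emitted, one per bin at the bin-center polar angle from +z, with length
#' proportional to the bin count.
#'
#' @param x N x 3 matrix of vectors, or an `angle_distribution`.
#' @param path output path.
#' @param scale arrow length scale (Angstrom per unit vector, or Angstrom
#'   for the largest histogram bin).
#' @param anchors N x 3 matrix of arrow base points (default origin).
#' @param color BILD color name.
#' @return `path`, invisibly.
#' @export
write_bild <- function(x, path, scale = 1, anchors = NULL, color = "orange") {
  if (inherits(x, "angle_distribution")) {
    theta <- deg2rad(x$bin_center)
    len <- scale * x$count / max(x$count, 1)
    vecs <- cbind(sin(theta), 0, cos(theta)) * len
    anchors <- matrix(0, nrow(vecs), 3)
  } else {
    vecs <- as.matrix(x)
    stopifnot(ncol(vecs) == 3)
    if (is.null(anchors)) anchors <- matrix(0, nrow(vecs), 3)
    anchors <- as.matrix(anchors)
    stopifnot(identical(dim(anchors), dim(vecs)))
    vecs <- vecs * scale
  }
  tips <- anchors + vecs
  lines <- c(paste(".color", color),
             paste(".arrow",
                   fmt_num(anchors[, 1], 6), fmt_num(anchors[, 2], 6),
                   fmt_num(anchors[, 3], 6),
                   fmt_num(tips[, 1], 6), fmt_num(tips[, 2], 6),
                   fmt_num(tips[, 3], 6)))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a BILD file written by [write_bild()]
#'
#' Reads `.arrow` records back into base points and tip points; used for
#' round-trip checks and quick QC.
#'
#' @param path a BILD file.
#' @return list with matrices `from`, `to` and the last `.color` seen.
#' @export
read_bild <- function(path) {
  lines <- readLines(path)
  col <- NA_character_
  from <- NULL; to <- NULL
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 0) next
    if (parts[1] == ".color") col <- paste(parts[-1], collapse = " ")
    if (parts[1] == ".arrow") {
      v <- as.numeric(parts[2:7])
      from <- rbind(from, v[1:3])
      to <- rbind(to, v[4:6])
    }
  }
  list(from = from, to = to, color = col)
}

# ---------------------------------------------------------------------------
# Particle tables

PARTICLE_COLUMNS <- c("id", "x", "y", "z", "rot", "tilt", "psi",
                      "tomogram", "meniscus", "class")

#' Read / write the particle metadata table
#'
#' TSV with header columns `id, x, y, z, rot, tilt, psi, tomogram,
#' meniscus, class`: positions in Angstrom, ZYZ Euler angles in degrees,
#' `meniscus` one of `upper`, `lower`, `bulk`.
#'
#' @param path TSV path.
#' @return data.frame in the package's particle schema.
#' @export
read_particles <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "x", "y", "z", "rot", "tilt", "psi"), names(tab))
  if (length(missing) > 0)
    stop(sprintf("particle table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (is.null(tab$tomogram)) tab$tomogram <- "tomo"
  if (is.null(tab$meniscus)) tab$meniscus <- "bulk"
  if (is.null(tab$class)) tab$class <- NA
  tab
}

#' @rdname read_particles
#' @param particles data.frame in the particle schema.
#' @export
write_particles <- function(particles, path) {
  p <- particles
  if (is.null(p$class)) p$class <- NA
  lines <- c(paste(PARTICLE_COLUMNS, collapse = "\t"),
             paste(p$id, fmt_num(p$x, 17), fmt_num(p$y, 17), fmt_num(p$z, 17),
                   fmt_num(p$rot, 17), fmt_num(p$tilt, 17), fmt_num(p$psi, 17),
                   p$tomogram, p$meniscus, p$class, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read particle metadata from a STAR file
#'
#' Minimal reader for the single-loop STAR tables used to exchange particle
#' orientations: maps `_rlnCoordinateX/Y/Z` (multiplied by `voxel_size`),
#' `_rlnAngleRot/Tilt/Psi` and `_rlnMicrographName` (or `_rlnTomoName`)
#' onto the package's particle schema.
#'
#' @param path STAR file path.
#' @param voxel_size Angstrom per pixel used to scale the coordinate tags
#'   (STAR coordinates are conventionally in pixels).
#' @return data.frame in the particle schema.
#' @export
read_star_particles <- function(path, voxel_size = 1) {
  lines <- readLines(path)
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  if (length(loop_at) == 0) stop("no loop_ block found in STAR file")
  i <- loop_at[length(loop_at)] + 1
  tags <- character(0)
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    tags <- c(tags, sub("\\s.*$", "", trimws(lines[i])))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "data_") || startsWith(ln, "#")) break
    rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
    i <- i + 1
  }
  if (length(rows) == 0) stop("empty STAR loop")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- tags
  get_num <- function(tag, default = NA_real_) {
    if (tag %in% names(tab)) as.numeric(tab[[tag]]) else default
  }
  n <- nrow(tab)
  tomo <- if ("_rlnTomoName" %in% names(tab)) tab[["_rlnTomoName"]]
          else if ("_rlnMicrographName" %in% names(tab)) tab[["_rlnMicrographName"]]
          else rep("tomo", n)
  data.frame(id = seq_len(n),
             x = get_num("_rlnCoordinateX") * voxel_size,
             y = get_num("_rlnCoordinateY") * voxel_size,
             z = get_num("_rlnCoordinateZ") * voxel_size,
             rot = get_num("_rlnAngleRot", 0),
             tilt = get_num("_rlnAngleTilt", 0),
             psi = get_num("_rlnAnglePsi", 0),
             tomogram = tomo,
             meniscus = "bulk",
             class = NA,
             stringsAsFactors = FALSE)
}
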