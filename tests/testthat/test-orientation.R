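# Denaturation vectors, displacement angles, histograms, BILD output.

test_that("ZYZ Euler convention behaves as documented", {
  expect_equal(euler_to_matrix(c(0, 0, 0)), diag(3), tolerance = 1e-15)
  expect_equal(as.numeric(euler_to_matrix(c(0, 180, 0)) %*% c(0, 0, 1)),
               c(0, 0, -1), tolerance = 1e-12)
  # rot is the azimuth of the rotated z axis
  v <- euler_to_matrix(c(90, 90, 0)) %*% c(0, 0, 1)
  expect_equal(as.numeric(v), c(0, 1, 0), tolerance = 1e-12)
  # matrix round trip over random rotations, including gimbal cases
  set.seed(5)
  for (i in 1:20) {
    e <- c(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi, runif(1, 0, 360))
    R <- euler_to_matrix(e)
    expect_equal(euler_to_matrix(matrix_to_euler(R)), R, tolerance = 1e-10)
  }
  for (tilt in c(0, 180)) {
    R <- euler_to_matrix(c(123, tilt, 45))
    expect_equal(euler_to_matrix(matrix_to_euler(R)), R, tolerance = 1e-10)
  }
})

test_that("reference denaturation vector points at the erased dome", {
  intact <- dome_phantom(erase = "none")
  top <- dome_phantom(erase = "top")
  bottom <- dome_phantom(erase = "bottom")
  v_top <- reference_denaturation_vector(intact, top)
  expect_angle_close(v_top, c(0, 0, 1), 5)
  v_bot <- reference_denaturation_vector(intact, bottom)
  expect_angle_close(v_bot, -v_top, 5)
  expect_error(reference_denaturation_vector(intact, intact), "identical")
})

test_that("per-particle vectors are rotations of the reference vector", {
  p_ref <- c(0, 0, 1)
  particles <- data.frame(rot = c(0, 0, 45), tilt = c(0, 180, 90),
                          psi = c(0, 0, 120))
  v <- particle_denaturation_vectors(particles, p_ref)
  expect_equal(v[1, ], p_ref, tolerance = 1e-12)
  expect_equal(v[2, ], c(0, 0, -1), tolerance = 1e-12)
  # round trip: R^-1 v == p_ref, and unit norm
  set.seed(9)
  particles <- data.frame(rot = runif(25, 0, 360),
                          tilt = acos(runif(25, -1, 1)) * 180 / pi,
                          psi = runif(25, 0, 360))
  p_ref <- c(0.3, -0.4, 0.866)
  v <- particle_denaturation_vectors(particles, p_ref)
  expect_equal(rowSums(v^2), rep(1, 25), tolerance = 1e-10)
  for (i in 1:25) {
    R <- euler_to_matrix(as.numeric(particles[i, ]))
    expect_equal(as.numeric(t(R) %*% v[i, ]),
                 p_ref / sqrt(sum(p_ref^2)), tolerance = 1e-10)
  }
  # permuting particles permutes vectors identically (no hidden state)
  perm <- sample(25)
  expect_equal(particle_denaturation_vectors(particles[perm, ], p_ref),
               v[perm, ], tolerance = 1e-14)
})

flat_surface <- function(side, z = 0, extent = 1000) {
  fit_surface(cbind(c(0, extent, 0, extent), c(0, 0, extent, extent), z),
              side = side)
}

test_that("displacement angle hits the closed-form cases", {
  surf <- list("tomo1/upper" = flat_surface("upper"))
  # tilt 0 -> P_denat = +z = normal -> 0 deg; tilt 90 -> perpendicular
  particles <- data.frame(id = 1:3, x = 500, y = 500, z = 0,
                          rot = 0, tilt = c(0, 90, 180), psi = 0,
                          tomogram = "tomo1", meniscus = "upper")
  d <- displacement_angles(particles, particle_denaturation_vectors(particles, c(0, 0, 1)), surf)
  expect_equal(d$delta, c(0, 90, 180), tolerance = 1e-6)
  # missing surface -> lookup error
  bad <- particles; bad$tomogram <- "tomo9"
  expect_error(displacement_angles(bad, particle_denaturation_vectors(bad, c(0, 0, 1)), surf),
               "no fitted surface")
})

test_that("bulk particles are excluded with a reported count", {
  surf <- list("tomo1/upper" = flat_surface("upper"))
  particles <- data.frame(id = 1:4, x = 500, y = 500, z = c(0, 0, 300, 400),
                          rot = 0, tilt = 0, psi = 0, tomogram = "tomo1",
                          meniscus = c("upper", "upper", "bulk", "bulk"))
  v <- particle_denaturation_vectors(particles, c(0, 0, 1))
  expect_message(d <- displacement_angles(particles, v, surf), "2 bulk")
  expect_equal(nrow(d), 2)
  expect_equal(attr(d, "n_bulk_excluded"), 2)
})

test_that("flipping the surface side maps delta to 180 - delta", {
  up <- list("tomo1/upper" = flat_surface("upper"))
  dn <- list("tomo1/lower" = flat_surface("lower"))
  set.seed(13)
  particles <- data.frame(id = 1:30, x = runif(30, 100, 900),
                          y = runif(30, 100, 900), z = 0,
                          rot = runif(30, 0, 360),
                          tilt = acos(runif(30, -1, 1)) * 180 / pi,
                          psi = runif(30, 0, 360),
                          tomogram = "tomo1", meniscus = "upper")
  v <- particle_denaturation_vectors(particles, c(0, 0, 1))
  d_up <- displacement_angles(particles, v, up)
  particles$meniscus <- "lower"
  d_dn <- displacement_angles(particles, v, dn)
  expect_equal(d_dn$delta, 180 - d_up$delta, tolerance = 1e-9)
})

test_that("delta is invariant under a global rotation about z", {
  set.seed(14)
  n <- 40
  particles <- data.frame(id = 1:n, x = runif(n, 100, 900),
                          y = runif(n, 100, 900), z = 0,
                          rot = runif(n, 0, 360),
                          tilt = acos(runif(n, -1, 1)) * 180 / pi,
                          psi = runif(n, 0, 360),
                          tomogram = "tomo1", meniscus = "upper")
  p_ref <- c(0.2, 0.5, 0.84)
  surf <- list("tomo1/upper" = fit_surface(
    cbind(particles$x, particles$y, particles$z), side = "upper"))
  d0 <- displacement_angles(particles,
                            particle_denaturation_vectors(particles, p_ref),
                            surf)
  Rg <- euler_to_matrix(c(25, 0, 0))  # in-plane rotation keeps a height field
  rot_particles <- particles
  xy <- t(Rg[1:2, 1:2] %*% t(cbind(particles$x, particles$y)))
  rot_particles$x <- xy[, 1]; rot_particles$y <- xy[, 2]
  for (i in 1:n) {
    Ri <- euler_to_matrix(as.numeric(particles[i, c("rot", "tilt", "psi")]))
    e <- matrix_to_euler(Rg %*% Ri)
    rot_particles[i, c("rot", "tilt", "psi")] <- e
  }
  surf_r <- list("tomo1/upper" = fit_surface(
    cbind(rot_particles$x, rot_particles$y, rot_particles$z), side = "upper"))
  d1 <- displacement_angles(rot_particles,
                            particle_denaturation_vectors(rot_particles, p_ref),
                            surf_r)
  expect_equal(d1$delta, d0$delta, tolerance = 1e-6)
})

test_that("angle_histogram bins at 7.5 degrees with a right-closed last bin", {
  h <- angle_histogram(c(0, 3, 7.5, 179.9, 180))
  expect_equal(nrow(h), 24)
  expect_equal(sum(h$count), 5)
  expect_equal(h$count[1], 2)   # 0 and 3
  expect_equal(h$count[2], 1)   # 7.5 starts bin 2
  expect_equal(h$count[24], 2)  # 179.9 and the closed right edge 180
  h0 <- angle_histogram(rep(0, 10))
  expect_equal(h0$count[1], 10)
  expect_true(all(h0$count[-1] == 0))
  expect_error(angle_histogram(c(-1, 5)), "within")
  expect_error(angle_histogram(c(5, 181)), "within")
  expect_error(angle_histogram(numeric(0)), "no angles")
  expect_error(angle_histogram(c(5, 10), bin_width = 7), "divide")
})

test_that("sine correction flattens the uniform-direction null", {
  # 1e5 uniformly random directions against a fixed axis
  set.seed(17)
  delta <- acos(runif(1e5, -1, 1)) * 180 / pi
  h <- angle_histogram(delta)
  inner <- h$sine_corrected[2:23]
  expect_lt(max(inner) / min(inner), 1.15)
})

test_that("BILD output is well formed and round-trips", {
  path <- withr::local_tempfile(fileext = ".bild")
  write_bild(matrix(c(0, 0, 1), 1), path, scale = 10)
  lines <- readLines(path)
  expect_true(any(grepl("^\\.arrow 0 0 0 0 0 10$", lines)))
  # n vectors -> n arrows; reader recovers endpoints
  set.seed(19)
  v <- matrix(rnorm(30), 10); v <- v / sqrt(rowSums(v^2))
  anchors <- matrix(runif(30, 0, 100), 10)
  write_bild(v, path, scale = 5, anchors = anchors)
  parsed <- read_bild(path)
  expect_equal(nrow(parsed$from), 10)
  expect_equal(parsed$from, unname(anchors), tolerance = 1e-4)
  expect_equal(parsed$to, unname(anchors + 5 * v), tolerance = 1e-4)
  # histogram fan emission
  h <- angle_histogram(acos(runif(500, -1, 1)) * 180 / pi)
  write_bild(h, path, scale = 20)
  expect_equal(nrow(read_bild(path)$from), 24)
})

test_that("particle TSV and STAR readers agree on the schema", {
  set.seed(23)
  particles <- data.frame(id = 1:6, x = runif(6, 0, 500), y = runif(6, 0, 500),
                          z = runif(6, 0, 500), rot = runif(6, 0, 360),
                          tilt = runif(6, 0, 180), psi = runif(6, 0, 360),
                          tomogram = "t1", meniscus = "lower", class = NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_particles(particles, path)
  back <- read_particles(path)
  expect_equal(back$x, particles$x, tolerance = 1e-12)
  expect_equal(back$rot, particles$rot, tolerance = 1e-12)
  star <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
               "_rlnAngleRot #4", "_rlnAngleTilt #5", "_rlnAnglePsi #6",
               "_rlnMicrographName #7",
               paste(particles$x / 2, particles$y / 2, particles$z / 2,
                     particles$rot, particles$tilt, particles$psi, "t1")),
             star)
  st <- read_star_particles(star, voxel_size = 2)
  expect_equal(st$x, particles$x, tolerance = 1e-9)
  expect_equal(st$tilt, particles$tilt, tolerance = 1e-9)
  expect_identical(st$tomogram, rep("t1", 6))
})
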