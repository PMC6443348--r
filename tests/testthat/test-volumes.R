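# Volume data model, MRC I/O, filters, difference maps, FSC machinery.

test_that("volume3d validates its invariants", {
  expect_error(volume3d(array(0, c(2, 4, 4))), "at least 4")
  expect_error(volume3d(array(NA_real_, c(4, 4, 4))), "finite")
  expect_error(volume3d(array(0, c(4, 4, 4)), voxel_size = 0), "positive")
  v <- volume3d(array(1, c(4, 5, 6)), voxel_size = 2, origin = c(1, 2, 3))
  expect_identical(dim(v), c(4L, 5L, 6L))
})

test_that("MRC write/read roundtrip preserves grid, voxel size and data", {
  path <- withr::local_tempfile(fileext = ".mrc")
  # float32-representable data so the roundtrip is bit-exact
  dat <- array(as.numeric(sample(-100:100, 4^3, replace = TRUE)) / 4,
               c(4, 4, 4))
  v <- volume3d(dat, voxel_size = 3.39, origin = c(10, -5, 2.5))
  write_mrc(v, path)
  v2 <- read_mrc(path)
  expect_identical(v2$data, v$data)
  expect_equal(v2$voxel_size, 3.39, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
  # all-zero fixture
  z <- volume3d(array(0, c(4, 4, 4)), voxel_size = 1)
  write_mrc(z, path)
  expect_true(all(read_mrc(path)$data == 0))
})

test_that("malformed MRC input fails with a format error naming the field", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(2048), path)
  expect_error(read_mrc(path), "MAP magic")
  # craft a header with an unsupported mode
  v <- volume3d(array(0, c(4, 4, 4)))
  write_mrc(v, path)
  raw <- readBin(path, "raw", n = file.size(path))
  raw[13:16] <- writeBin(3L, raw(), size = 4, endian = "little")[1:4]
  writeBin(raw, path)
  expect_error(read_mrc(path), "mode")
  writeBin(raw(100), path)
  expect_error(read_mrc(path), "shorter than 1024")
})

test_that("difference_map subtracts voxelwise with optional clamping", {
  v <- noise_volume(32, 4, seed = 2)
  expect_warning(d0 <- difference_map(v, v), "identically zero")
  expect_true(all(d0$data == 0))
  one <- volume3d(array(1, c(8, 8, 8)) + array(0, c(8, 8, 8)))
  two <- volume3d(array(2, c(8, 8, 8)))
  expect_true(all(difference_map(one, two, clamp_negative = FALSE)$data == -1))
  expect_true(all(difference_map(one, two)$data == 0))
  # erased dome: support of the difference is confined to the erased region
  intact <- dome_phantom(erase = "none")
  damaged <- dome_phantom(erase = "top")
  d <- difference_map(intact, damaged)
  box <- dim(d$data)[3]
  zmid <- (box - 1) / 2
  idx <- which(d$data > 0.05 * max(d$data), arr.ind = TRUE)
  expect_true(all(idx[, 3] - 1 > zmid))           # +z half-box only
  # grid mismatch is an error, not a resample
  small <- volume3d(array(0, c(8, 8, 8)))
  expect_error(difference_map(intact, small), "shape mismatch")
  off <- volume3d(intact$data, voxel_size = intact$voxel_size + 0.01)
  expect_error(difference_map(intact, off), "voxel size mismatch")
})

test_that("center_of_mass works in the physical frame", {
  a <- array(0, c(16, 16, 16))
  a[3, 5, 7] <- 2
  v <- volume3d(a, voxel_size = 2.5, origin = c(10, 0, -5))
  expect_equal(center_of_mass(v),
               c(10, 0, -5) + c(2, 4, 6) * 2.5, tolerance = 1e-12)
  # two equal point masses -> midpoint
  b <- array(0, c(16, 16, 16))
  b[1, 8, 8] <- 1; b[11, 8, 8] <- 1
  expect_equal(center_of_mass(volume3d(b))[1], 5, tolerance = 1e-12)
  # centrosymmetric phantom -> geometric grid center
  ph <- dome_phantom()
  expect_equal(center_of_mass(ph), grid_center_of(ph), tolerance = 1e-6)
  expect_error(center_of_mass(volume3d(array(0, c(4, 4, 4)))), "empty density")
})

test_that("bandpass_filter keeps the passband and removes the DC term", {
  # phantom built only from frequencies below 1/50 A^-1 (shells 2-3 of a
  # 48-voxel, 4 A grid: freq <= 3/192 = 0.0156 < 0.02)
  n <- 48; vx <- 4
  x <- 0:(n - 1)
  w <- function(k, dim_axis) {
    arr <- array(cos(2 * pi * k * x / n), rep(n, 3))
    if (dim_axis == 2) arr <- aperm(arr, c(2, 1, 3))
    if (dim_axis == 3) arr <- aperm(arr, c(3, 2, 1))
    arr
  }
  v <- volume3d(w(2, 1) + 0.5 * w(3, 2) + 0.25 * w(2, 3), voxel_size = vx)
  lp <- bandpass_filter(v, Inf, 50)
  expect_lt(sqrt(mean((lp$data - v$data)^2)) / sd(as.numeric(v$data)), 0.01)
  # band-pass removes DC: mean ~ 0
  v2 <- volume3d(v$data + 7, voxel_size = vx)
  bp <- bandpass_filter(v2, 308, 12)
  expect_lt(abs(mean(bp$data)), 1e-10 * max(abs(v2$data)))
  # commutes with global scaling
  sc <- bandpass_filter(volume3d(3 * v$data, voxel_size = vx), 308, 12)
  expect_equal(sc$data, 3 * bandpass_filter(v, 308, 12)$data,
               tolerance = 1e-12)
  expect_error(bandpass_filter(v, Inf, 2 * vx - 1), "Nyquist")
  expect_error(bandpass_filter(v, 12, 308), "coarser")
})

test_that("gaussian_filter conserves density and has the requested width", {
  v <- noise_volume(32, 4, seed = 3)
  expect_identical(gaussian_filter(v, 0)$data, v$data)
  g <- gaussian_filter(v, 2)
  expect_equal(sum(g$data), sum(v$data), tolerance = 1e-9)
  # delta -> isotropic Gaussian with empirical stddev sigma +/- 1%
  a <- array(0, c(32, 32, 32)); a[17, 17, 17] <- 1
  imp <- gaussian_filter(volume3d(a), 2)$data
  x <- (0:31) - 16
  for (ax in 1:3) {
    m <- apply(imp, ax, sum)
    sd_emp <- sqrt(sum(m * x^2) / sum(m))
    expect_equal(sd_emp, 2, tolerance = 0.01)
  }
  # commutes with global scaling
  expect_equal(gaussian_filter(volume3d(5 * v$data, voxel_size = 4), 2)$data,
               5 * g$data, tolerance = 1e-12)
  expect_error(gaussian_filter(v, -1), "nonnegative")
})

test_that("phase_randomize preserves amplitudes and low-resolution phases", {
  v <- structured_phantom(box = 48, voxel_size = 4, seed = 5)
  pr <- phase_randomize(v, beyond_res = 60, seed = 9)
  A1 <- Mod(fft(v$data)); A2 <- Mod(fft(pr$data))
  expect_lt(max(abs(A1 - A2)) / max(A1), 1e-6)
  # Parseval: total power conserved
  expect_equal(sum(v$data^2), sum(pr$data^2), tolerance = 1e-9)
  # determinism
  expect_identical(pr$data, phase_randomize(v, 60, seed = 9)$data)
  # FSC ~ 1 below the cutoff, |FSC| < 0.1 averaged beyond
  curve <- fsc(v, pr)
  shell_w <- 1 / (48 * 4)
  below <- curve$correlation[curve$shell_freq < 1 / 60 - shell_w]
  above <- curve$correlation[curve$shell_freq > 1.25 / 60]
  expect_true(all(below > 0.99))
  expect_lt(mean(abs(above)), 0.1)
  expect_error(phase_randomize(v, 2 * v$voxel_size - 1), "Nyquist")
})

test_that("fsc is 1 for self, -1 for negation, symmetric, near 0 for noise", {
  v <- structured_phantom(box = 32, voxel_size = 4, seed = 6)
  self <- fsc(v, v)
  expect_true(all(abs(self$correlation - 1) < 1e-9))
  neg <- fsc(v, volume3d(-v$data, voxel_size = 4))
  expect_true(all(abs(neg$correlation + 1) < 1e-9))
  a <- noise_volume(32, 4, seed = 11)
  b <- noise_volume(32, 4, seed = 12)
  expect_equal(fsc(a, b)$correlation, fsc(b, a)$correlation, tolerance = 1e-12)
  # white-noise floor: per-shell mean |FSC| < 3 / sqrt(n_shell_voxels),
  # Monte-Carlo over 10 seed pairs, shells with > 100 voxels
  acc <- NULL
  for (s in 1:10) {
    cur <- fsc(noise_volume(32, 4, seed = 100 + s),
               noise_volume(32, 4, seed = 200 + s))
    acc <- rbind(acc, abs(cur$correlation[cur$n_voxels > 100]))
  }
  nv <- fsc(a, b)
  bound <- 3 / sqrt(nv$n_voxels[nv$n_voxels > 100])
  expect_true(all(colMeans(acc) < bound))
  expect_error(fsc(a, noise_volume(16, 4, seed = 1)), "mismatch")
})

test_that("resolution_at interpolates the first downward crossing", {
  curve <- structure(data.frame(shell_freq = seq(0.01, 0.1, by = 0.01),
                                correlation = rep(1, 10)),
                     class = c("fsc_curve", "data.frame"))
  r <- resolution_at(curve, 0.143)
  expect_equal(as.numeric(r), 10)
  expect_true(attr(r, "limit"))
  # exact crossing at a shell
  curve2 <- curve; curve2$correlation <- c(1, 1, 0.5, 0.1, rep(0, 6))
  expect_equal(as.numeric(resolution_at(curve2, 0.5)), 1 / 0.03,
               tolerance = 1e-12)
  # linear drop from 1 at 1/40 to 0 at 1/20, threshold 0.5 -> 26.67 A
  f <- seq(1 / 40, 1 / 20, length.out = 11)
  curve3 <- structure(data.frame(shell_freq = f,
                                 correlation = seq(1, 0, length.out = 11)),
                      class = c("fsc_curve", "data.frame"))
  expect_equal(as.numeric(resolution_at(curve3, 0.5)),
               1 / ((1 / 40 + 1 / 20) / 2), tolerance = 1e-9)
  # monotone in threshold: a higher threshold never reports finer resolution
  v <- structured_phantom(box = 32, voxel_size = 4, seed = 7)
  cur <- fsc(add_noise(v, 1, seed = 8), add_noise(v, 1, seed = 9))
  res <- vapply(c(0.1, 0.143, 0.3, 0.5, 0.8),
                function(t) as.numeric(resolution_at(cur, t)), numeric(1))
  expect_true(all(diff(res) >= -1e-9))
})

test_that("fsc curve TSV export has the two-column layout", {
  v <- structured_phantom(box = 32, voxel_size = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fsc_tsv(fsc(v, v), path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("shell_freq", "correlation"))
  expect_true(all(diff(tab$shell_freq) > 0))
})

test_that("mask_bias_check separates benign from mask-imprinted cases", {
  ph <- structured_phantom(box = 48, voxel_size = 4, seed = 15)
  h1 <- add_noise(ph, 2, seed = 16)
  h2 <- add_noise(ph, 2, seed = 17)
  sphere <- local({
    ax <- (0:47) - 23.5
    X <- array(ax, c(48, 48, 48))
    r <- sqrt(X^2 + aperm(X, c(2, 1, 3))^2 + aperm(X, c(3, 2, 1))^2)
    array(as.numeric(r < 16), c(48, 48, 48))
  })
  soft_mask <- gaussian_filter(volume3d(sphere, voxel_size = 4), 2)
  soft_mask$data <- pmin(pmax(soft_mask$data, 0), 1)
  benign <- mask_bias_check(h1, h2, soft_mask, rand_beyond = 60, seed = 3)
  expect_identical(benign$verdict, "unbiased")
  # pathological: half-maps equal to the tight binary mask itself
  tight <- volume3d(sphere, voxel_size = 4)
  patho <- mask_bias_check(tight, tight, tight, rand_beyond = 60, seed = 3)
  expect_identical(patho$verdict, "biased")
  expect_identical(formals(mask_bias_check)$rand_beyond, 60)
})
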