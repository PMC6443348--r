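# Shared internal helpers: seeded evaluation, Fourier grids, small numerics.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Signed integer Fourier index along one axis of length n (fftfreq * n).
fft_index <- function(n) {
  i <- 0:(n - 1L)
  ifelse(i <= n %/% 2, i, i - n)
}

# Array (same shape as the volume) of radial spatial frequency magnitude in
# 1/Angstrom, and of continuous shell radius in Fourier pixels of the largest
# dimension. Shell width is one Fourier pixel: freq(s) = s / (D * voxel).
fourier_radius <- function(dim, voxel_size) {
  kx <- fft_index(dim[1]) / (dim[1] * voxel_size)
  ky <- fft_index(dim[2]) / (dim[2] * voxel_size)
  kz <- fft_index(dim[3]) / (dim[3] * voxel_size)
  kx2 <- array(kx^2, dim = dim)
  ky2 <- aperm(array(ky^2, dim = dim[c(2, 1, 3)]), c(2, 1, 3))
  kz2 <- aperm(array(kz^2, dim = dim[c(3, 2, 1)]), c(3, 2, 1))
  sqrt(kx2 + ky2 + kz2)
}

shell_pixel_radius <- function(dim, voxel_size) {
  D <- max(dim)
  fourier_radius(dim, voxel_size) * D * voxel_size
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Deterministic numeric formatting used by all text writers so that identical
# inputs yield byte-identical files.
fmt_num <- function(x, digits = 10) {
  vapply(x, function(v) sprintf(paste0("%.", digits, "g"), v), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
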