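# Shared fixtures, all generated in code.

# Asymmetric multi-blob phantom for alignment tests: no central mass and
# strongly unequal blob weights, so the rotational self-correlation is low
# (next-best grid rotation scores ~0.88 vs 1) and the orientation search is
# well conditioned. Smooth Gaussians keep the interpolation round-trip
# correlation above 0.999.
blob_phantom <- function(box = 32, voxel_size = 8) {
  c0 <- (box - 1) / 2
  ax <- (0:(box - 1)) - c0
  X <- array(ax, c(box, box, box))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  g <- function(cx, cy, cz, s, a)
    a * exp(-((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) / (2 * s^2))
  dat <- g(7, 0, 0, 3, 1) + g(0, 8, 0, 2.8, 0.7) +
    g(0, 0, 7, 2.6, 0.5) + g(-5, -5, -4, 2.4, 0.35)
  volume3d(dat, voxel_size = voxel_size)
}

# Two-dome phantom: soft central ball plus two polar domes; erase_top
# removes the +z dome. Used for difference-map direction tests.
dome_phantom <- function(box = 32, voxel_size = 4, erase = c("none", "top", "bottom")) {
  erase <- match.arg(erase)
  c0 <- (box - 1) / 2
  ax <- (0:(box - 1)) - c0
  X <- array(ax, c(box, box, box))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  soft <- function(t) 1 / (1 + exp(-t))
  ball <- soft(0.30 * box - sqrt(X^2 + Y^2 + Z^2) - 0.1 * box)
  zd <- 0.24 * box
  rd <- 0.12 * box
  dome_up <- soft(rd - sqrt(X^2 + Y^2 + (Z - zd)^2))
  dome_dn <- soft(rd - sqrt(X^2 + Y^2 + (Z + zd)^2))
  dat <- ball + dome_up + dome_dn
  if (erase == "top") dat <- dat - dome_up
  if (erase == "bottom") dat <- dat - dome_dn
  volume3d(dat, voxel_size = voxel_size)
}

rotated_copy <- function(vol, euler) {
  d <- dim(vol$data)
  R <- euler_to_matrix(euler)
  volume3d(array(awiorient:::cpp_rotate_vol(as.numeric(vol$data),
                                            as.integer(d), R), d),
           voxel_size = vol$voxel_size, origin = vol$origin)
}

shifted_copy <- function(vol, shift) {
  d <- dim(vol$data)
  volume3d(array(awiorient:::cpp_shift_vol(as.numeric(vol$data),
                                           as.integer(d),
                                           as.integer(shift)), d),
           voxel_size = vol$voxel_size, origin = vol$origin)
}

add_noise <- function(vol, snr, seed) {
  awiorient:::with_seed(seed, {
    sig_pow <- mean(vol$data^2)
    volume3d(vol$data + rnorm(length(vol$data), sd = sqrt(sig_pow / snr)),
             voxel_size = vol$voxel_size, origin = vol$origin)
  })
}

noise_volume <- function(box = 32, voxel_size = 4, seed = 1) {
  awiorient:::with_seed(seed,
    volume3d(array(rnorm(box^3), c(box, box, box)), voxel_size = voxel_size))
}

# Smooth structured phantom with power across many shells (random smooth
# field), for FSC / phase-randomization tests.
structured_phantom <- function(box = 48, voxel_size = 4, seed = 5,
                               sigma_px = 1.5) {
  v <- noise_volume(box, voxel_size, seed)
  gaussian_filter(v, sigma_px)
}

grid_center_of <- function(v) v$origin + (dim(v$data) - 1) / 2 * v$voxel_size

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, max(-1, sum(a * b)))) * 180 / pi
}

expect_angle_close <- function(a, b, tol_deg) {
  expect_lt(angle_between_deg(a, b), tol_deg)
}
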