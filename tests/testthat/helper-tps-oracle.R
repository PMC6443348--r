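# Independent oracle: assemble and solve the dense (N+3) bordered thin-plate
# system directly with solve(), on the raw (uncentered) coordinates.
tps_oracle <- function(points, lambda = 0) {
  xy <- points[, 1:2, drop = FALSE]
  z <- points[, 3]
  n <- nrow(points)
  D <- as.matrix(dist(xy))
  U <- D^2 * log(D)
  U[!is.finite(U)] <- 0
  P <- cbind(1, xy)
  M <- rbind(cbind(U + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(M, c(z, 0, 0, 0))
  list(weights = sol[1:n], affine = sol[n + 1:3], xy = xy)
}

tps_oracle_eval <- function(fit, q) {
  d <- sqrt(outer(q[, 1], fit$xy[, 1], `-`)^2 +
            outer(q[, 2], fit$xy[, 2], `-`)^2)
  U <- d^2 * log(d)
  U[!is.finite(U)] <- 0
  fit$affine[1] + q %*% fit$affine[2:3] + U %*% fit$weights
}
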