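# Independent oracles used across the suite.

# Line-source geometry function by direct numerical integration of the
# defining kernel: G(r, theta) = (1/L) * integral over the active length of
# 1 / |P - l zhat|^2 dl, with P = (r sin t, r cos t).  Independent of the
# closed-form branches in the package.
oracle_geometry <- function(r, theta, L = 0.19) {
  th <- theta * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  f <- function(l) 1 / (y^2 + (z - l)^2)
  stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-12)$value / L
}

# Reference bilinear interpolation on a dose grid, written independently of
# the package's stencil code (no mask handling: callers use unmasked grids).
oracle_bilinear <- function(grid, y, z) {
  ya <- grid$y_axis; za <- grid$z_axis
  j <- min(max(findInterval(y, ya, rightmost.closed = TRUE), 1L), length(ya) - 1L)
  i <- min(max(findInterval(z, za, rightmost.closed = TRUE), 1L), length(za) - 1L)
  ty <- (y - ya[j]) / (ya[j + 1L] - ya[j])
  tz <- (z - za[i]) / (za[i + 1L] - za[i])
  (1 - tz) * ((1 - ty) * grid$values[i, j] + ty * grid$values[i, j + 1L]) +
    tz * ((1 - ty) * grid$values[i + 1L, j] + ty * grid$values[i + 1L, j + 1L])
}

# Brute-force multi-pellet field: evaluate the analytic kernel at
# (y, z - z_i) for each active pellet and sum, on the grid nodes.
oracle_multi_pellet <- function(spec, braid, y_axis, z_axis) {
  off <- pellet_offsets(braid)
  acc <- matrix(0, length(z_axis), length(y_axis))
  for (i in seq_len(nrow(off))) {
    pts <- expand.grid(z = z_axis - off$center_z[i], y = y_axis,
                       KEEP.OUT.ATTRS = FALSE)
    pol <- cart_to_polar(pts$y, pts$z)
    acc <- acc + off$relative_activity[i] *
      matrix(evaluate_kernel(spec, pol$r, pol$theta), nrow = length(z_axis))
  }
  acc
}

# Directed Hausdorff-style mismatch between a vertex set and its z-mirror.
mirror_mismatch <- function(contours) {
  worst <- 0
  for (lv in contours) {
    pts <- do.call(rbind, lv$polylines)
    if (is.null(pts) || !nrow(pts)) next
    mir <- cbind(y = pts[, "y"], z = -pts[, "z"])
    for (k in seq_len(nrow(pts))) {
      d <- sqrt((mir[, 1] - pts[k, "y"])^2 + (mir[, 2] - pts[k, "z"])^2)
      worst <- max(worst, min(d))
    }
  }
  worst
}

# Quick explicit-braid builder for tests.
make_braid <- function(z, w = rep(1, length(z)), name = "test") {
  load_braid(list(
    name = name,
    pellets = lapply(seq_along(z), function(i)
      list(z_cm = z[i], kind = "active", relative_activity = w[i]))))
}
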