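# TG-43U1 mathematical core: line-source geometry function, dose-rate
# constant, radial dose function g(r), 2D anisotropy function F(r,theta),
# quintic radial fit, and dose reconstruction by table interpolation.
#
# Conventions: r in cm from the source center, theta in degrees from the
# source long axis (+z); reference point (r0, theta0) = (1 cm, 90 deg).
# Angles are degrees at every interface; radians are internal only.

.THETA_AXIS_TOL_DEG <- 1e-6  # on-axis branch band for the geometry function

#' Line-source geometry function G_L(r, theta)
#'
#' For angles inside a narrow on-axis band (theta < 1e-6 degrees, and the
#' mirror band at 180 degrees) the on-axis closed form
#' `G = 1 / (r^2 - L^2/4)` is used; elsewhere the arctangent form
#' `G = [atan((r cos(t) + L/2) / (r sin(t))) - atan((r cos(t) - L/2) /
#' (r sin(t)))] / (L r sin(t))`, which equals `beta / (L r sin(t))` with
#' `beta` the angle subtended by the active length.  Angles above 90
#' degrees are mapped to their mirror image before evaluation, so
#' `G(r, theta) == G(r, 180 - theta)` holds exactly.
#'
#' @param r Radial distance(s) from the source center, cm; must exceed
#'   `L/2` on the source axis.
#' @param theta Polar angle(s) from the source long axis, degrees, in
#'   `[0, 180]`.  Recycled against `r`.
#' @param L Active length of the source, cm (0.19 cm for the GZP6 pellet).
#' @return Geometry function value(s), cm^-2.
#' @seealso [geometry_function_normalized()]
#' @export
geometry_function <- function(r, theta, L = 0.19) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("geometry_function: 'L' must be a single positive number (cm)")
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("geometry_function: 'r' must be positive and finite")
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    stop("geometry_function: 'theta' must lie in [0, 180] degrees")
  # exact mirror symmetry about the transverse plane
  theta <- ifelse(theta > 90, 180 - theta, theta)
  on_axis <- theta < .THETA_AXIS_TOL_DEG
  if (any(on_axis & r <= L / 2))
    stop("geometry_function: r <= L/2 on the source axis is outside the ",
         "line-source domain")
  out <- numeric(n)
  if (any(on_axis)) out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  if (any(!on_axis)) {
    ro <- r[!on_axis]
    th <- theta[!on_axis] * pi / 180
    s <- ro * sin(th)
    beta <- atan((ro * cos(th) + L / 2) / s) - atan((ro * cos(th) - L / 2) / s)
    out[!on_axis] <- beta / (L * s)
  }
  out
}

#' Geometry function relative to an ideal point source
#'
#' Returns `G_L(r, theta) * r^2`, i.e. the line-source geometry function
#' normalized by the point-source inverse-square factor at the same
#' distance.  This is the dimensionless quantity tabulated for the GZP6
#' source; it tends to 1 as `L -> 0` or `r >> L`.
#'
#' @inheritParams geometry_function
#' @return Dimensionless value(s).
#' @export
geometry_function_normalized <- function(r, theta, L = 0.19) {
  geometry_function(r, theta, L) * rep_len(as.numeric(r),
                                           max(length(r), length(theta)))^2
}

#' Dose-rate constant
#'
#' The ratio of the dose rate at the reference point (1 cm, 90 degrees) in
#' water to the air-kerma strength of the source.
#'
#' @param dose_at_ref Dose rate at (r0, theta0), cGy/h.
#' @param Sk Air-kerma strength, U (1 U = 1 uGy m^2/h).
#' @return Dose-rate constant, cGy/h/U.
#' @export
dose_rate_constant <- function(dose_at_ref, Sk) {
  if (!is.numeric(Sk) || length(Sk) != 1L || !is.finite(Sk) || Sk <= 0)
    stop("dose_rate_constant: 'Sk' must be a single positive number (U)")
  dose_at_ref / Sk
}

#' Extract the radial dose function g(r) from transverse-axis samples
#'
#' `g(r) = [D(r, theta0) / D(r0, theta0)] * [G(r0, theta0) / G(r, theta0)]`:
#' the transverse dose fall-off with the geometry factor divided out,
#' normalized to 1 at the reference distance.
#'
#' @param samples A [polar_dose_samples()] object (or equivalent data
#'   frame) restricted to the transverse plane, `theta == theta0`.
#' @param L Active length, cm.
#' @param r0,theta0 Reference point (1 cm, 90 degrees).
#' @param r0_tol Matching tolerance for locating the reference sample, cm.
#' @return Data frame with columns `r_cm` and `g`; `g` at `r0` is exactly 1.
#' @export
radial_dose_function <- function(samples, L = 0.19, r0 = 1, theta0 = 90,
                                 r0_tol = 1e-9) {
  samples <- as.data.frame(samples)
  tr <- samples[abs(samples$theta - theta0) < 1e-9, , drop = FALSE]
  if (!nrow(tr))
    stop("radial_dose_function: no samples at theta = ", theta0, " degrees")
  if (any(tr$dose_rate <= 0))
    stop("radial_dose_function: all dose-rate values must be positive")
  i0 <- which(abs(tr$r - r0) <= r0_tol)
  if (!length(i0))
    stop("radial_dose_function: samples must include the reference distance ",
         "r0 = ", r0, " cm (add a sample at r0 on the transverse axis)")
  i0 <- i0[1L]
  G <- geometry_function(tr$r, theta0, L)
  G0 <- geometry_function(r0, theta0, L)
  g <- (tr$dose_rate / tr$dose_rate[i0]) * (G0 / G)
  g[i0] <- 1  # exact by definition
  out <- data.frame(r_cm = tr$r, g = g)
  out[order(out$r_cm), , drop = FALSE]
}

#' Extract the 2D anisotropy function F(r, theta)
#'
#' `F(r, theta) = [D(r, theta) / D(r, theta0)] * [G(r, theta0) /
#' G(r, theta)]`: the angular dose variation at fixed radius relative to
#' the transverse plane, with the geometry factor divided out.  Every
#' radius in the output must have a transverse (`theta0`) sample;
#' (r, theta) combinations absent from the input are reported as `NA`
#' (missing), which downstream interpolation skips.
#'
#' @inheritParams radial_dose_function
#' @param samples A [polar_dose_samples()] object covering one or more radii.
#' @return Data frame with columns `r_cm`, `theta_deg`, `F` on the full
#'   lattice of sampled radii and angles; missing combinations are `NA`.
#'   `F` at `theta0` is exactly 1 for every radius.
#' @export
anisotropy_function <- function(samples, L = 0.19, theta0 = 90) {
  samples <- as.data.frame(samples)
  if (any(samples$dose_rate <= 0))
    stop("anisotropy_function: all dose-rate values must be positive")
  rs <- sort(unique(samples$r))
  ths <- sort(unique(samples$theta))
  out <- expand.grid(r_cm = rs, theta_deg = ths, KEEP.OUT.ATTRS = FALSE)
  out$F <- NA_real_
  for (r in rs) {
    sub <- samples[abs(samples$r - r) < 1e-12, , drop = FALSE]
    i0 <- which(abs(sub$theta - theta0) < 1e-9)
    if (!length(i0))
      stop("anisotropy_function: no theta = ", theta0,
           " degree sample at r = ", r, " cm")
    d0 <- sub$dose_rate[i0[1L]]
    G0 <- geometry_function(r, theta0, L)
    Fv <- (sub$dose_rate / d0) * (G0 / geometry_function(r, sub$theta, L))
    Fv[i0[1L]] <- 1  # exact by definition
    idx <- match(paste(r, sub$theta), paste(out$r_cm, out$theta_deg))
    out$F[idx] <- Fv
  }
  out[order(out$r_cm, out$theta_deg), , drop = FALSE]
}

#' Fit a polynomial to the radial dose function
#'
#' Unweighted ordinary least squares of `g` on powers of `r` up to
#' `order` (degree 5 by default, the standard form for this source):
#' `g(r) = a0 + a1 r + ... + a5 r^5`, with the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` evaluated on the fitted nodes.
#'
#' @param g_table Data frame with columns `r_cm` and `g` (at least
#'   `order + 1` distinct radii).
#' @param order Polynomial degree.
#' @return A `radial_poly_fit` object: `coefficients` named `a0..a<order>`
#'   and `r_squared`.
#' @export
fit_radial_polynomial <- function(g_table, order = 5L) {
  g_table <- as.data.frame(g_table)
  r <- g_table$r_cm
  g <- g_table$g
  if (anyDuplicated(r))
    stop("fit_radial_polynomial: duplicate r values make the design ",
         "rank-deficient")
  if (length(unique(r)) < order + 1L)
    stop("fit_radial_polynomial: need at least ", order + 1L,
         " distinct r nodes for a degree-", order, " fit")
  fit <- stats::lm(g ~ stats::poly(r, order, raw = TRUE))
  cf <- unname(stats::coef(fit))
  names(cf) <- paste0("a", seq_along(cf) - 1L)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((g - mean(g))^2)
  structure(list(coefficients = cf, r_squared = r2,
                 order = as.integer(order)),
            class = "radial_poly_fit")
}

#' Evaluate a fitted radial polynomial
#'
#' @param fit A `radial_poly_fit` from [fit_radial_polynomial()].
#' @param r Radii, cm.
#' @return Polynomial values at `r`.
#' @export
evaluate_radial_polynomial <- function(fit, r) {
  stopifnot(inherits(fit, "radial_poly_fit"))
  drop(outer(as.numeric(r), seq_along(fit$coefficients) - 1L, `^`) %*%
         fit$coefficients)
}

#' @export
print.radial_poly_fit <- function(x, ...) {
  cat(sprintf("<radial_poly_fit: degree %d, R^2 = %.6f>\n", x$order,
              x$r_squared))
  print(x$coefficients)
  invisible(x)
}

# ---- parameter set ---------------------------------------------------------

#' Assemble a TG-43 parameter set
#'
#' The complete description needed to reconstruct the dose rate anywhere
#' around the source: dose-rate constant, active length, tabulated g(r)
#' and F(r, theta), and the reference point.  The tables are renormalized
#' on construction so that `g(r0) == 1` and `F(r, theta0) == 1` hold
#' exactly; rows with missing (`NA`) anisotropy values are dropped and
#' treated as absent cells.
#'
#' @param lambda Dose-rate constant, cGy/h/U.
#' @param L Active length, cm.
#' @param g_table Data frame `r_cm`, `g`; must include `r0`.
#' @param F_table Data frame `r_cm`, `theta_deg`, `F`; each radius must
#'   include `theta0`.
#' @param r0,theta0 Reference point (1 cm, 90 degrees).
#' @return A `tg43_params` object.
#' @export
tg43_parameter_set <- function(lambda, L, g_table, F_table, r0 = 1,
                               theta0 = 90) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("tg43_parameter_set: 'lambda' must be positive")
  if (!is.numeric(L) || L <= 0)
    stop("tg43_parameter_set: 'L' must be positive")
  g_table <- as.data.frame(g_table)[, c("r_cm", "g")]
  g_table <- g_table[order(g_table$r_cm), , drop = FALSE]
  i0 <- which(abs(g_table$r_cm - r0) < 1e-9)
  if (!length(i0))
    stop("tg43_parameter_set: 'g_table' must include r0 = ", r0, " cm")
  if (any(g_table$g <= 0))
    stop("tg43_parameter_set: g values must be positive")
  g_table$g <- g_table$g / g_table$g[i0[1L]]

  F_table <- as.data.frame(F_table)[, c("r_cm", "theta_deg", "F")]
  F_table <- F_table[!is.na(F_table$F), , drop = FALSE]
  if (any(F_table$F <= 0))
    stop("tg43_parameter_set: F values must be positive")
  F_table <- F_table[order(F_table$r_cm, F_table$theta_deg), , drop = FALSE]
  for (r in unique(F_table$r_cm)) {
    sel <- F_table$r_cm == r
    i90 <- which(sel & abs(F_table$theta_deg - theta0) < 1e-9)
    if (!length(i90))
      stop("tg43_parameter_set: 'F_table' lacks a theta0 = ", theta0,
           " degree entry at r = ", r, " cm")
    F_table$F[sel] <- F_table$F[sel] / F_table$F[i90[1L]]
  }
  structure(list(lambda = lambda, L = L, r0 = r0, theta0 = theta0,
                 g_table = g_table, F_table = F_table),
            class = "tg43_params")
}

#' @export
print.tg43_params <- function(x, ...) {
  cat(sprintf(
    "<tg43_params: lambda = %.4g cGy/h/U, L = %.3g cm, %d g(r) nodes, %d F cells>\n",
    x$lambda, x$L, nrow(x$g_table), nrow(x$F_table)))
  invisible(x)
}

#' Write / read a TG-43 parameter set as JSON
#'
#' The document has scalar keys `lambda`, `L_cm`, `r0_cm`, `theta0_deg`,
#' a `g` array of `[r, g]` pairs, and an `F` array of `[r, theta, F]`
#' triples (missing anisotropy cells are simply absent).
#'
#' @param params A `tg43_params` object.
#' @param path File path.
#' @return `write_tg43_params` returns `path` invisibly;
#'   `read_tg43_params` returns a `tg43_params`.
#' @export
write_tg43_params <- function(params, path) {
  stopifnot(inherits(params, "tg43_params"))
  doc <- list(
    lambda = params$lambda, L_cm = params$L,
    r0_cm = params$r0, theta0_deg = params$theta0,
    g = lapply(seq_len(nrow(params$g_table)),
               function(i) unlist(params$g_table[i, c("r_cm", "g")],
                                  use.names = FALSE)),
    F = lapply(seq_len(nrow(params$F_table)),
               function(i) unlist(params$F_table[i, c("r_cm", "theta_deg", "F")],
                                  use.names = FALSE))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tg43_params
#' @export
read_tg43_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.data.frame(doc$g)
  names(g) <- c("r_cm", "g")
  Ft <- as.data.frame(doc$F)
  names(Ft) <- c("r_cm", "theta_deg", "F")
  tg43_parameter_set(doc$lambda, doc$L_cm, g, Ft, r0 = doc$r0_cm,
                     theta0 = doc$theta0_deg)
}

#' Read g(r) / F(r, theta) tables from CSV
#'
#' Expected headers: `r_cm,g` for radial tables and `r_cm,theta_deg,F`
#' for anisotropy tables.  Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @return A data frame with the validated columns.
#' @export
read_g_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("r_cm", "g") %in% names(df)))
    stop("read_g_table: CSV must have header 'r_cm,g'")
  df[, c("r_cm", "g")]
}

#' @rdname read_g_table
#' @export
read_F_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("r_cm", "theta_deg", "F") %in% names(df)))
    stop("read_F_table: CSV must have header 'r_cm,theta_deg,F'")
  df[, c("r_cm", "theta_deg", "F")]
}

# ---- interpolation and reconstruction --------------------------------------

# Linear interpolation of g(r); below the smallest node the nearest node is
# used (with a warning), above the largest node behaviour follows 'mode'.
.interp_g <- function(params, r, mode) {
  tab <- params$g_table
  rmin <- tab$r_cm[1L]
  rmax <- tab$r_cm[nrow(tab)]
  out <- numeric(length(r))
  below <- r < rmin
  above <- r > rmax
  if (any(below)) {
    warning("g(r): r below the smallest tabulated radius (", rmin,
            " cm); using the nearest node")
  }
  if (any(above)) {
    if (mode == "strict")
      stop("g(r): r beyond the largest tabulated radius (", rmax,
           " cm) in strict mode")
    warning("g(r): r beyond the largest tabulated radius (", rmax,
            " cm); clamping")
  }
  rc <- pmin(pmax(r, rmin), rmax)
  stats::approx(tab$r_cm, tab$g, xout = rc, method = "linear")$y
}

# F(r, theta): along each tabulated r-column, interpolate linearly in theta
# over the available (non-missing) angles, clamping beyond the column's
# angular range; then interpolate linearly between the two bracketing
# r-columns.  Below the smallest radius the nearest column is used (with a
# warning); above the largest, behaviour follows 'mode'.
.interp_F <- function(params, r, theta, mode) {
  tab <- params$F_table
  rs <- sort(unique(tab$r_cm))
  col_eval <- function(rcol, th) {
    sub <- tab[tab$r_cm == rcol, , drop = FALSE]
    if (nrow(sub) == 1L) return(rep(sub$F, length(th)))
    stats::approx(sub$theta_deg, sub$F, xout = pmin(pmax(th, min(sub$theta_deg)),
                                                    max(sub$theta_deg)),
                  method = "linear")$y
  }
  rmin <- rs[1L]
  rmax <- rs[length(rs)]
  if (any(r < rmin))
    warning("F(r,theta): r below the smallest tabulated radius (", rmin,
            " cm); using the nearest column")
  if (any(r > rmax)) {
    if (mode == "strict")
      stop("F(r,theta): r beyond the largest tabulated radius (", rmax,
           " cm) in strict mode")
    warning("F(r,theta): r beyond the largest tabulated radius (", rmax,
            " cm); clamping")
  }
  rc <- pmin(pmax(r, rmin), rmax)
  out <- numeric(length(rc))
  for (i in seq_along(rc)) {
    k <- findInterval(rc[i], rs, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(rs) - 1L)
    r_lo <- rs[k]; r_hi <- rs[k + 1L]
    f_lo <- col_eval(r_lo, theta[i])
    if (rc[i] == r_lo) { out[i] <- f_lo; next }
    f_hi <- col_eval(r_hi, theta[i])
    w <- (rc[i] - r_lo) / (r_hi - r_lo)
    out[i] <- (1 - w) * f_lo + w * f_hi
  }
  out
}

#' Reconstruct the dose rate at a point from a TG-43 parameter set
#'
#' The five-factor product `Sk * lambda * [G(r,theta)/G(r0,theta0)] * g(r)
#' * F(r,theta)` with g and F interpolated from the stored tables (g linear
#' in r; F linear in theta along each radius column over the available
#' angles, then linear in r).  At the reference point the product is
#' exactly `Sk * lambda`.
#'
#' Extrapolation policy: below the smallest tabulated radius the nearest
#' table node/column is used with a warning; above the largest, `"strict"`
#' mode raises an error and `"lenient"` mode clamps with a warning.
#'
#' @param params A `tg43_params` object.
#' @param Sk Air-kerma strength, U.
#' @param r,theta Evaluation point(s): cm and degrees.
#' @param mode `"strict"` or `"lenient"` extrapolation policy.
#' @return Dose rate(s), cGy/h.
#' @export
reconstruct_dose_rate <- function(params, Sk, r, theta,
                                  mode = c("strict", "lenient")) {
  stopifnot(inherits(params, "tg43_params"))
  mode <- match.arg(mode)
  if (!is.numeric(Sk) || Sk < 0)
    stop("reconstruct_dose_rate: 'Sk' must be non-negative (U)")
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  Gratio <- geometry_function(r, theta, params$L) /
    geometry_function(params$r0, params$theta0, params$L)
  Sk * params$lambda * Gratio * .interp_g(params, r, mode) *
    .interp_F(params, r, theta, mode)
}
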