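# Cartesian (y, z) dose-rate grids: construction, the grid CSV dialect,
# coordinate transforms, bilinear resampling to polar samples, and isodose
# contour extraction.  y is the transverse ("away") coordinate, z the axial
# ("along") coordinate; cylindrical symmetry about the z axis is assumed,
# so only y >= 0 is ever tabulated and negative y mirrors onto |y|.

.GRID_UNITS <- c("cGy/h/U", "Gy")
.GRID_MAGIC <- "# gzp6dose-grid v1"

#' Construct a Cartesian dose grid
#'
#' @param y_axis Strictly increasing transverse coordinates, cm.
#' @param z_axis Strictly increasing axial coordinates, cm.
#' @param values Matrix of dose rate (cGy/h/U) or dose (Gy), with shape
#'   `(length(z_axis), length(y_axis))` — rows are z, columns are y.
#'   `NA` entries are treated as masked (missing) cells.
#' @param unit Unit tag, `"cGy/h/U"` or `"Gy"`.
#' @param mask Optional logical matrix of the same shape marking missing
#'   cells (combined with `is.na(values)`).
#' @return A `dose_grid` object with fields `y_axis`, `z_axis`, `values`
#'   (masked cells `NA`), `mask`, `unit`.
#' @export
dose_grid <- function(y_axis, z_axis, values, unit = "cGy/h/U", mask = NULL) {
  y_axis <- as.numeric(y_axis)
  z_axis <- as.numeric(z_axis)
  if (is.unsorted(y_axis, strictly = TRUE) || is.unsorted(z_axis, strictly = TRUE))
    stop("dose_grid: axes must be strictly increasing with no duplicates")
  values <- as.matrix(values)
  if (!identical(dim(values), c(length(z_axis), length(y_axis))))
    stop("dose_grid: 'values' must have shape (length(z_axis), length(y_axis))")
  if (!unit %in% .GRID_UNITS)
    stop("dose_grid: unknown unit tag '", unit, "' (expected ",
         paste(.GRID_UNITS, collapse = " or "), ")")
  if (is.null(mask)) mask <- is.na(values) else mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (any(values[!mask] < 0))
    stop("dose_grid: unmasked values must be non-negative")
  dimnames(values) <- NULL
  structure(list(y_axis = y_axis, z_axis = z_axis, values = values,
                 mask = mask, unit = unit),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid %d z x %d y [%s], y in [%g, %g] cm, z in [%g, %g] cm, %d masked>\n",
    length(x$z_axis), length(x$y_axis), x$unit,
    min(x$y_axis), max(x$y_axis), min(x$z_axis), max(x$z_axis), sum(x$mask)))
  invisible(x)
}

#' Write / read a dose grid in the grid CSV dialect
#'
#' Dialect: line 1 is `# gzp6dose-grid v1 unit=<tag>`; line 2 is the
#' header `z_cm\\y_cm,<y1>,<y2>,...`; each following line is
#' `<z>,<v1>,<v2>,...`.  Masked cells are written as empty fields; on
#' reading, `-` is also accepted as masked (the convention of published
#' dose tables).  Values are serialized at full double precision, so
#' read-after-write is bit-exact.  Files may store z rows in descending
#' order; the reader normalizes to ascending.
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns a
#'   [dose_grid()].
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  fmt <- function(x) sprintf("%.17g", x)
  rows <- vapply(seq_along(grid$z_axis), function(i) {
    v <- ifelse(grid$mask[i, ], "", fmt(grid$values[i, ]))
    paste(c(fmt(grid$z_axis[i]), v), collapse = ",")
  }, character(1))
  writeLines(c(paste0(.GRID_MAGIC, " unit=", grid$unit),
               paste(c("z_cm\\y_cm", fmt(grid$y_axis)), collapse = ","),
               rows),
             path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], .GRID_MAGIC))
    stop("read_grid: not a gzp6dose-grid v1 file: ", path)
  unit <- sub(".*unit=", "", lines[1L])
  if (!unit %in% .GRID_UNITS)
    stop("read_grid: unknown unit tag '", unit, "'")
  hdr <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  y_axis <- as.numeric(hdr[-1L])
  if (anyNA(y_axis)) stop("read_grid: malformed y-axis header")
  body <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  ncol_exp <- length(y_axis) + 1L
  # a trailing masked cell yields one short field vector; pad it
  body <- lapply(body, function(f) c(f, rep("", max(0L, ncol_exp - length(f)))))
  if (any(lengths(body) != ncol_exp))
    stop("read_grid: ragged rows (expected ", ncol_exp, " fields per row)")
  z_axis <- as.numeric(vapply(body, `[[`, character(1), 1L))
  if (anyNA(z_axis)) stop("read_grid: malformed z coordinates")
  cells <- t(vapply(body, function(f) f[-1L], character(length(y_axis))))
  masked <- cells %in% c("", "-")
  vals <- suppressWarnings(as.numeric(cells))
  if (any(is.na(vals) & !masked)) stop("read_grid: malformed numeric cell")
  vals <- matrix(vals, nrow = length(z_axis))
  if (all(diff(z_axis) < 0)) {       # stored top-down; normalize
    ord <- order(z_axis)
    z_axis <- z_axis[ord]
    vals <- vals[ord, , drop = FALSE]
  }
  if (is.unsorted(z_axis, strictly = TRUE))
    stop("read_grid: z axis is not monotone")
  dose_grid(y_axis, z_axis, vals, unit = unit)
}

#' Cartesian to polar coordinates
#'
#' Maps a grid point (y, z) to the TG-43 polar frame: `r = sqrt(y^2 +
#' z^2)` and `theta` measured from the +z (source long) axis, in
#' `[0, 180]` degrees.  Negative y mirrors to `|y|` (cylindrical
#' symmetry).
#'
#' @param y,z Coordinates, cm (vectorized).
#' @return Data frame with columns `r` (cm) and `theta` (degrees).
#' @export
cart_to_polar <- function(y, z) {
  n <- max(length(y), length(z))
  y <- abs(rep_len(as.numeric(y), n))
  z <- rep_len(as.numeric(z), n)
  r <- sqrt(y^2 + z^2)
  if (any(r == 0))
    stop("cart_to_polar: the origin (0, 0) has no polar angle")
  data.frame(r = r, theta = atan2(y, z) * 180 / pi)
}

#' Polar dose samples
#'
#' @param r Radii, cm (> 0).
#' @param theta Polar angles, degrees in `[0, 180]`.
#' @param dose_rate Dose rates, cGy/h/U (> 0).
#' @return A data frame of class `polar_dose_samples` with columns
#'   `r`, `theta`, `dose_rate`.
#' @export
polar_dose_samples <- function(r, theta, dose_rate) {
  df <- data.frame(r = as.numeric(r), theta = as.numeric(theta),
                   dose_rate = as.numeric(dose_rate))
  if (any(df$r <= 0)) stop("polar_dose_samples: r must be positive")
  if (any(df$theta < 0 | df$theta > 180))
    stop("polar_dose_samples: theta must lie in [0, 180] degrees")
  if (any(df$dose_rate <= 0))
    stop("polar_dose_samples: dose_rate must be positive")
  class(df) <- c("polar_dose_samples", "data.frame")
  df
}

# Bilinear interpolation at (y, z), never using masked cells as stencil
# nodes: points coinciding with an unmasked grid node return that node's
# value exactly; if any stencil corner is masked, the nearest unmasked
# node's value is substituted with a warning.
.interp_grid <- function(grid, y, z) {
  ya <- grid$y_axis; za <- grid$z_axis; V <- grid$values
  n <- length(y)
  out <- numeric(n)
  fell_back <- FALSE
  oob <- y < ya[1L] | y > ya[length(ya)] | z < za[1L] | z > za[length(za)]
  if (any(oob))
    stop("dose grid interpolation: point(s) outside the grid bounding box: ",
         paste(sprintf("(y=%g, z=%g)", y[oob], z[oob]), collapse = ", "))
  for (k in seq_len(n)) {
    j <- findInterval(y[k], ya, rightmost.closed = TRUE)
    i <- findInterval(z[k], za, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(ya) - 1L)
    i <- min(max(i, 1L), length(za) - 1L)
    # node coincidence (tolerance absorbs trig round-off in polar mapping)
    jn <- which(abs(ya - y[k]) <= 1e-9)[1L]
    zn <- which(abs(za - z[k]) <= 1e-9)[1L]
    if (!is.na(jn) && !is.na(zn) && !grid$mask[zn, jn]) {
      out[k] <- V[zn, jn]
      next
    }
    c00 <- V[i, j]; c01 <- V[i, j + 1L]
    c10 <- V[i + 1L, j]; c11 <- V[i + 1L, j + 1L]
    if (anyNA(c(c00, c01, c10, c11))) {
      fell_back <- TRUE
      unm <- which(!grid$mask, arr.ind = TRUE)
      d2 <- (za[unm[, 1L]] - z[k])^2 + (ya[unm[, 2L]] - y[k])^2
      nn <- unm[which.min(d2), ]
      out[k] <- V[nn[1L], nn[2L]]
      next
    }
    ty <- (y[k] - ya[j]) / (ya[j + 1L] - ya[j])
    tz <- (z[k] - za[i]) / (za[i + 1L] - za[i])
    out[k] <- (1 - tz) * ((1 - ty) * c00 + ty * c01) +
      tz * ((1 - ty) * c10 + ty * c11)
  }
  if (fell_back)
    warning("dose grid interpolation: masked cell(s) in the stencil; ",
            "nearest unmasked value used")
  out
}

#' Resample a Cartesian dose grid onto polar nodes
#'
#' Evaluates the grid by bilinear interpolation at `(y, z) = (r sin(t),
#' r cos(t))` for every combination of the requested radii and angles.
#' Masked cells are never used as stencil nodes: if a stencil corner is
#' masked, the nearest unmasked grid value is substituted with a warning.
#'
#' @param grid A [dose_grid()].
#' @param r_nodes Radii, cm.
#' @param theta_nodes Polar angles, degrees.
#' @return A [polar_dose_samples()] data frame (one row per node pair).
#' @export
grid_to_polar_samples <- function(grid, r_nodes, theta_nodes) {
  stopifnot(inherits(grid, "dose_grid"))
  nodes <- expand.grid(r = as.numeric(r_nodes), theta = as.numeric(theta_nodes),
                       KEEP.OUT.ATTRS = FALSE)
  th <- nodes$theta * pi / 180
  y <- nodes$r * sin(th)
  z <- nodes$r * cos(th)
  oob <- y < grid$y_axis[1L] | y > max(grid$y_axis) |
    z < grid$z_axis[1L] | z > max(grid$z_axis)
  if (any(oob))
    stop("grid_to_polar_samples: node(s) outside the grid bounding box: ",
         paste(sprintf("(r=%g, theta=%g)", nodes$r[oob], nodes$theta[oob]),
               collapse = ", "))
  polar_dose_samples(nodes$r, nodes$theta, .interp_grid(grid, y, z))
}

#' Extract isodose contours from a dose grid
#'
#' Marching-squares level sets with linear interpolation along cell edges
#' (via [grDevices::contourLines()]).  Masked cells are excluded: no
#' contour segment crosses them.  A level outside the data range yields an
#' empty polyline list for that level, not an error.
#'
#' @param grid A [dose_grid()].
#' @param levels Positive, strictly increasing dose levels in the grid's
#'   unit.  Default `c(1, 2, 5, 10, 15, 20)`, the standard display levels
#'   in Gy for this unit's treatment plans.
#' @return An `isodose_contours` object: a list with one element per
#'   level, each holding `level`, `unit`, and `polylines` (a list of
#'   two-column `(y, z)` matrices).
#' @export
extract_isodose_contours <- function(grid, levels = c(1, 2, 5, 10, 15, 20)) {
  stopifnot(inherits(grid, "dose_grid"))
  levels <- as.numeric(levels)
  if (any(levels <= 0)) stop("extract_isodose_contours: levels must be positive")
  if (is.unsorted(levels, strictly = TRUE))
    stop("extract_isodose_contours: levels must be strictly increasing")
  # contourLines wants z[i, j] on (x[i], y[j]); our values are (z, y).
  # A constant grid legitimately has no level sets; silence the note.
  cl <- suppressWarnings(
    grDevices::contourLines(x = grid$z_axis, y = grid$y_axis,
                            z = grid$values, levels = levels))
  out <- lapply(levels, function(lv) {
    polys <- Filter(function(p) p$level == lv, cl)
    list(level = lv, unit = grid$unit,
         polylines = lapply(polys, function(p) {
           m <- cbind(y = p$y, z = p$x)
           dimnames(m) <- list(NULL, c("y", "z"))
           m
         }))
  })
  names(out) <- format(levels, trim = TRUE)
  structure(out, class = "isodose_contours")
}

#' @export
print.isodose_contours <- function(x, ...) {
  for (lv in x)
    cat(sprintf("level %g %s: %d polyline(s)\n", lv$level, lv$unit,
                length(lv$polylines)))
  invisible(x)
}

#' Write an isodose contour set as JSON
#'
#' One object per level: `{level, unit, polylines: [[[y, z], ...], ...]}`.
#'
#' @param contours An `isodose_contours` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "isodose_contours"))
  doc <- lapply(unclass(contours), function(lv) {
    list(level = lv$level, unit = lv$unit,
         polylines = lapply(lv$polylines, function(m) {
           lapply(seq_len(nrow(m)), function(i) c(m[i, "y"], m[i, "z"]))
         }))
  })
  jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
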