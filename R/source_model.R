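# Source braids: ordered arrangements of active and inert pellets in one
# GZP6 treatment channel.  Pellets are axial point anchors for dose-kernel
# placement; their 3D shape is not modelled.

#' Construct a single pellet
#'
#' A pellet is an axial point anchor along the braid axis.  Active pellets
#' carry a positive activity weight, expressed relative to the activity of
#' the reference (single-pellet) source; inert steel spacer pellets carry
#' weight zero.
#'
#' @param center_z Axial position of the pellet center, cm.
#' @param kind Either `"active"` or `"inert"`.
#' @param relative_activity Dimensionless weight; must be positive for
#'   active pellets and zero for inert ones.
#' @return A `pellet` object (named list).
#' @export
pellet <- function(center_z, kind = c("active", "inert"),
                   relative_activity = if (kind == "active") 1 else 0) {
  kind <- match.arg(kind)
  if (!is.numeric(center_z) || length(center_z) != 1L || !is.finite(center_z))
    stop("pellet: 'center_z' must be a single finite number (cm)")
  if (!is.numeric(relative_activity) || length(relative_activity) != 1L ||
      !is.finite(relative_activity) || relative_activity < 0)
    stop("pellet: 'relative_activity' must be a single non-negative number")
  if (kind == "inert" && relative_activity != 0)
    stop("pellet: 'relative_activity' must be 0 for an inert pellet")
  if (kind == "active" && relative_activity == 0)
    stop("pellet: 'relative_activity' must be > 0 for an active pellet")
  structure(list(center_z = center_z, kind = kind,
                 relative_activity = relative_activity),
            class = "pellet")
}

#' Physical dimensions of the active source pellet
#'
#' The GZP6 active pellet is a nickel-plated cobalt cylinder.  The TG-43
#' active length `L` is the length of the radioactive core, i.e. the overall
#' pellet length minus the plating at both ends: 0.2 cm - 2 x 0.005 cm =
#' 0.19 cm by default.
#'
#' @param active_length_L Active (core) length, cm.
#' @param core_diameter Core diameter, cm.
#' @param plating_thickness Nickel plating thickness, cm.
#' @return A `source_geometry` object.
#' @export
source_geometry <- function(active_length_L = 0.19, core_diameter = 0.1,
                            plating_thickness = 0.005) {
  dims <- c(active_length_L = active_length_L, core_diameter = core_diameter,
            plating_thickness = plating_thickness)
  if (!all(is.finite(dims)) || any(dims <= 0))
    stop("source_geometry: all dimensions must be positive")
  structure(as.list(dims), class = "source_geometry")
}

#' Construct a source braid
#'
#' @param name Identifier for the braid.
#' @param pellets List of [pellet()] objects with strictly increasing
#'   `center_z`; at least one must be active.
#' @param inter_pellet_spacing Default center-to-center spacing, cm, used
#'   when positions are generated from a pellet count (0.65 cm for GZP6).
#' @return A `source_braid` object with a `pellets` data frame
#'   (`z_cm`, `kind`, `relative_activity`).
#' @export
source_braid <- function(name, pellets, inter_pellet_spacing = 0.65) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("source_braid: 'name' must be a non-empty string")
  if (!length(pellets))
    stop("source_braid: at least one pellet is required")
  ok <- vapply(pellets, inherits, logical(1), what = "pellet")
  if (!all(ok)) stop("source_braid: 'pellets' must be a list of pellet objects")
  df <- data.frame(
    z_cm = vapply(pellets, `[[`, numeric(1), "center_z"),
    kind = vapply(pellets, `[[`, character(1), "kind"),
    relative_activity = vapply(pellets, `[[`, numeric(1), "relative_activity"),
    stringsAsFactors = FALSE
  )
  if (any(duplicated(df$z_cm)))
    stop("source_braid: duplicate pellet positions in 'z_cm'")
  if (is.unsorted(df$z_cm, strictly = TRUE))
    stop("source_braid: pellet centers must be strictly increasing in 'z_cm'")
  if (!any(df$kind == "active"))
    stop("source_braid: braid must contain at least one active pellet")
  if (!is.numeric(inter_pellet_spacing) || inter_pellet_spacing <= 0)
    stop("source_braid: 'inter_pellet_spacing' must be positive")
  structure(list(name = name, pellets = df,
                 inter_pellet_spacing = inter_pellet_spacing),
            class = "source_braid")
}

#' @export
print.source_braid <- function(x, ...) {
  n_act <- sum(x$pellets$kind == "active")
  cat(sprintf("<source_braid '%s': %d pellet(s), %d active>\n",
              x$name, nrow(x$pellets), n_act))
  print(x$pellets, row.names = FALSE)
  invisible(x)
}

.braid_allowed_keys <- c("name", "pellets", "n_active", "spacing_cm", "weights")

#' Load a source braid from a configuration document
#'
#' The document (JSON or YAML file, or an already-parsed list) declares a
#' `name` and either an explicit `pellets` list (each entry `z_cm`, `kind`,
#' `relative_activity`) or a generated layout via `n_active` active pellets
#' at `spacing_cm` center-to-center spacing with optional per-pellet
#' `weights`.  Generated positions are centered so the activity-unweighted
#' centroid of the active pellets lies at z = 0.  Unknown keys are rejected.
#'
#' @param config Path to a `.json`/`.yaml`/`.yml` file, or a named list.
#' @return A validated [source_braid()].
#' @export
load_braid <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("load_braid: file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::read_json(config, simplifyVector = FALSE),
      yaml = ,
      yml  = yaml::read_yaml(config),
      stop("load_braid: unsupported config extension '.", ext,
           "' (use .json, .yaml or .yml)"))
  }
  if (!is.list(config)) stop("load_braid: 'config' must be a file path or list")
  unknown <- setdiff(names(config), .braid_allowed_keys)
  if (length(unknown))
    stop("load_braid: unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$name)) stop("load_braid: missing required key 'name'")

  if (!is.null(config$pellets)) {
    pl <- lapply(config$pellets, function(p) {
      extra <- setdiff(names(p), c("z_cm", "kind", "relative_activity"))
      if (length(extra))
        stop("load_braid: unknown pellet key(s): ", paste(extra, collapse = ", "))
      if (is.null(p$z_cm) || is.null(p$kind))
        stop("load_braid: each pellet needs 'z_cm' and 'kind'")
      ra <- if (is.null(p$relative_activity)) {
        if (identical(p$kind, "active")) 1 else 0
      } else p$relative_activity
      pellet(as.numeric(p$z_cm), p$kind, as.numeric(ra))
    })
    spacing <- 0.65
  } else {
    n <- config$n_active
    if (is.null(n))
      stop("load_braid: config needs either 'pellets' or 'n_active'")
    n <- as.integer(n)
    if (is.na(n) || n < 1)
      stop("load_braid: 'n_active' must be a positive integer")
    spacing <- if (is.null(config$spacing_cm)) 0.65 else as.numeric(config$spacing_cm)
    if (!is.finite(spacing) || spacing <= 0)
      stop("load_braid: 'spacing_cm' must be positive")
    w <- if (is.null(config$weights)) rep(1, n) else as.numeric(unlist(config$weights))
    if (length(w) != n)
      stop("load_braid: 'weights' must have length n_active (", n, ")")
    if (any(!is.finite(w)) || any(w <= 0))
      stop("load_braid: 'weights' must all be positive")
    # active-pellet centroid at z = 0
    z <- (seq_len(n) - (n + 1) / 2) * spacing
    pl <- Map(function(zi, wi) pellet(zi, "active", wi), z, w)
  }
  source_braid(config$name, pl, inter_pellet_spacing = spacing)
}

#' Serialize a braid back to its configuration list
#'
#' Inverse of [load_braid()] for round-tripping: the returned list can be
#' passed to [load_braid()] (or written as JSON/YAML) and reproduces the
#' same braid.
#'
#' @param braid A [source_braid()].
#' @return A named list with keys `name` and `pellets`.
#' @export
braid_config <- function(braid) {
  stopifnot(inherits(braid, "source_braid"))
  list(
    name = braid$name,
    pellets = lapply(seq_len(nrow(braid$pellets)), function(i) {
      p <- braid$pellets[i, ]
      list(z_cm = p$z_cm, kind = p$kind, relative_activity = p$relative_activity)
    })
  )
}

#' Axial offsets and weights of the active pellets
#'
#' Inert pellets are excluded; order along z is preserved.  These offsets
#' are the shift distances used by the superimposition algorithm.
#'
#' @param braid A [source_braid()].
#' @return A data frame with columns `center_z` (cm) and `relative_activity`.
#' @export
pellet_offsets <- function(braid) {
  stopifnot(inherits(braid, "source_braid"))
  act <- braid$pellets[braid$pellets$kind == "active", , drop = FALSE]
  data.frame(center_z = act$z_cm, relative_activity = act$relative_activity,
             row.names = NULL)
}
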