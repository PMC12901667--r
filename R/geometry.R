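#' Landscape specification for a patch-corridor microcosm
#'
#' A landscape is two 16 x 10 mm habitat patches joined by a narrow corridor
#' (the "Short" and "Long" fragmentation levels), or a single isolated patch
#' (the "Control"). The canonical frame puts the origin at the bottom-left
#' corner of the Start patch, with `x` across the patch width and `y`
#' increasing along the dispersal axis (Start -> Corridor -> Target). All
#' lengths are millimetres.
#'
#' @param patch_length patch extent along the dispersal axis (mm).
#' @param patch_width patch extent across the dispersal axis (mm).
#' @param corridor_length corridor extent along the dispersal axis (mm).
#' @param corridor_width corridor extent across the dispersal axis (mm).
#' @param fragmentation label, one of `"Short"`, `"Long"`, `"Control"`.
#' @param has_corridor logical; `FALSE` for a Control (single-patch) landscape.
#' @return an object of class `landscape_spec`.
#' @seealso [build_default_landscape()], [assign_zone()], [accessible_area()]
#' @export
landscape_spec <- function(patch_length, patch_width,
                           corridor_length = 0, corridor_width = 0,
                           fragmentation = "Short",
                           has_corridor = TRUE) {
  stopifnot(
    is.numeric(patch_length), patch_length > 0,
    is.numeric(patch_width), patch_width > 0
  )
  if (has_corridor) {
    if (!(corridor_width > 0 && corridor_width <= patch_width))
      stop("corridor_width must lie in (0, patch_width]")
    if (!(corridor_length > 0))
      stop("corridor_length must be positive for a corridor landscape")
  } else {
    corridor_length <- 0
    corridor_width <- 0
  }
  structure(
    list(
      patch_length = as.numeric(patch_length),
      patch_width = as.numeric(patch_width),
      corridor_length = as.numeric(corridor_length),
      corridor_width = as.numeric(corridor_width),
      fragmentation = as.character(fragmentation),
      has_corridor = isTRUE(has_corridor)
    ),
    class = "landscape_spec"
  )
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat("<landscape_spec>", x$fragmentation, "\n")
  cat(sprintf("  patch: %g x %g mm\n", x$patch_length, x$patch_width))
  if (x$has_corridor)
    cat(sprintf("  corridor: %g x %g mm\n", x$corridor_width, x$corridor_length))
  else
    cat("  single isolated patch (no corridor)\n")
  cat(sprintf("  accessible area: %g mm^2\n", accessible_area(x)))
  invisible(x)
}

#' Build the default dispersal landscape for a fragmentation level
#'
#' Default dimensions: 16 x 10 mm patches; corridor 2.5 mm wide and 10 mm
#' (Short) or 20 mm (Long) long, so that the Long corridor is exactly twice
#' the Short one. The Control is a single isolated 16 x 10 mm patch.
#'
#' @param fragmentation `"Short"`, `"Long"` or `"Control"`.
#' @return a [landscape_spec()].
#' @export
#' @examples
#' build_default_landscape("Short")
#' build_default_landscape("Control")
build_default_landscape <- function(fragmentation = c("Short", "Long", "Control")) {
  fragmentation <- match.arg(fragmentation)
  switch(fragmentation,
    Short = landscape_spec(16, 10, corridor_length = 10, corridor_width = 2.5,
                           fragmentation = "Short"),
    Long = landscape_spec(16, 10, corridor_length = 20, corridor_width = 2.5,
                          fragmentation = "Long"),
    Control = landscape_spec(16, 10, fragmentation = "Control",
                             has_corridor = FALSE)
  )
}

## x-interval [lo, hi) of the corridor band, centred on the patch width.
corridor_band <- function(spec) {
  c(lo = (spec$patch_width - spec$corridor_width) / 2,
    hi = (spec$patch_width + spec$corridor_width) / 2)
}

## y breakpoints of the zone partition along the dispersal axis.
zone_breaks <- function(spec) {
  P <- spec$patch_length
  L <- spec$corridor_length
  c(start_hi = P, corridor_hi = P + L, target_hi = 2 * P + L)
}

#' Test whether points lie inside the accessible area of a landscape
#'
#' Uses the half-open convention: a point on the lower/left boundary of a
#' region belongs to it, a point on the upper/right boundary does not, so
#' every point belongs to at most one region.
#'
#' @param x,y coordinates in mm (vectorised).
#' @param spec a [landscape_spec()].
#' @return logical vector.
#' @export
point_in_landscape <- function(x, y, spec) {
  stopifnot(inherits(spec, "landscape_spec"), length(x) == length(y))
  W <- spec$patch_width
  b <- zone_breaks(spec)
  in_start <- x >= 0 & x < W & y >= 0 & y < b["start_hi"]
  if (!spec$has_corridor) return(unname(in_start))
  cb <- corridor_band(spec)
  in_corr <- x >= cb["lo"] & x < cb["hi"] &
    y >= b["start_hi"] & y < b["corridor_hi"]
  in_target <- x >= 0 & x < W & y >= b["corridor_hi"] & y < b["target_hi"]
  unname(in_start | in_corr | in_target)
}

#' Assign positions to landscape zones
#'
#' Maps each (x, y) position to exactly one zone of the landscape: `Start`
#' (`y` in the first patch), `Corridor` (`y` in the corridor interval and `x`
#' within the corridor band), or `Target` (`y` in the far patch). Control
#' landscapes always return `Control`. Intervals are half-open so every
#' interior point receives exactly one label.
#'
#' @param x,y coordinates in mm (vectorised).
#' @param spec a [landscape_spec()].
#' @return factor of zone labels with levels Start, Corridor, Target, Control.
#' @export
#' @examples
#' sp <- build_default_landscape("Short")
#' assign_zone(c(5, 5, 5), c(8, 20, 30), sp)
assign_zone <- function(x, y, spec) {
  stopifnot(inherits(spec, "landscape_spec"), length(x) == length(y))
  bad <- !point_in_landscape(x, y, spec) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "position (%.3f, %.3f) mm is outside the accessible area of the %s landscape",
      x[i], y[i], spec$fragmentation
    ))
  }
  if (!spec$has_corridor)
    return(factor(rep("Control", length(x)), levels = .zone_levels))
  b <- zone_breaks(spec)
  z <- ifelse(y < b["start_hi"], "Start",
              ifelse(y < b["corridor_hi"], "Corridor", "Target"))
  factor(z, levels = .zone_levels)
}

#' Accessible area of a landscape
#'
#' Total wetted area of the landscape: both patches plus the corridor, or the
#' single patch for a Control. Used e.g. for the uniform-occupancy limit of
#' the null movement model.
#'
#' @param spec a [landscape_spec()].
#' @return area in mm^2.
#' @export
#' @examples
#' accessible_area(build_default_landscape("Short")) # 345
accessible_area <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  patch <- spec$patch_length * spec$patch_width
  if (!spec$has_corridor) return(patch)
  2 * patch + spec$corridor_length * spec$corridor_width
}

#' Per-zone accessible areas
#'
#' @param spec a [landscape_spec()].
#' @return named numeric vector of areas (mm^2) per zone.
#' @export
zone_areas <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  patch <- spec$patch_length * spec$patch_width
  if (!spec$has_corridor) return(c(Control = patch))
  c(Start = patch,
    Corridor = spec$corridor_length * spec$corridor_width,
    Target = patch)
}

#' Read or write a landscape specification as a YAML config
#'
#' Landscape specs serialise to a small human-editable key-value file; all
#' lengths are millimetres.
#'
#' @param spec a [landscape_spec()].
#' @param path file path.
#' @return `read_landscape()` returns a [landscape_spec()];
#'   `write_landscape()` returns `path` invisibly.
#' @export
write_landscape <- function(spec, path) {
  stopifnot(inherits(spec, "landscape_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
#' @examples
#' read_landscape(system.file("extdata", "landscape_short.yml",
#'                            package = "microdisp"))
read_landscape <- function(path) {
  x <- yaml::read_yaml(path)
  landscape_spec(
    patch_length = x$patch_length, patch_width = x$patch_width,
    corridor_length = x$corridor_length %||% 0,
    corridor_width = x$corridor_width %||% 0,
    fragmentation = x$fragmentation %||% "Short",
    has_corridor = x$has_corridor %||% TRUE
  )
}
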