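#' Artifact non-uniformity metric of a radiograph
#'
#' Quantifies the structured non-uniformity the infill lattice imprints on
#' a radiograph. The region of interest is the part silhouette eroded by
#' `erosion_margin` (a disc structuring element), which strips the
#' high-contrast perimeter-wall rim so the metric tracks infill
#' non-uniformity. Metrics: `"sd_pathlength"` — population standard
#' deviation of the path length within the mask (default; robust summary
#' of lattice contrast); `"peak_to_peak"` — max minus min (outlier
#' sensitive, kept as a secondary metric).
#'
#' @param radiograph a `radiograph`
#' @param erosion_margin mask erosion margin, mm
#' @param metric_id `"sd_pathlength"` or `"peak_to_peak"`
#' @param threshold silhouette path-length threshold, mm
#' @return metric value, mm
#' @export
artifact_metric <- function(radiograph, erosion_margin = 1.35,
                            metric_id = c("sd_pathlength", "peak_to_peak"),
                            threshold = 0) {
  metric_id <- match.arg(metric_id)
  mask <- silhouette(radiograph, threshold)
  r <- round(erosion_margin / radiograph$pixel_spacing)
  if (r > 0) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    mask <- EBImage::erode(mask, brush) > 0
  }
  if (!any(mask))
    stop("eroded mask is empty; use a smaller erosion_margin")
  vals <- radiograph$path_length[mask]
  if (any(!is.finite(vals))) stop("non-finite path lengths in mask")
  switch(metric_id,
         sd_pathlength = sqrt(mean((vals - mean(vals))^2)),
         peak_to_peak = max(vals) - min(vals))
}

new_artifact_profile <- function(samples, metric_id, erosion_margin) {
  stopifnot(all(diff(samples$angle) > 0))
  structure(list(samples = samples, metric_id = metric_id,
                 erosion_margin = erosion_margin),
            class = "artifact_profile")
}

#' @export
print.artifact_profile <- function(x, ...) {
  s <- x$samples
  cat(sprintf("artifact_profile: %d angles in [%g, %g] deg, metric %s (erosion %.3g mm)\n",
              nrow(s), min(s$angle), max(s$angle), x$metric_id, x$erosion_margin))
  cat(sprintf("  min %.4f mm at %g deg; max %.4f mm at %g deg\n",
              min(s$metric), s$angle[which.min(s$metric)],
              max(s$metric), s$angle[which.max(s$metric)]))
  invisible(x)
}

#' Plot an artifact profile
#' @param x an `artifact_profile`
#' @param ... passed to [graphics::plot()]
#' @export
plot.artifact_profile <- function(x, ...) {
  graphics::plot(x$samples$angle, x$samples$metric, type = "l",
                 xlab = "tilt angle (deg)",
                 ylab = sprintf("%s (mm)", x$metric_id), ...)
  invisible(x)
}

#' Sweep the projection tilt angle and measure artifact
#'
#' Projects the volume at each tilt angle (all other geometry fixed) and
#' evaluates the artifact metric, producing the angle-to-artifact profile
#' used to locate the projections of least and greatest infill artifact.
#' Fully deterministic given its inputs.
#'
#' @param volume a `voxel_volume`
#' @param base_geom a [projection_geometry()]; its `tilt` is replaced by
#'   each sweep angle
#' @param angles increasing vector of tilt angles, degrees
#' @param metric_id,erosion_margin,threshold see [artifact_metric()]
#' @return an `artifact_profile`
#' @export
sweep_angles <- function(volume, base_geom = projection_geometry(),
                         angles = seq(0, 90, by = 0.5),
                         metric_id = c("sd_pathlength", "peak_to_peak"),
                         erosion_margin = 1.35, threshold = 0) {
  metric_id <- match.arg(metric_id)
  stopifnot(length(angles) >= 1, all(diff(angles) > 0))
  vals <- vapply(angles, function(th) {
    g <- base_geom
    g$tilt <- th %% 360
    tryCatch(artifact_metric(project(volume, g), erosion_margin, metric_id,
                             threshold),
             error = function(e) stop("at tilt ", th, " deg: ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  new_artifact_profile(data.frame(angle = angles, metric = vals),
                       metric_id, erosion_margin)
}

# golden-section search for an extremum of f on [lo, hi] (maximize if
# maximize = TRUE) down to bracket width <= step
golden_section <- function(f, lo, hi, step, maximize) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  sgn <- if (maximize) 1 else -1
  while (b - a > step) {
    if (sgn * f1 >= sgn * f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' Locate the angles of least and greatest artifact
#'
#' Finds the coarse argmin and argmax of the profile, then (when a
#' `refine` callable is supplied) refines each by golden-section search
#' within one coarse step of the bracket until the bracket is at most
#' `step` degrees. Ties break toward the smallest angle. If
#' `symmetry_period` is given the returned angles are reported modulo
#' that period.
#'
#' @param profile an `artifact_profile`
#' @param refine optional function(angle) -> metric used for sub-step
#'   refinement (typically a closure over [project()] +
#'   [artifact_metric()])
#' @param step refinement resolution, degrees
#' @param symmetry_period optional pattern symmetry period, degrees
#' @return list with `angle_min`, `metric_min`, `angle_max`, `metric_max`
#' @export
find_extrema <- function(profile, refine = NULL, step = 0.25,
                         symmetry_period = NULL) {
  s <- profile$samples
  if (nrow(s) < 3) stop("profile needs at least 3 samples")
  if (any(!is.finite(s$metric))) stop("non-finite metric values in profile")
  stopifnot(step > 0)
  coarse <- if (nrow(s) > 1) min(diff(s$angle)) else step

  locate <- function(maximize) {
    sgn <- if (maximize) 1 else -1
    i <- which(sgn * s$metric >= max(sgn * s$metric) - 1e-12)[1]  # smallest-angle tie
    ang <- s$angle[i]
    met <- s$metric[i]
    if (!is.null(refine) && coarse > step) {
      lo <- max(min(s$angle), ang - coarse)
      hi <- min(max(s$angle), ang + coarse)
      ang <- golden_section(refine, lo, hi, step, maximize)
      met <- refine(ang)
      # keep the coarse sample unless refinement strictly improved on it
      # (also enforces the smallest-angle tie rule on flat profiles)
      if (!(sgn * met > sgn * s$metric[i])) { ang <- s$angle[i]; met <- s$metric[i] }
    }
    list(angle = ang, metric = met)
  }
  mn <- locate(FALSE)
  mx <- locate(TRUE)
  wrap <- function(a) if (is.null(symmetry_period)) a else a %% symmetry_period
  list(angle_min = wrap(mn$angle), metric_min = mn$metric,
       angle_max = wrap(mx$angle), metric_max = mx$metric)
}

#' Default sweep tilt-axis azimuth for an infill pattern
#'
#' The tilt axis is chosen so that every wall family of the pattern
#' misaligns from the beam as the tilt angle grows, except at the tilt
#' that the pattern geometry singles out. For grid infill the axis lies
#' along the lattice's diagonal mirror plane (pattern azimuth minus 45
#' degrees), oblique to both wall families: an axis parallel to one
#' family would keep the orthogonal family beam-aligned at every tilt and
#' flatten the artifact profile. For cubic infill the axis is the primary
#' wall-family azimuth, so that family's 45-degree-inclined walls become
#' beam-aligned at a tilt of +45 degrees. For gyroid the axis follows the
#' pattern azimuth.
#'
#' @param infill an [infill_spec()]
#' @return tilt-axis azimuth in degrees
#' @export
default_tilt_axis <- function(infill) {
  stopifnot(inherits(infill, "infill_spec"))
  if (infill$pattern == "grid") infill$azimuth - 45 else infill$azimuth
}

#' Write an artifact profile as CSV
#'
#' Columns: `angle_deg`, `metric_mm`, `metric_id`, `erosion_margin_mm`.
#'
#' @param profile an `artifact_profile`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(angle_deg = profile$samples$angle,
                   metric_mm = profile$samples$metric,
                   metric_id = profile$metric_id,
                   erosion_margin_mm = profile$erosion_margin)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
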