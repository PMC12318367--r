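#' Projection geometry for a simulated radiograph
#'
#' Describes the x-ray geometry: parallel or cone beam, source-to-image
#' distance (SID), source-to-object distance (SOD, cone only), detector
#' pixel spacing and size, and the orientation of the central ray. The
#' tilt is the angle in degrees between the central ray and the build (Z,
#' extruded) axis; `tilt_axis_azimuth` is the in-plane direction (degrees
#' from +X) of the rotation axis about which the ray tilts. The part stays
#' fixed and the ray direction rotates. Defaults follow a clinical
#' radiography setup: SID 1000 mm, detector pixel 0.150 mm.
#'
#' @param mode `"parallel"` (default; at SID 1000 mm and desk-scale parts
#'   the cone angle is below 1.2 degrees, so divergence is negligible for
#'   artifact localization) or `"cone"`
#' @param sid source-to-image distance, mm
#' @param sod source-to-object distance, mm (cone only; default `sid - 50`)
#' @param detector_pixel detector pixel spacing, mm
#' @param detector_dims integer pair (nu, nv), or `NULL` to auto-size to
#'   the volume's rotated footprint plus a 2 mm margin
#' @param tilt angle between central ray and build axis, degrees
#' @param tilt_axis_azimuth azimuth of the in-plane tilt axis, degrees
#' @return an object of class `projection_geometry`
#' @export
projection_geometry <- function(mode = c("parallel", "cone"), sid = 1000,
                                sod = NULL, detector_pixel = 0.150,
                                detector_dims = NULL, tilt = 0,
                                tilt_axis_azimuth = 0) {
  mode <- match.arg(mode)
  stopifnot(sid > 0, detector_pixel > 0)
  if (mode == "cone") {
    if (is.null(sod)) sod <- sid - 50
    if (sod <= 0 || sod >= sid)
      stop("cone mode requires 0 < sod < sid")
  }
  tilt <- tilt %% 360
  structure(list(mode = mode, sid = sid, sod = sod,
                 detector_pixel = detector_pixel,
                 detector_dims = detector_dims, tilt = tilt,
                 tilt_axis_azimuth = tilt_axis_azimuth),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection_geometry: %s beam, tilt %.2f deg (axis azimuth %.1f deg)\n",
              x$mode, x$tilt, x$tilt_axis_azimuth))
  cat(sprintf("  SID %.0f mm%s, pixel %.4g mm\n", x$sid,
              if (x$mode == "cone") sprintf(", SOD %.0f mm", x$sod) else "",
              x$detector_pixel))
  invisible(x)
}

# central ray direction and detector axes for a geometry:
# axis a = (cos az, sin az, 0); ray d = sin(tilt) * m - cos(tilt) * z
# with m = (-sin az, cos az, 0); detector axes u = a, v = d x u.
geometry_frame <- function(geom) {
  az <- geom$tilt_axis_azimuth * pi / 180
  th <- geom$tilt * pi / 180
  a <- c(cos(az), sin(az), 0)
  m <- c(-sin(az), cos(az), 0)
  d <- sin(th) * m - cos(th) * c(0, 0, 1)
  v <- c(d[2] * a[3] - d[3] * a[2],
         d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1])
  list(d = d, u = a, v = v)
}

volume_center <- function(volume)
  volume$origin + (volume$dims - 1) * volume$spacing / 2

volume_corners <- function(volume) {
  lo <- volume$origin - volume$spacing / 2
  hi <- lo + volume$dims * volume$spacing
  as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                        z = c(lo[3], hi[3])))
}

#' Forward-project a voxel volume into a radiograph
#'
#' Computes a digitally reconstructed radiograph of the binary volume:
#' for every detector pixel, the exact summed intersection length (mm) of
#' its ray with occupied voxels, by incremental Siddon-style ray-grid
#' traversal. Parallel mode: all rays share the tilted central-ray
#' direction and the detector plane passes through the volume center.
#' Cone mode: rays diverge from a point source at distance SOD from the
#' volume center toward a detector at SID.
#'
#' @param volume a `voxel_volume`
#' @param geom a [projection_geometry()]
#' @return an object of class `radiograph`: `path_length` matrix (mm),
#'   `pixel_spacing`, `geometry`
#' @export
project <- function(volume, geom = projection_geometry()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(geom, "projection_geometry"))
  if (volume$spacing <= 0) stop("volume has zero spacing")
  fr <- geometry_frame(geom)
  c0 <- volume_center(volume)
  cone <- geom$mode == "cone"
  src <- if (cone) c0 - geom$sod * fr$d else c(0, 0, 0)
  det_c <- if (cone) c0 + (geom$sid - geom$sod) * fr$d else c0

  dims <- geom$detector_dims
  if (is.null(dims)) {
    corners <- volume_corners(volume)
    if (cone) {
      rel <- sweep(corners, 2, src)
      tden <- rel %*% fr$d
      scale <- as.numeric(geom$sid / tden)
      proj <- rel * scale
      pu <- proj %*% fr$u - sum((det_c - src) * fr$u)
      pv <- proj %*% fr$v - sum((det_c - src) * fr$v)
    } else {
      rel <- sweep(corners, 2, det_c)
      pu <- rel %*% fr$u
      pv <- rel %*% fr$v
    }
    margin <- 2
    dims <- c(2L * as.integer(ceiling((max(abs(pu)) + margin) / geom$detector_pixel)) + 1L,
              2L * as.integer(ceiling((max(abs(pv)) + margin) / geom$detector_pixel)) + 1L)
  }
  pl <- .project_volume(volume$occupancy, volume$dims, volume$origin,
                        volume$spacing, if (cone) 1L else 0L,
                        fr$d, src, det_c, fr$u, fr$v,
                        geom$detector_pixel, dims[1], dims[2])
  structure(list(path_length = pl, pixel_spacing = geom$detector_pixel,
                 geometry = geom, frame = fr, detector_center = det_c),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("radiograph: %d x %d pixels at %.4g mm (%s beam, tilt %.2f deg)\n",
              nrow(x$path_length), ncol(x$path_length), x$pixel_spacing,
              x$geometry$mode, x$geometry$tilt))
  cat(sprintf("  path length: max %.3f mm, mean %.3f mm\n",
              max(x$path_length), mean(x$path_length)))
  invisible(x)
}

#' Display a radiograph
#'
#' Renders the path-length map (or its radiographic intensity transform
#' when `mu` is given) as a grayscale image, dark where path length is
#' large, mimicking film.
#'
#' @param x a `radiograph`
#' @param mu optional linear attenuation coefficient, 1/mm; when supplied
#'   the displayed quantity is `exp(-mu * path_length)`
#' @param ... passed to [graphics::image()]
#' @export
plot.radiograph <- function(x, mu = NULL, ...) {
  img <- if (is.null(mu)) max(x$path_length) - x$path_length
         else exp(-mu * x$path_length)
  graphics::image(img, col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

#' Radiographic intensity transform of a path-length map
#'
#' Monochromatic Beer-Lambert mapping `I = I0 * exp(-mu * L)`, for
#' visualization of path-length radiographs with a material attenuation
#' coefficient. The artifact analysis itself always uses path length.
#'
#' @param radiograph a `radiograph`
#' @param mu linear attenuation coefficient, 1/mm
#' @param I0 unattenuated intensity
#' @return matrix of intensities
#' @export
path_to_intensity <- function(radiograph, mu, I0 = 1) {
  I0 * exp(-mu * radiograph$path_length)
}

#' Part silhouette of a radiograph
#'
#' Binary mask of the projected part: the largest connected component of
#' pixels whose path length exceeds `threshold`, with interior holes
#' filled. This is the region of interest within which the artifact
#' metric is evaluated.
#'
#' @param radiograph a `radiograph`
#' @param threshold path-length threshold, mm
#' @return logical matrix of the same size as the radiograph
#' @export
silhouette <- function(radiograph, threshold = 0) {
  stopifnot(threshold >= 0)
  mask <- radiograph$path_length > threshold
  if (!any(mask)) stop("no part in view: silhouette is empty")
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  comp <- lab == big
  filled <- EBImage::fillHull(comp)
  as.matrix(filled) > 0
}

#' Write a radiograph to disk
#'
#' Writes the path-length map as a 32-bit float TIFF (values in mm), an
#' optional window/level-scaled 16-bit PNG preview, and a JSON sidecar
#' echoing the projection geometry.
#'
#' @param radiograph a `radiograph`
#' @param path output TIFF path (`.tif`/`.tiff`)
#' @param png_preview also write a scaled 16-bit PNG next to the TIFF
#' @return `path`, invisibly
#' @export
write_radiograph <- function(radiograph, path, png_preview = TRUE) {
  pl <- radiograph$path_length
  # tiff stores matrices row-major top-down; transpose so x runs along
  # image columns and v along rows
  tiff::writeTIFF(t(pl) / max(max(pl), 1e-12), path, bits.per.sample = 32)
  g <- radiograph$geometry
  sidecar <- list(mode = g$mode, sid = g$sid, sod = g$sod,
                  detector_pixel = g$detector_pixel,
                  detector_dims = dim(pl), tilt = g$tilt,
                  tilt_axis_azimuth = g$tilt_axis_azimuth,
                  path_length_scale_mm = max(pl),
                  units = "stored value x path_length_scale_mm = mm")
  jsonlite::write_json(sidecar, paste0(sub("\\.tiff?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (png_preview) {
    img <- t(pl) / max(max(pl), 1e-12)
    png::writePNG(1 - img, paste0(sub("\\.tiff?$", "", path), ".png"))
  }
  invisible(path)
}
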