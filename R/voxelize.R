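#' Construct an empty voxel volume
#'
#' Axis-aligned binary occupancy grid with isotropic spacing. `origin` is
#' the physical position (mm) of the center of voxel `[1, 1, 1]`; storage
#' is a raw 3-D array (0/1), x fastest.
#'
#' @param dims integer triple (nx, ny, nz)
#' @param origin numeric triple, mm
#' @param spacing isotropic voxel size, mm (default 0.1125, i.e. 112.5 um)
#' @return an object of class `voxel_volume`
#' @export
voxel_volume <- function(dims, origin = c(0, 0, 0), spacing = 0.1125) {
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0, length(origin) == 3)
  occ <- array(as.raw(0), dim = as.integer(dims))
  structure(list(occupancy = occ, origin = as.numeric(origin),
                 spacing = spacing, dims = as.integer(dims)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume: %d x %d x %d voxels at %.4g mm (%.3g x %.3g x %.3g mm)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$dims[1] * x$spacing, x$dims[2] * x$spacing, x$dims[3] * x$spacing))
  cat(sprintf("  occupied: %d voxels (%.3f mm^3)\n",
              occupied_count(x), occupied_volume(x)))
  invisible(x)
}

# number of occupied voxels / occupied physical volume (mm^3)
occupied_count <- function(volume) sum(volume$occupancy != as.raw(0))
#' Total occupied material volume of a voxel volume, mm^3
#' @param volume a `voxel_volume`
#' @export
occupied_volume <- function(volume) occupied_count(volume) * volume$spacing^3

#' Voxelize a toolpath model into a binary volume ("virtual print")
#'
#' Rasterizes every extrusion segment as a bead: a stadium (capsule)
#' footprint in XY of width [bead_width()] swept along the segment path,
#' extruded vertically over `(z_end - layer_height, z_end]`. A voxel is
#' occupied iff its center lies inside any bead; overlapping beads union.
#' The grid covers the extruded toolpath's bounding box (inflated by the
#' bead radius) expanded by `padding` on all sides.
#'
#' @param model a `print_model`
#' @param spacing isotropic voxel size, mm; the reference resolution is
#'   0.1125 mm (112.5 um)
#' @param padding extra margin around the part, mm
#' @return a `voxel_volume`
#' @export
voxelize <- function(model, spacing = 0.1125, padding = 2) {
  stopifnot(inherits(model, "print_model"), spacing > 0)
  h <- model$constants$layer_height
  segs <- model$segments[model$segments$role == "extrude", , drop = FALSE]
  if (nrow(segs) == 0) {
    vol <- voxel_volume(c(1, 1, 1), spacing = spacing)
    return(vol)
  }
  if (spacing > h)
    warning("spacing (", spacing, " mm) exceeds layer height (", h,
            " mm); thin beads may be missed")
  L <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2 + (segs$z1 - segs$z0)^2)
  keep <- L > 1e-9
  segs <- segs[keep, , drop = FALSE]
  L <- L[keep]
  w <- bead_width(segs$feed_delta, L, model$constants)

  r <- w / 2
  xmin <- min(pmin(segs$x0, segs$x1) - r) - padding
  xmax <- max(pmax(segs$x0, segs$x1) + r) + padding
  ymin <- min(pmin(segs$y0, segs$y1) - r) - padding
  ymax <- max(pmax(segs$y0, segs$y1) + r) + padding
  zmin <- min(segs$z1 - h) - padding
  zmax <- max(segs$z1) + padding
  dims <- pmax(1L, as.integer(ceiling(c(xmax - xmin, ymax - ymin, zmax - zmin) / spacing)))
  origin <- c(xmin, ymin, zmin) + spacing / 2

  vol <- voxel_volume(dims, origin, spacing)
  .voxelize_segments(vol$occupancy, vol$dims, vol$origin, vol$spacing,
                     as.matrix(segs[, c("x0", "y0", "z0")]),
                     as.matrix(segs[, c("x1", "y1", "z1")]),
                     w, h)
  vol
}

#' Fraction of occupied voxels within an axis-aligned box
#'
#' @param volume a `voxel_volume`
#' @param box numeric `c(xmin, ymin, zmin, xmax, ymax, zmax)` in mm, or
#'   `NULL` for the whole grid
#' @return occupied / total voxel count within the box
#' @export
fill_fraction <- function(volume, box = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (is.null(box)) return(occupied_count(volume) / prod(volume$dims))
  stopifnot(length(box) == 6)
  idx <- function(a, lo = TRUE) {
    i <- (box[a] - volume$origin[((a - 1) %% 3) + 1]) / volume$spacing + 1
    if (lo) max(1L, as.integer(ceiling(i - 1e-9)))
    else min(volume$dims[a - 3], as.integer(floor(i + 1e-9)))
  }
  i0 <- idx(1); j0 <- idx(2); k0 <- idx(3)
  i1 <- idx(4, FALSE); j1 <- idx(5, FALSE); k1 <- idx(6, FALSE)
  if (i1 < i0 || j1 < j0 || k1 < k0)
    stop("mask region does not intersect the voxel grid")
  sub <- volume$occupancy[i0:i1, j0:j1, k0:k1]
  sum(sub != as.raw(0)) / length(sub)
}

# ---- analytic phantoms (validation fixtures) ----------------------------

#' Solid box phantom volume
#'
#' Voxelizes an axis-aligned solid box (centered at the origin) by the
#' same voxel-center occupancy rule as [voxelize()]; used to validate the
#' projector against analytic path lengths.
#'
#' @param size numeric triple: box edge lengths, mm
#' @param spacing voxel size, mm
#' @param padding margin, mm
#' @return a `voxel_volume`
#' @export
slab_phantom <- function(size = c(20, 20, 10), spacing = 0.2, padding = 2) {
  ext <- size / 2 + padding
  dims <- as.integer(ceiling(2 * ext / spacing))
  origin <- -ext + spacing / 2
  vol <- voxel_volume(dims, origin, spacing)
  .fill_shape(vol$occupancy, vol$dims, vol$origin, vol$spacing, 0L,
              c(-size / 2, size / 2))
  vol
}

#' Solid sphere phantom volume
#'
#' @param radius sphere radius, mm
#' @param spacing voxel size, mm
#' @param padding margin, mm
#' @return a `voxel_volume`
#' @export
sphere_phantom <- function(radius = 5, spacing = 0.2, padding = 2) {
  ext <- radius + padding
  dims <- as.integer(ceiling(rep(2 * ext / spacing, 3)))
  origin <- rep(-ext + spacing / 2, 3)
  vol <- voxel_volume(dims, origin, spacing)
  .fill_shape(vol$occupancy, vol$dims, vol$origin, vol$spacing, 1L,
              c(0, 0, 0, radius))
  vol
}

# ---- MetaImage I/O ------------------------------------------------------

#' Write a voxel volume as MetaImage
#'
#' Writes an 8-bit binary MetaImage volume: single-file `.mha` (header +
#' raw data) or `.mhd` header with a sibling `.raw` file, with spacing and
#' origin recorded in the header.
#'
#' @param volume a `voxel_volume`
#' @param path output path ending in `.mha` or `.mhd`
#' @return `path`, invisibly
#' @export
write_metaimage <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  single <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (!single && !grepl("\\.mhd$", path, ignore.case = TRUE))
    stop("path must end in .mha or .mhd")
  datafile <- if (single) "LOCAL" else basename(sub("\\.mhd$", ".raw", path, ignore.case = TRUE))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(volume$dims, collapse = " ")),
    paste("ElementSpacing =", paste(rep(volume$spacing, 3), collapse = " ")),
    paste("Offset =", paste(volume$origin, collapse = " ")),
    "ElementType = MET_UCHAR",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (single) {
    writeBin(as.vector(volume$occupancy), con)
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.vector(volume$occupancy), rawcon)
    close(rawcon)
  }
  invisible(path)
}

#' Read a MetaImage volume written by [write_metaimage()]
#'
#' @param path `.mha` or `.mhd` file
#' @return a `voxel_volume`
#' @export
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated MetaImage header")
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementType, "MET_UCHAR"))
    stop("only MET_UCHAR volumes are supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  if (max(abs(spacing - spacing[1])) > 1e-9)
    stop("anisotropic spacing is not supported")
  origin <- as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  n <- prod(dims)
  dat <- if (identical(hdr$ElementDataFile, "LOCAL")) {
    readBin(con, "raw", n)
  } else {
    readBin(file.path(dirname(path), hdr$ElementDataFile), "raw", n)
  }
  if (length(dat) != n) stop("truncated MetaImage data")
  vol <- voxel_volume(dims, origin, spacing[1])
  vol$occupancy <- array(dat, dim = dims)
  vol
}
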