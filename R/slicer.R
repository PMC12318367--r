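#' Part specification for the built-in slicer
#'
#' Describes a regular hexagonal prism test specimen: width across flats,
#' height, number of perimeter loops and solid top/bottom layers. The
#' default 40 mm x 10 mm part with 2 perimeters and no solid layers is the
#' reference specimen used throughout the artifact analyses; solid layers
#' only add a uniform path-length offset at normal incidence and blur the
#' localization of artifact extrema, so they default to zero.
#'
#' @param across_flats hexagon width across flats, mm
#' @param height part height, mm (rounded to a whole number of layers)
#' @param perimeter_count number of concentric perimeter loops per layer
#' @param bottom_solid_layers,top_solid_layers solid (100% rectilinear)
#'   layers at the bottom/top of the part
#' @return an object of class `part_spec`
#' @export
part_spec <- function(across_flats = 40, height = 10, perimeter_count = 2,
                      bottom_solid_layers = 0, top_solid_layers = 0) {
  stopifnot(across_flats > 0, height > 0, perimeter_count >= 0,
            bottom_solid_layers >= 0, top_solid_layers >= 0)
  structure(list(across_flats = across_flats, height = height,
                 perimeter_count = as.integer(perimeter_count),
                 bottom_solid_layers = as.integer(bottom_solid_layers),
                 top_solid_layers = as.integer(top_solid_layers)),
            class = "part_spec")
}

#' Infill specification
#'
#' @param pattern one of `"grid"`, `"cubic"`, `"gyroid"`
#' @param density target infill area/volume fraction in (0, 1]
#' @param extrusion_width deposited bead width, mm (at least 0.9 x nozzle)
#' @param phase_offset lateral phase of the pattern, mm
#' @param azimuth in-plane orientation of the pattern's primary line
#'   family, degrees from +X. Defaults: 45 for grid (slicer convention),
#'   0 for cubic and gyroid.
#' @return an object of class `infill_spec`
#' @export
infill_spec <- function(pattern = c("grid", "cubic", "gyroid"),
                        density = 0.15, extrusion_width = 0.45,
                        phase_offset = 0, azimuth = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(density > 0, density <= 1, extrusion_width > 0)
  if (is.null(azimuth)) azimuth <- if (pattern == "grid") 45 else 0
  structure(list(pattern = pattern, density = density,
                 extrusion_width = extrusion_width,
                 phase_offset = phase_offset, azimuth = azimuth),
            class = "infill_spec")
}

# --- polygon helpers (convex regions only: hexagons and their insets) ----

# regular hexagon, width across flats af, centered at origin, vertices at
# multiples of 60 degrees (flat edges facing +/-30, +/-90, +/-150 degrees)
hexagon_polygon <- function(across_flats) {
  r <- across_flats / sqrt(3)  # circumradius
  a <- (0:5) * pi / 3
  cbind(x = r * cos(a), y = r * sin(a))
}

# inset a regular hexagon by d (shrinks the apothem by d)
inset_hexagon <- function(across_flats, d) {
  af <- across_flats - 2 * d
  if (af <= 0) return(NULL)
  hexagon_polygon(af)
}

# area of a simple polygon (shoelace)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# half-plane representation n.x <= c of a convex CCW polygon
convex_halfplanes <- function(poly) {
  nv <- nrow(poly)
  nxt <- c(2:nv, 1)
  ex <- poly[nxt, 1] - poly[, 1]
  ey <- poly[nxt, 2] - poly[, 2]
  # outward normal for CCW polygon: (ey, -ex)
  nx <- ey; ny <- -ex
  len <- sqrt(nx^2 + ny^2)
  nx <- nx / len; ny <- ny / len
  list(nx = nx, ny = ny, c = nx * poly[, 1] + ny * poly[, 2])
}

point_in_convex <- function(pts, hp, tol = 1e-9) {
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_along(hp$c))
    inside <- inside & (hp$nx[i] * pts[, 1] + hp$ny[i] * pts[, 2] <= hp$c[i] + tol)
  inside
}

# Clip an open polyline (n x 2 matrix) to a convex polygon. Returns a list
# of polylines (possibly empty). Cyrus-Beck interval clipping per segment,
# with contiguous in-region runs merged back into single polylines.
clip_polyline_convex <- function(pts, hp) {
  n <- nrow(pts)
  if (n < 2) return(list())
  p <- pts[-n, , drop = FALSE]
  d <- pts[-1, , drop = FALSE] - p
  t0 <- rep(0, n - 1)
  t1 <- rep(1, n - 1)
  ok <- rep(TRUE, n - 1)
  for (i in seq_along(hp$c)) {
    num <- hp$c[i] - (hp$nx[i] * p[, 1] + hp$ny[i] * p[, 2])
    den <- hp$nx[i] * d[, 1] + hp$ny[i] * d[, 2]
    par <- abs(den) < 1e-12
    ok <- ok & !(par & num < 0)          # parallel and outside
    ent <- !par & den < 0                 # entering
    ext <- !par & den > 0                 # exiting
    t <- num / ifelse(par, 1, den)
    t0[ent] <- pmax(t0[ent], t[ent])
    t1[ext] <- pmin(t1[ext], t[ext])
  }
  ok <- ok & (t0 <= t1 + 1e-12)
  if (!any(ok)) return(list())
  out <- list()
  cur <- NULL
  for (s in seq_len(n - 1)) {
    if (!ok[s]) { if (!is.null(cur)) { out[[length(out) + 1L]] <- cur; cur <- NULL }; next }
    a <- p[s, ] + t0[s] * d[s, ]
    b <- p[s, ] + t1[s] * d[s, ]
    if (is.null(cur)) {
      cur <- rbind(a, b)
    } else if (t0[s] < 1e-12 && all(abs(cur[nrow(cur), ] - a) < 1e-9)) {
      cur <- rbind(cur, b)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- rbind(a, b)
    }
    if (t1[s] < 1 - 1e-12) { out[[length(out) + 1L]] <- cur; cur <- NULL }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  out[vapply(out, function(m) sum(sqrt(rowSums((m[-1, , drop = FALSE] -
    m[-nrow(m), , drop = FALSE])^2))) > 1e-9, logical(1))]
}

# family of parallel chords: lines along direction u(azimuth), offsets
# along the left normal m(azimuth), clipped to the region
parallel_chords <- function(hp, bbox_radius, azimuth_deg, spacing, offset0) {
  u <- c(cos(azimuth_deg * pi / 180), sin(azimuth_deg * pi / 180))
  m <- c(-u[2], u[1])
  kmin <- floor((-bbox_radius - offset0) / spacing)
  kmax <- ceiling((bbox_radius - offset0) / spacing)
  out <- list()
  for (k in kmin:kmax) {
    o <- offset0 + k * spacing
    a <- o * m - bbox_radius * u
    b <- o * m + bbox_radius * u
    out <- c(out, clip_polyline_convex(rbind(a, b), hp))
  }
  out
}

#' Grid infill polylines for one layer
#'
#' Two orthogonal families of parallel lines at the pattern azimuth and
#' azimuth + 90 deg, with spacing `s = 2 * extrusion_width / density` so the
#' deposited area fraction equals the target density. The pattern is
#' identical at every layer, so the deposited beads stack into continuous
#' vertical walls through the whole print.
#'
#' @param region convex polygon (n x 2 matrix, mm) to fill
#' @param layer_z layer top Z, mm (unused: the grid pattern is z-invariant)
#' @param infill an [infill_spec()]
#' @return list of polylines (2-column matrices, mm)
#' @export
grid_infill <- function(region, layer_z, infill) {
  if (is.null(region) || nrow(region) < 3) return(list())
  hp <- convex_halfplanes(region)
  rad <- max(sqrt(rowSums(region^2))) + 1
  s <- 2 * infill$extrusion_width / infill$density
  c(parallel_chords(hp, rad, infill$azimuth, s, infill$phase_offset),
    parallel_chords(hp, rad, infill$azimuth + 90, s, infill$phase_offset))
}

#' Cubic infill polylines for one layer
#'
#' Three families of parallel lines with azimuths 120 deg apart and spacing
#' `s = 3 * extrusion_width / density`. Each family's lines shift laterally
#' by one layer height per layer (in-plane offset decreases with `layer_z`
#' along the family's left normal), so successive layers stack into planar
#' walls inclined 45 degrees to the build direction — the diagonal faces of
#' a corner-standing cubic lattice.
#'
#' @inheritParams grid_infill
#' @return list of polylines (2-column matrices, mm)
#' @export
cubic_infill <- function(region, layer_z, infill) {
  if (is.null(region) || nrow(region) < 3) return(list())
  hp <- convex_halfplanes(region)
  rad <- max(sqrt(rowSums(region^2))) + 1
  s <- 3 * infill$extrusion_width / infill$density
  out <- list()
  for (az in infill$azimuth + c(0, 120, 240)) {
    out <- c(out, parallel_chords(hp, rad, az, s, infill$phase_offset - layer_z))
  }
  out
}

# gyroid implicit function with period P (triply periodic minimal surface)
gyroid_g <- function(x, y, z, period) {
  k <- 2 * pi / period
  sin(k * x) * cos(k * y) + sin(k * y) * cos(k * z) + sin(k * z) * cos(k * x)
}

# in-plane gradient of gyroid_g at fixed z
gyroid_grad_xy <- function(x, y, z, period) {
  k <- 2 * pi / period
  list(gx = k * (cos(k * x) * cos(k * y) - sin(k * z) * sin(k * x)),
       gy = k * (-sin(k * x) * sin(k * y) + cos(k * y) * cos(k * z)))
}

# zero-level isocontours of the gyroid in the slab z = layer_z over a
# rectangle, as polylines; vertices Newton-refined onto the isosurface
gyroid_contours <- function(xlim, ylim, layer_z, period, step) {
  xs <- seq(xlim[1], xlim[2], by = step)
  ys <- seq(ylim[1], ylim[2], by = step)
  g <- outer(xs, ys, gyroid_g, z = layer_z, period = period)
  cl <- grDevices::contourLines(xs, ys, g, levels = 0)
  lapply(cl, function(cc) {
    px <- cc$x; py <- cc$y
    for (it in 1:5) {  # damped Newton projection onto g = 0
      gv <- gyroid_g(px, py, layer_z, period)
      gr <- gyroid_grad_xy(px, py, layer_z, period)
      n2 <- gr$gx^2 + gr$gy^2
      n2[n2 < 1e-12] <- 1
      dx <- gv * gr$gx / n2
      dy <- gv * gr$gy / n2
      # cap the step near saddle points, where the gradient vanishes
      sl <- sqrt(dx^2 + dy^2)
      damp <- ifelse(sl > step / 2, step / (2 * sl), 1)
      px <- px - damp * dx
      py <- py - damp * dy
    }
    cbind(px, py)
  })
}

#' Gyroid infill polylines for one layer
#'
#' The layer's toolpaths are the zero isocontours of the gyroid implicit
#' surface `sin(kx)cos(ky) + sin(ky)cos(kz) + sin(kz)cos(kx)` (with
#' `k = 2*pi/period`) evaluated at the layer height and clipped to the
#' region; the azimuth rotates the pattern in-plane. Contours are sampled
#' by marching squares at a grid fine enough that chord lengths stay below
#' half the extrusion width, then Newton-projected onto the isosurface.
#' The `period` must be supplied via [calibrate_gyroid_period()] (stored by
#' [generate_part()] in the infill spec as `$period`).
#'
#' @inheritParams grid_infill
#' @param period gyroid period, mm (overrides `infill$period`)
#' @return list of polylines (2-column matrices, mm)
#' @export
gyroid_infill <- function(region, layer_z, infill, period = NULL) {
  if (is.null(region) || nrow(region) < 3) return(list())
  if (is.null(period)) period <- infill$period
  if (is.null(period))
    stop("gyroid infill needs a period; run calibrate_gyroid_period()")
  hp <- convex_halfplanes(region)
  rad <- max(sqrt(rowSums(region^2)))
  step <- infill$extrusion_width / 3
  az <- infill$azimuth * pi / 180
  rot <- matrix(c(cos(az), sin(az), -sin(az), cos(az)), 2, 2)
  # generate in pattern frame over a disc-covering square, rotate to part frame
  lim <- c(-rad - step, rad + step) + infill$phase_offset
  polys <- gyroid_contours(lim, lim, layer_z, period, step)
  out <- list()
  for (pp in polys) {
    pts <- pp %*% t(rot)
    out <- c(out, clip_polyline_convex(pts, hp))
  }
  out
}

# mean isocontour length per unit area of the gyroid at period P,
# averaged over nz slices of one z-period
gyroid_contour_length_per_area <- function(period, nz = 12, n = 64) {
  xs <- seq(0, period, length.out = n + 1)[-(n + 1)]
  total <- 0
  for (z in (seq_len(nz) - 0.5) / nz * period) {
    g <- outer(xs, xs, gyroid_g, z = z, period = period)
    # wrap one sample row/col so contours span the full period
    gw <- rbind(cbind(g, g[, 1]), c(g[1, ], g[1, 1]))
    xw <- c(xs, period)
    cl <- grDevices::contourLines(xw, xw, gw, levels = 0)
    for (cc in cl)
      total <- total + sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }
  total / (nz * period^2)
}

#' Calibrate the gyroid period for a target density
#'
#' Finds the gyroid period `P` such that the deposited area fraction —
#' mean isocontour length per unit area times the extrusion width — equals
#' the target density within 2%. Solved by bisection on `P` in [1, 100] mm
#' against a numeric contour-length evaluation; the contour length per
#' unit area scales as `1/P`, so density is monotone decreasing in `P`.
#'
#' @param density target area fraction in (0, 1)
#' @param extrusion_width bead width, mm
#' @return period `P` in mm
#' @examples
#' P <- calibrate_gyroid_period(0.15, 0.45)
#' @export
calibrate_gyroid_period <- function(density, extrusion_width) {
  stopifnot(density > 0, density < 1, extrusion_width > 0)
  dens_at <- function(P) extrusion_width * gyroid_contour_length_per_area(P)
  lo <- 1; hi <- 100
  dlo <- dens_at(lo); dhi <- dens_at(hi)
  if (density > dlo || density < dhi)
    stop("density ", density, " not achievable with extrusion width ",
         extrusion_width, " mm and period in [1, 100] mm")
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    dm <- dens_at(mid)
    if (abs(dm - density) / density < 0.005) return(mid)
    if (dm > density) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# 100% rectilinear fill for solid layers: parallel lines at bead-width
# spacing, direction alternating 45/135 degrees by layer parity
solid_fill <- function(region, layer_index, infill) {
  if (is.null(region) || nrow(region) < 3) return(list())
  hp <- convex_halfplanes(region)
  rad <- max(sqrt(rowSums(region^2))) + 1
  az <- if (layer_index %% 2 == 0) 45 else 135
  parallel_chords(hp, rad, az, infill$extrusion_width, 0)
}

# append polyline moves (travel to start, extrude along) to a segment list
polyline_segments <- function(poly, z, w, constants, prev_end) {
  n <- nrow(poly)
  segs <- vector("list", n)
  j <- 0L
  if (is.null(prev_end) || any(abs(prev_end - c(poly[1, ], z)) > 1e-9)) {
    from <- if (is.null(prev_end)) c(poly[1, ], z) else prev_end
    j <- j + 1L
    segs[[j]] <- c(from, poly[1, ], z, 0)  # travel
  }
  for (i in seq_len(n - 1)) {
    L <- sqrt(sum((poly[i + 1, ] - poly[i, ])^2))
    if (L < 2e-4) next  # below the G-code coordinate resolution
    j <- j + 1L
    segs[[j]] <- c(poly[i, ], z, poly[i + 1, ], z, feed_for_bead(w, L, constants))
  }
  segs[seq_len(j)]
}

#' Generate a hexagonal test specimen as a toolpath model
#'
#' Emulates slicing a regular hexagonal prism: per layer, concentric
#' perimeter loops inset by multiples of the extrusion width, then infill
#' polylines (grid, cubic, or gyroid at the requested density) clipped to
#' the innermost inset polygon shrunk by half an extrusion width. Solid
#' bottom/top layers, when requested, use 100%-density rectilinear fill.
#' Every extrusion move's filament feed is computed so the deposited bead
#' has cross-section `extrusion_width x layer_height` (exact inverse of
#' [bead_width()]), so slicing and voxelization agree on bead geometry by
#' construction.
#'
#' @param part a [part_spec()]
#' @param infill an [infill_spec()]
#' @param constants a [printer_constants()]
#' @return a `print_model`
#' @examples
#' m <- generate_part(part_spec(across_flats = 12, height = 1),
#'                    infill_spec("grid"))
#' @export
generate_part <- function(part, infill, constants = printer_constants()) {
  stopifnot(inherits(part, "part_spec"), inherits(infill, "infill_spec"))
  w <- infill$extrusion_width
  if (w < 0.9 * constants$nozzle_diameter)
    stop("extrusion_width must be at least 0.9 x nozzle_diameter")
  h <- constants$layer_height
  n_layers <- max(1L, as.integer(round(part$height / h)))

  if (infill$pattern == "gyroid" && is.null(infill$period))
    infill$period <- calibrate_gyroid_period(infill$density, w)

  # perimeter centerlines at insets (i + 0.5) w; infill clip region at
  # (perimeter_count + 0.5) w
  loops <- list()
  for (i in seq_len(part$perimeter_count)) {
    hx <- inset_hexagon(part$across_flats, (part$perimeter_count - i + 0.5) * w)
    if (is.null(hx))
      stop("part too small for ", part$perimeter_count, " perimeter loops")
    loops[[i]] <- rbind(hx, hx[1, , drop = FALSE])  # closed, innermost-first? outermost last
  }
  region <- inset_hexagon(part$across_flats, (part$perimeter_count + 0.5) * w)
  if (is.null(region) || polygon_area(region) <= 0)
    stop("infill region empty after insetting: across_flats = ",
         part$across_flats, ", perimeters = ", part$perimeter_count)

  all_segs <- list()
  prev_end <- NULL
  for (li in seq_len(n_layers) - 1L) {
    z <- (li + 1L) * h
    solid <- li < part$bottom_solid_layers || li >= n_layers - part$top_solid_layers
    paths <- loops
    fill <- if (solid) {
      solid_fill(region, li, infill)
    } else {
      switch(infill$pattern,
             grid   = grid_infill(region, z, infill),
             cubic  = cubic_infill(region, z, infill),
             gyroid = gyroid_infill(region, z, infill))
    }
    for (pl in c(paths, fill)) {
      segs <- polyline_segments(pl, z, w, constants, prev_end)
      if (length(segs)) {
        all_segs <- c(all_segs, segs)
        last <- segs[[length(segs)]]
        prev_end <- last[4:6]
      }
    }
  }
  mat <- do.call(rbind, all_segs)
  segments <- data.frame(
    x0 = mat[, 1], y0 = mat[, 2], z0 = mat[, 3],
    x1 = mat[, 4], y1 = mat[, 5], z1 = mat[, 6],
    feed_delta = mat[, 7],
    role = ifelse(mat[, 7] > 0, "extrude", "travel"),
    layer_index = layer_of(mat[, 6], h))
  model <- new_print_model(segments, constants)
  model$part <- part
  model$infill <- infill
  model
}
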