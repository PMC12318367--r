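#' Printer constants
#'
#' Physical constants of the FDM printer/filament combination that govern
#' how much material a move deposits: filament diameter (feedstock), layer
#' height (bead height), and nozzle diameter (lower bound on bead width).
#' Defaults correspond to a standard desktop FDM setup: 1.75 mm PLA
#' filament, 0.2 mm layers, 0.4 mm nozzle.
#'
#' @param filament_diameter filament diameter in mm (> 0)
#' @param layer_height layer height in mm (> 0, at most `nozzle_diameter`)
#' @param nozzle_diameter nozzle bore in mm (> 0)
#' @return an object of class `printer_constants`
#' @examples
#' printer_constants()
#' @export
printer_constants <- function(filament_diameter = 1.75,
                              layer_height = 0.2,
                              nozzle_diameter = 0.4) {
  stopifnot(filament_diameter > 0, layer_height > 0, nozzle_diameter > 0)
  if (layer_height > nozzle_diameter)
    stop("layer_height (", layer_height, " mm) must not exceed nozzle_diameter (",
         nozzle_diameter, " mm)")
  structure(list(filament_diameter = filament_diameter,
                 layer_height = layer_height,
                 nozzle_diameter = nozzle_diameter),
            class = "printer_constants")
}

#' @export
print.printer_constants <- function(x, ...) {
  cat(sprintf("printer_constants: filament %.3g mm, layer %.3g mm, nozzle %.3g mm\n",
              x$filament_diameter, x$layer_height, x$nozzle_diameter))
  invisible(x)
}

# cross-sectional area of the filament feedstock, mm^2
filament_area <- function(constants) pi * constants$filament_diameter^2 / 4

# layer i spans z in (i*h, (i+1)*h]; assign by the move's end Z
layer_of <- function(z, layer_height) {
  pmax(0L, as.integer(ceiling(z / layer_height - 1e-6)) - 1L)
}

new_print_model <- function(segments, constants, prime_count = 0L) {
  # segments: data.frame with x0,y0,z0,x1,y1,z1,feed_delta,role,layer_index
  stopifnot(is.data.frame(segments))
  if (nrow(segments)) {
    bb <- rbind(
      apply(segments[, c("x0", "y0", "z0")], 2, min),
      apply(segments[, c("x1", "y1", "z1")], 2, max))
    bb[1, ] <- pmin(bb[1, ], apply(segments[, c("x1", "y1", "z1")], 2, min))
    bb[2, ] <- pmax(bb[2, ], apply(segments[, c("x0", "y0", "z0")], 2, max))
    dimnames(bb) <- list(c("min", "max"), c("x", "y", "z"))
  } else {
    bb <- matrix(0, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z")))
  }
  structure(list(segments = segments, constants = constants,
                 bounding_box = bb, prime_count = prime_count),
            class = "print_model")
}

#' @export
print.print_model <- function(x, ...) {
  ne <- sum(x$segments$role == "extrude")
  cat(sprintf("print_model: %d segments (%d extrude, %d travel)\n",
              nrow(x$segments), ne, nrow(x$segments) - ne))
  if (nrow(x$segments)) {
    bb <- x$bounding_box
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    cat(sprintf("  total filament feed: %.3f mm\n",
                sum(x$segments$feed_delta[x$segments$role == "extrude"])))
  }
  invisible(x)
}

# split a G-code line into command word + parameter tokens, handling
# comments, blank lines and N-number/checksum framing
strip_gcode_line <- function(line) {
  line <- sub(";.*$", "", line)
  line <- sub("\\*[0-9]+\\s*$", "", line)   # checksum
  line <- sub("^\\s*N[0-9]+\\s+", "", line) # line number
  trimws(line)
}

#' Parse G-code into a toolpath model
#'
#' Reads Marlin/Prusa-dialect G-code (linear moves only) and returns the
#' ordered list of toolpath segments with per-segment filament feed.
#' Supported words: `G0`/`G1` (linear move), `G90`/`G91` (absolute/relative
#' positioning, E included), `M82`/`M83` (absolute/relative extrusion),
#' `G92` (axis reset, notably `E`), `G21` (mm units). Comments (`;`),
#' blank lines, line numbers (`N...`) and checksums (`*nn`) are ignored, as
#' are temperature/fan and other unrecognized M-codes. A move with positive
#' extrusion delta and nonzero XYZ displacement becomes an `extrude`
#' segment; retraction (negative delta) or zero-extrusion moves become
#' `travel` segments. A positive extrusion with no motion (de-retraction
#' prime) deposits nothing; such events are counted in `prime_count`.
#'
#' @param lines character vector of G-code lines, or a file path when
#'   `is_path = TRUE`
#' @param constants a [printer_constants()] object
#' @param is_path interpret `lines` as a file path
#' @param skip_arcs if `TRUE`, arc moves (`G2`/`G3`) are skipped with a
#'   warning instead of raising an error
#' @return a `print_model`: ordered segments, constants, bounding box
#' @examples
#' m <- parse_gcode(c("G90", "M82", "G1 Z0.2", "G1 X10 Y0 E0.5"))
#' m$segments
#' @export
parse_gcode <- function(lines, constants = printer_constants(),
                        is_path = FALSE, skip_arcs = FALSE) {
  if (is_path) lines <- readLines(lines, warn = FALSE)
  pos <- c(x = 0, y = 0, z = 0)
  e <- 0
  abs_pos <- TRUE
  abs_e <- TRUE
  prime_count <- 0L
  n <- length(lines)
  # pre-allocated growing columns
  cap <- max(256L, n)
  x0 <- y0 <- z0 <- x1 <- y1 <- z1 <- fd <- numeric(cap)
  role <- character(cap)
  k <- 0L

  for (i in seq_len(n)) {
    ln <- strip_gcode_line(lines[i])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    cmd <- toupper(toks[1])
    if (cmd %in% c("G2", "G3", "G02", "G03")) {
      if (skip_arcs) { warning("skipping arc move at line ", i); next }
      stop("arc moves (G2/G3) are not supported (line ", i,
           "); re-slice with arcs disabled or use skip_arcs = TRUE")
    }
    if (cmd == "G20")
      stop("inch units (G20) are not supported (line ", i, "); use mm (G21)")
    if (cmd == "G90") { abs_pos <- TRUE; abs_e <- TRUE; next }
    if (cmd == "G91") { abs_pos <- FALSE; abs_e <- FALSE; next }
    if (cmd == "M82") { abs_e <- TRUE; next }
    if (cmd == "M83") { abs_e <- FALSE; next }
    if (cmd == "G92") {
      for (tk in toks[-1]) {
        ax <- toupper(substr(tk, 1, 1))
        val <- suppressWarnings(as.numeric(substring(tk, 2)))
        if (is.na(val)) stop("malformed coordinate token '", tk, "' at line ", i)
        if (ax == "E") e <- val
        else if (ax %in% c("X", "Y", "Z")) pos[tolower(ax)] <- val
      }
      next
    }
    if (!(cmd %in% c("G0", "G1", "G00", "G01"))) next  # tolerate unknown commands

    new_pos <- pos
    new_e <- e
    saw_e <- FALSE
    for (tk in toks[-1]) {
      ax <- toupper(substr(tk, 1, 1))
      if (ax == "F") next
      val <- suppressWarnings(as.numeric(substring(tk, 2)))
      if (is.na(val)) stop("malformed coordinate token '", tk, "' at line ", i)
      if (ax %in% c("X", "Y", "Z")) {
        new_pos[tolower(ax)] <- if (abs_pos) val else pos[tolower(ax)] + val
      } else if (ax == "E") {
        saw_e <- TRUE
        new_e <- if (abs_e) val else e + val
      }
    }
    de <- if (saw_e) new_e - e else 0
    moved <- any(new_pos != pos)
    if (moved) {
      k <- k + 1L
      if (k > cap) {  # grow
        cap <- cap * 2L
        length(x0) <- length(y0) <- length(z0) <- cap
        length(x1) <- length(y1) <- length(z1) <- length(fd) <- cap
        length(role) <- cap
      }
      x0[k] <- pos["x"]; y0[k] <- pos["y"]; z0[k] <- pos["z"]
      x1[k] <- new_pos["x"]; y1[k] <- new_pos["y"]; z1[k] <- new_pos["z"]
      fd[k] <- de
      role[k] <- if (de > 0) "extrude" else "travel"
    } else if (de > 0) {
      prime_count <- prime_count + 1L  # stationary prime: not deposited
    }
    pos <- new_pos
    e <- new_e
  }

  idx <- seq_len(k)
  segments <- data.frame(
    x0 = x0[idx], y0 = y0[idx], z0 = z0[idx],
    x1 = x1[idx], y1 = y1[idx], z1 = z1[idx],
    feed_delta = fd[idx], role = role[idx],
    layer_index = layer_of(z1[idx], constants$layer_height))
  if (prime_count > 0)
    warning(prime_count, " stationary prime move(s) ignored (not deposited)")
  new_print_model(segments, constants, prime_count)
}

#' Bead width of an extrusion move
#'
#' Width of the rectangular-cross-section bead that conserves the extruded
#' filament volume: `w = feed_delta * A_fil / (L * layer_height)` with
#' `A_fil = pi * filament_diameter^2 / 4`. This is the deposited track
#' width used by the voxelizer.
#'
#' @param feed_delta filament feed over the move, mm (> 0)
#' @param length_mm XY(Z) path length of the move, mm (> 0)
#' @param constants a [printer_constants()] object
#' @return bead width in mm
#' @examples
#' bead_width(0.5, 10)  # ~0.601 mm
#' @export
bead_width <- function(feed_delta, length_mm, constants = printer_constants()) {
  if (any(length_mm <= 0))
    stop("degenerate extrusion: zero path length with positive feed (blob)")
  feed_delta * filament_area(constants) / (length_mm * constants$layer_height)
}

# inverse of bead_width: filament feed that realizes a bead of width w
feed_for_bead <- function(width, length_mm, constants) {
  width * length_mm * constants$layer_height / filament_area(constants)
}

#' Serialize a toolpath model to G-code
#'
#' Emits absolute-coordinate, absolute-extrusion Marlin-dialect G-code that
#' round-trips through [parse_gcode()]: segment count, roles and endpoints
#' are preserved to the coordinate format precision (4 decimal places, mm;
#' extrusion 5 decimal places).
#'
#' @param model a `print_model`
#' @param path optional file to write; if `NULL` the lines are returned
#' @return character vector of G-code lines (invisibly when `path` given)
#' @export
write_gcode <- function(model, path = NULL) {
  segs <- model$segments
  out <- c("; generated by printdrr", "G21", "G90", "M82", "G92 E0")
  if (nrow(segs)) {
    n <- nrow(segs)
    lines <- character(2L * n)
    m <- 0L
    cur <- c(NA_real_, NA_real_, NA_real_)
    e <- 0
    fmt <- function(v) formatC(v, format = "f", digits = 4)
    for (i in seq_len(n)) {
      st <- c(segs$x0[i], segs$y0[i], segs$z0[i])
      en <- c(segs$x1[i], segs$y1[i], segs$z1[i])
      if (any(is.na(cur)) || any(abs(cur - st) > 5e-5)) {
        m <- m + 1L
        lines[m] <- paste0("G0 X", fmt(st[1]), " Y", fmt(st[2]), " Z", fmt(st[3]))
        cur <- st
      }
      m <- m + 1L
      if (segs$role[i] == "extrude") {
        e <- e + segs$feed_delta[i]
        lines[m] <- paste0("G1 X", fmt(en[1]), " Y", fmt(en[2]), " Z", fmt(en[3]),
                           " E", formatC(e, format = "f", digits = 5))
      } else {
        lines[m] <- paste0("G0 X", fmt(en[1]), " Y", fmt(en[2]), " Z", fmt(en[3]))
      }
      cur <- en
    }
    out <- c(out, lines[seq_len(m)])
  }
  out <- c(out, "; end")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
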