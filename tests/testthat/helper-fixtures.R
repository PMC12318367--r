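# Lazily computed, session-cached fixtures shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small hexagonal fixture: 20 mm across flats, 2 perimeters
small_fixture <- function(pattern, height = 4, density = 0.15) {
  cached(paste("fix", pattern, height, density), {
    generate_part(part_spec(across_flats = 20, height = height),
                  infill_spec(pattern, density = density))
  })
}

small_volume <- function(pattern, spacing = 0.1125, height = 4) {
  cached(paste("vol", pattern, spacing, height), {
    voxelize(small_fixture(pattern, height), spacing = spacing)
  })
}

# total extruded filament volume of a model, mm^3
extruded_volume <- function(model) {
  segs <- model$segments
  sum(segs$feed_delta[segs$role == "extrude"]) *
    pi * model$constants$filament_diameter^2 / 4
}

# synthetic radiograph wrapper around a bare path-length matrix
fake_radiograph <- function(path_length, pixel = 0.15) {
  structure(list(path_length = path_length, pixel_spacing = pixel,
                 geometry = projection_geometry(detector_pixel = pixel)),
            class = "radiograph")
}
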