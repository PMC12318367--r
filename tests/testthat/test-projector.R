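test_that("an empty volume projects to an all-zero radiograph", {
  v <- voxel_volume(c(20, 20, 20), origin = c(-2, -2, -2), spacing = 0.2)
  r <- project(v, projection_geometry())
  expect_true(all(r$path_length == 0))
  expect_error(silhouette(r), "empty")
})

test_that("slab path length follows t / cos(theta)", {
  v <- cached("slab", slab_phantom(c(20, 20, 10), spacing = 0.2))
  for (th in c(0, 15, 30, 45, 60)) {
    r <- project(v, projection_geometry(tilt = th))
    # central pixel, far from edges
    ctr <- r$path_length[(nrow(r$path_length) + 1) %/% 2,
                         (ncol(r$path_length) + 1) %/% 2]
    expect_equal(ctr, 10 / cos(th * pi / 180), tolerance = 0.02)
  }
})

test_that("sphere projection matches the analytic chord profile", {
  sp <- 0.2
  v <- cached("sphere", sphere_phantom(5, spacing = sp))
  r <- project(v, projection_geometry(detector_pixel = 0.15))
  n <- nrow(r$path_length)
  iu <- seq_len(n)
  # impact parameter of each pixel along the central row
  dvals <- abs((iu - (n + 1) / 2) * 0.15)
  row <- r$path_length[, (ncol(r$path_length) + 1) %/% 2]
  chord <- ifelse(dvals < 5, 2 * sqrt(pmax(25 - dvals^2, 0)), 0)
  # away from the rim the digital chord tracks the analytic one
  core <- dvals < 4.5
  expect_lt(max(abs(row[core] - chord[core])), 2 * sp)
})

test_that("projection at tilt equals projection of the rotated volume", {
  # the sphere is rotation-invariant: tilting the ray must not change the
  # radiograph beyond discretization error
  v <- cached("sphere", sphere_phantom(5, spacing = 0.2))
  dims <- c(91L, 91L)
  r0 <- project(v, projection_geometry(tilt = 0, detector_dims = dims))
  r1 <- project(v, projection_geometry(tilt = 37, tilt_axis_azimuth = 20,
                                       detector_dims = dims))
  # compare away from the rim, where near-tangent rays make the
  # voxelized surface staircase dominate; the tilted view must track the
  # analytic chord map (the ideal rotated image) to discretization error
  off <- (seq_len(91) - 46) * 0.15
  rad <- sqrt(outer(off^2, off^2, "+"))
  chord <- ifelse(rad < 5, 2 * sqrt(pmax(25 - rad^2, 0)), 0)
  core <- rad < 3.5
  expect_lt(max(abs(r1$path_length[core] - chord[core])), 2 * 0.2)
  expect_lt(mean(abs(r0$path_length[core] - r1$path_length[core])), 0.2)
})

test_that("parallel projection at matched sampling conserves mass", {
  v <- cached("slab", slab_phantom(c(20, 20, 10), spacing = 0.2))
  r <- project(v, projection_geometry(detector_pixel = 0.2))
  expect_equal(sum(r$path_length) * 0.2^2, occupied_volume(v),
               tolerance = 0.01)
  vg <- small_volume("grid")
  rg <- project(vg, projection_geometry(detector_pixel = vg$spacing))
  expect_equal(sum(rg$path_length) * vg$spacing^2, occupied_volume(vg),
               tolerance = 0.01)
})

test_that("cone beam converges to the parallel beam at large distances", {
  v <- cached("slab", slab_phantom(c(20, 20, 10), spacing = 0.2))
  rp <- project(v, projection_geometry(tilt = 10))
  dims <- dim(rp$path_length)
  # magnification at the volume center plane is sid/sod = 2, so a cone
  # detector at twice the pixel pitch samples the same center-plane rays
  rc2 <- project(v, projection_geometry("cone", sid = 2e5, sod = 1e5,
                                        tilt = 10, detector_dims = dims,
                                        detector_pixel = 2 * 0.15))
  expect_lt(max(abs(rc2$path_length - rp$path_length)), 0.2)
})

test_that("radiographs are finite, non-negative, and mm-scaled", {
  r <- project(small_volume("grid"), projection_geometry(tilt = 33))
  expect_true(all(is.finite(r$path_length)))
  expect_true(all(r$path_length >= 0))
  expect_lt(max(r$path_length), 20)
  expect_equal(r$pixel_spacing, 0.15)  # default detector pitch
  expect_equal(r$geometry$sid, 1000)   # default SID
})

test_that("silhouette recovers the part footprint", {
  v <- small_volume("grid")
  r <- project(v, projection_geometry())
  mask <- silhouette(r)
  hex_area <- sqrt(3) / 2 * 20^2  # across-flats formula
  expect_equal(sum(mask) * r$pixel_spacing^2, hex_area, tolerance = 0.02)
  # a solid slab's silhouette is its footprint
  vs <- cached("slab", slab_phantom(c(20, 20, 10), spacing = 0.2))
  rs <- project(vs, projection_geometry())
  ms <- silhouette(rs)
  expect_equal(sum(ms) * 0.15^2, 400, tolerance = 0.02)
})

test_that("radiograph files round-trip path lengths and geometry", {
  r <- project(small_volume("grid", spacing = 0.2, height = 1), projection_geometry())
  d <- withr::local_tempdir()
  p <- file.path(d, "rad.tif")
  write_radiograph(r, p)
  expect_true(file.exists(p))
  expect_true(file.exists(file.path(d, "rad.png")))
  sidecar <- jsonlite::read_json(file.path(d, "rad.json"))
  expect_equal(sidecar$sid, 1000)
  img <- tiff::readTIFF(p)
  expect_equal(max(img) * sidecar$path_length_scale_mm, max(r$path_length),
               tolerance = 1e-5)
})
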