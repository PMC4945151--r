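# Border extraction, measurement-line and band placement, landmark
# registration.

test_that("extract_borders recovers analytic border lengths exactly once", {
  # single disc in a surround: one closed border of length ~ 2*pi*r
  m <- sample_area_map("A1_in_A2", list(radius = 750))
  b <- find_region_border(m, c("A1", "A2"))
  expect_true(b$closed)
  expect_lt(abs(b$length - 2 * pi * 750) / (2 * pi * 750), 0.01)
  expect_equal(rowSums(b$tangents^2), rep(1, nrow(b$vertices)),
               tolerance = 1e-9)
  # rectangle region: border length equals the perimeter
  m <- sample_area_map("laminar_IIIa_IIIb", list(width = 2000, height = 800))
  b <- find_region_border(m, c("IIIa", "IIIb"))
  expect_equal(b$length, 2000)
  # 2x2 barrel map: no border segment is emitted twice
  m <- sample_barrel_map(2, 2, seed = 4)
  bs <- extract_borders(m)
  keys <- character(0)
  for (bb in bs) {
    v <- bb$vertices
    idx <- cbind(seq_len(nrow(v)),
                 c(seq_len(nrow(v))[-1], if (bb$closed) 1L else NA))
    idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
    keys <- c(keys, apply(idx, 1, function(ij)
      paste(sort(c(paste(round(v[ij[1], ], 6), collapse = ","),
                   paste(round(v[ij[2], ], 6), collapse = ","))),
            collapse = "|")))
  }
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("zero-area polygons are skipped with a warning", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  degen <- cbind(c(50, 60, 50), c(50, 50, 50))  # zero area
  m <- astroborder:::new_region_map(
    list(list(outer = sq, holes = list(), class = "A", id = "a"),
         list(outer = degen, holes = list(), class = "B", id = "b")),
    extent = c(0, 100, 0, 100),
    classify = function(x, y) rep("A", length(x)),
    areas = list(A = 1e4, B = 0), layout = list(type = "custom"))
  expect_warning(bs <- extract_borders(m), "degenerate")
  expect_length(bs, 0L)  # the square's edges all lie on the extent
})

test_that("rasters export as plain-text PGM pages", {
  m <- sample_barrel_map(1, 1, seed = 2)
  sc <- synth_scene(m, generator_config(fiber_density = c(core = 0.02),
                                        seed = 2))
  r <- rasterize_scene(sc, 10)
  stem <- file.path(tempdir(), "raster")
  paths <- write_raster_pgm(r, stem)
  expect_true(all(file.exists(paths)))
  hdr <- readLines(paste0(stem, "_astro.pgm"), n = 3)
  expect_identical(hdr[1], "P2")
  expect_identical(hdr[2], sprintf("%d %d", ncol(r$astro), nrow(r$astro)))
})

test_that("septal and core lines pair with identical orientation", {
  m <- sample_barrel_map(3, 3, seed = 8)
  ln <- place_septal_and_core_lines(m)
  sep <- ln[ln$class == "septal", ]
  core <- ln[ln$class == "core", ]
  expect_identical(nrow(sep), nrow(core))
  mrg <- merge(sep, core, by = "pair_key")
  expect_identical(mrg$angle.x, mrg$angle.y)   # exactly equal
  expect_identical(mrg$length.x, mrg$length.y)
  # septal line centers sit on the septum (classify at midpoint)
  mid <- cbind((sep$x0 + sep$x1) / 2, (sep$y0 + sep$y1) / 2)
  expect_true(all(classify_points(m, mid) == "septum"))
  mid_c <- cbind((core$x0 + core$x1) / 2, (core$y0 + core$y1) / 2)
  expect_true(all(classify_points(m, mid_c) == "core"))
})

test_that("the core span window excludes small barrels", {
  # all spans fixed at 300 um: nothing qualifies under the [350, 450] window
  m <- sample_barrel_map(2, 2, core_span = 300, septum_width = 50, seed = 1)
  ln <- place_septal_and_core_lines(m, line_length = 250,
                                    core_span_window = c(350, 450))
  expect_identical(nrow(ln), 0L)
  # and a single-barrel map has no inter-barrel border at all
  m1 <- sample_barrel_map(1, 1, seed = 1)
  expect_identical(nrow(place_septal_and_core_lines(m1)), 0L)
})

test_that("offset lines sit at their stated distance from the border", {
  # straight vertical-free case: laminar border at y = 0
  m <- sample_area_map("laminar_IIIa_IIIb", list(width = 3000, height = 1200))
  b <- find_region_border(m, c("IIIa", "IIIb"))
  ln <- place_offset_lines(m, b, offsets = c(50, 200), line_length = 375,
                           station_spacing = 400)
  expect_setequal(unique(ln$side), c("IIIa", "IIIb"))
  expect_setequal(unique(ln$offset), c(50, 200))
  # 4 lines per full station (2 offsets x 2 sides)
  expect_identical(nrow(ln) %% 4L, 0L)
  # point-to-border distance oracle: min distance over both endpoints and
  # center equals the offset within 1 um (straight border: |y|)
  d <- pmin(abs(ln$y0), abs(ln$y1))
  expect_lt(max(abs(d - ln$offset)), 1)
  # side label consistent with the sign of y
  expect_true(all((ln$y0 > 0) == (ln$side == "IIIa")))
  # offset 0 puts the line on the border
  l0 <- place_offset_lines(m, b, offsets = 0, line_length = 100)
  expect_true(all(abs(l0$y0) < 1e-6 & abs(l0$y1) < 1e-6))
})

test_that("offset lines on a circular border respect distance and side", {
  m <- sample_area_map("A1_in_A2", list(radius = 750))
  b <- find_region_border(m, c("A1", "A2"))
  ln <- place_offset_lines(m, b, offsets = 50, line_length = 50,
                           station_spacing = 200)
  r_ctr <- sqrt(((ln$x0 + ln$x1) / 2)^2 + ((ln$y0 + ln$y1) / 2)^2)
  expect_lt(max(abs(r_ctr[ln$side == "A1"] - 700)), 1)
  expect_lt(max(abs(r_ctr[ln$side == "A2"] - 800)), 1)
  # chord sagitta keeps every point within ~1 um of the nominal offset
  ends_r <- sqrt(ln$x0^2 + ln$y0^2)
  expect_lt(max(abs(ends_r[ln$side == "A2"] - 800)), 1.5)
})

test_that("blob lines hit centers, inter-blob centers and margins", {
  m <- sample_area_map("blob_interblob",
                       list(period = 1000, n_blobs = 5, blob_rx = 200,
                            blob_ry = 300, height = 800))
  ln <- place_blob_lines(m, line_length = 500, margin_gap = 50)
  bc <- ln[ln$class == "blob_center", ]
  expect_identical(nrow(bc), 5L)
  expect_equal(bc$x0, m$layout$centers, tolerance = 1e-9)
  ic <- ln[ln$class == "interblob_center", ]
  expect_equal(ic$x0, c(1000, 2000, 3000, 4000), tolerance = 1e-9)
  im <- ln[ln$class == "interblob_margin", ]
  expect_equal(im$x0, m$layout$centers + 200 + 50, tolerance = 1e-9)
  # all vertical and centered on the blob band
  expect_true(all(ln$x0 == ln$x1))
  expect_equal(ln$y1 - ln$y0, rep(500, nrow(ln)))
})

test_that("density bands are perpendicular, sized and oriented", {
  m <- sample_area_map("laminar_IIIa_IIIb", list(width = 3000, height = 1200))
  b <- find_region_border(m, c("IIIa", "IIIb"))
  bands <- place_density_bands(b, width = 25, length = 100, count = 10,
                               region_map = m, inner_class = "IIIa")
  expect_identical(nrow(bands), 10L)
  expect_true(all(bands$width == 25 & bands$length == 100))
  # straight border: all band axes parallel, perpendicular to the tangent
  expect_lt(max(abs(bands$nx)), 1e-9)
  expect_equal(abs(bands$ny), rep(1, 10))
  expect_lt(max(abs(bands$nx * bands$tx + bands$ny * bands$ty)), 1e-9)
  # axis points away from the inner class (IIIa at y > 0 -> ny negative)
  expect_true(all(bands$ny == -1))
  # human preset: 30 um wide bands
  b30 <- place_density_bands(b, width = 30, length = 100, count = 10)
  expect_true(all(b30$width == 30))
  # insufficient border length -> fewer bands with a warning
  short <- straight_border(0, 100)
  expect_warning(bs <- place_density_bands(short, width = 25, length = 100,
                                           count = 10), "non-overlapping")
  expect_lt(nrow(bs), 10L)
})

test_that("landmark transforms: recovery, residuals, inversion", {
  set.seed(42)
  src <- cbind(runif(5, 0, 1000), runif(5, 0, 1000))
  expect_error(estimate_landmark_transform(src[1, , drop = FALSE],
                                           src[1, , drop = FALSE]), "2 point")
  expect_error(estimate_landmark_transform(src[c(1, 1), ] * 0,
                                           src[c(1, 1), ] * 0), "degenerate")
  # identity
  tr <- estimate_landmark_transform(src, src)
  expect_equal(tr$rotation, 0)
  expect_equal(tr$rms, 0)
  # known 30 degree rotation + translation recovered within 1e-6
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  dst <- sweep(src %*% t(R), 2, c(120, -40), `+`)
  tr <- estimate_landmark_transform(src, dst)
  expect_equal(tr$rotation, th, tolerance = 1e-6)
  expect_equal(tr$translation, c(120, -40), tolerance = 1e-6)
  expect_equal(tr$rms, 0, tolerance = 1e-6)
  # one perturbed point among 5: closed form agrees with the numeric
  # least-squares oracle, residual positive and bounded by the perturbation
  dst2 <- dst; dst2[3, ] <- dst2[3, ] + c(8, -6)
  tr2 <- estimate_landmark_transform(src, dst2)
  orc <- oracle_rigid_fit(src, dst2)
  expect_equal(tr2$rms, orc$rms, tolerance = 1e-6)
  expect_equal(tr2$rotation, orc$rotation, tolerance = 1e-5)
  expect_gt(tr2$rms, 0)
  expect_lt(tr2$rms, 10)
  # transform o inverse = identity within 1e-6 um
  pts <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
  back <- apply_transform(invert_transform(tr2), apply_transform(tr2, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  # similarity fit recovers a known scale
  tr3 <- estimate_landmark_transform(src, 1.25 * dst, allow_scale = TRUE)
  expect_equal(tr3$scale, 1.25, tolerance = 1e-6)
})

test_that("rigid transforms preserve lengths and crossing counts", {
  set.seed(9)
  cs <- random_segments(120)
  ln <- astroborder:::make_lines(runif(8, 20, 80), runif(8, 20, 80),
                                 runif(8, 0, pi), runif(8, 20, 60), "t")
  tr <- structure(list(rotation = 0.7, translation = c(300, -150), scale = 1,
                       rms = 0), class = "rigid_transform")
  cs2 <- apply_transform(tr, cs)
  ln2 <- apply_transform(tr, ln)
  # isometry: every polyline length preserved within 1e-9 relative
  expect_equal(total_length(cs2), total_length(cs),
               tolerance = 1e-9)
  expect_equal(ln2$length, ln$length, tolerance = 1e-9)
  # joint transform leaves counts exactly unchanged
  expect_identical(count_line_crossings(ln2, cs2)$count,
                   count_line_crossings(ln, cs)$count)
  # identity transform leaves objects unchanged
  id <- structure(list(rotation = 0, translation = c(0, 0), scale = 1,
                       rms = 0), class = "rigid_transform")
  expect_equal(apply_transform(id, cs)$xy, cs$xy)
})
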