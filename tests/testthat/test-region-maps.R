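# Region map layouts: partition invariants, labels, and parameter checks.

test_that("barrel maps partition the extent with labeled cores", {
  m <- sample_barrel_map(5, 5, seed = 2)
  expect_equal(sum(vapply(m$polygons, function(p) p$class == "core", TRUE)),
               25L)
  labs <- vapply(Filter(function(p) p$class == "core", m$polygons),
                 `[[`, "", "id")
  expect_setequal(labs, as.vector(outer(LETTERS[1:5], 1:5, paste0)))
  # partition conservation: class areas sum to the extent area
  expect_equal(sum(region_areas(m)),
               diff(m$extent[1:2]) * diff(m$extent[3:4]),
               tolerance = 1e-6)
  # every sampled point belongs to exactly one class, never "outside"
  set.seed(1)
  xy <- cbind(runif(500, m$extent[1], m$extent[2]),
              runif(500, m$extent[3], m$extent[4]))
  expect_true(all(classify_points(m, xy) %in%
                    c("core", "septum", "background")))
  # Monte-Carlo area agreement per class (loose 3-sigma binomial bound)
  cls <- classify_points(m, xy)
  frac <- mean(cls == "core")
  want <- m$areas$core / sum(unlist(m$areas))
  expect_lt(abs(frac - want), 3 * sqrt(want * (1 - want) / 500))
})

test_that("a 1x1 barrel map is one core inside a septal ring", {
  m <- sample_barrel_map(1, 1, core_span = 400, septum_width = 60, seed = 1)
  cores <- Filter(function(p) p$class == "core", m$polygons)
  expect_length(cores, 1L)
  ctr <- colMeans(cores[[1]]$outer)
  expect_identical(classify_points(m, rbind(ctr)), "core")
  # septum of the stated width on every side of the core
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    just_out <- ctr + d * (200 + 30)
    expect_identical(classify_points(m, rbind(just_out)), "septum")
    beyond <- ctr + d * (200 + 61)
    expect_identical(classify_points(m, rbind(beyond)), "background")
  }
})

test_that("geometry parameters are validated", {
  expect_error(sample_barrel_map(0, 3), "rows")
  expect_error(sample_barrel_map(2, 2, core_span = -5), "non-positive")
  expect_error(sample_barrel_map(2, 2, septum_width = 0), "non-positive")
  expect_error(sample_area_map("A1_in_A2", list(radius = -1)), "positive")
  expect_error(sample_area_map("blob_interblob",
                               list(period = 300, blob_rx = 160)),
               "diameter")
})

test_that("area maps realize their stated geometry", {
  # disc-in-surround: radius honored on both sides of the border
  m <- sample_area_map("A1_in_A2", list(radius = 750))
  expect_identical(classify_points(m, rbind(c(0, 0), c(749, 0), c(751, 0))),
                   c("A1", "A1", "A2"))
  expect_equal(m$areas$A1, pi * 750^2)
  # laminar: border at y = 0 splits the classes by sign of y
  m <- sample_area_map("laminar_IIIa_IIIb", list(width = 2000, height = 800))
  set.seed(3)
  xy <- cbind(runif(200, 0, 2000), runif(200, -400, 400))
  cls <- classify_points(m, xy)
  expect_true(all(cls[xy[, 2] > 0] == "IIIa"))
  expect_true(all(cls[xy[, 2] < 0] == "IIIb"))
  # blobs: 5 centers at the stated 1 mm period
  m <- sample_area_map("blob_interblob", list(period = 1000, n_blobs = 5))
  expect_equal(m$layout$centers, c(500, 1500, 2500, 3500, 4500))
  expect_identical(classify_points(m, rbind(c(500, 0), c(1000, 0))),
                   c("blob", "interblob"))
})

test_that("maps are reproducible for a fixed seed", {
  a <- sample_barrel_map(3, 3, seed = 11)
  b <- sample_barrel_map(3, 3, seed = 11)
  expect_identical(a$layout$spans_w, b$layout$spans_w)
  expect_identical(a$extent, b$extent)
})
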