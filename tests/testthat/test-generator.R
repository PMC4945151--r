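# Synthetic morphology: confinement, stereology identities, thinning,
# calibration inversion, rasterization, determinism.

lam_map <- function(w = 2000, h = 2000)
  sample_area_map("laminar_IIIa_IIIb", list(width = w, height = h))

test_that("p_cross = 0 confines every branch to its class", {
  m <- lam_map()
  cfg <- generator_config(fiber_density = c(IIIa = 0.06, IIIb = 0.06),
                          p_cross = 0)
  a <- grow_astrocyte_arbors(m, cfg, seed = 21)
  seg <- curve_segments(a)
  # no segment straddles the y = 0 border (touching endpoints allowed)
  straddle <- sign(seg[, "y0"]) * sign(seg[, "y1"]) < 0 &
    pmin(abs(seg[, "y0"]), abs(seg[, "y1"])) > 1e-9
  expect_identical(sum(straddle), 0L)
  # and all vertices stay inside the extent
  expect_true(all(a$xy[, 1] >= m$extent[1] & a$xy[, 1] <= m$extent[2] &
                    a$xy[, 2] >= m$extent[3] & a$xy[, 2] <= m$extent[4]))
})

test_that("p_cross = 1 makes border lines indistinguishable from interior", {
  m <- lam_map()
  cfg <- generator_config(fiber_density = c(IIIa = 0.05, IIIb = 0.05),
                          p_cross = 1)
  border <- astroborder:::make_lines(1000, 0, 0, 300, "border")
  interior <- astroborder:::make_lines(1000, 600, 0, 300, "interior")
  db <- di <- numeric(50)
  for (s in 1:50) {
    a <- grow_astrocyte_arbors(m, cfg, seed = 300 + s)
    db[s] <- count_line_crossings(border, a)$count
    di[s] <- count_line_crossings(interior, a)$count
  }
  se <- sqrt(var(db) / 50 + var(di) / 50)
  expect_lt(abs(mean(db) - mean(di)), 3 * se)
})

test_that("interior line crossings obey the 2*L*rho/pi identity (arbors)", {
  m <- lam_map()
  cfg <- generator_config(fiber_density = c(IIIa = 0.05, IIIb = 0.05),
                          p_cross = 0)
  ln <- astroborder:::make_lines(1000, 600, 0.4, 300, "t")
  cnt <- numeric(100); rho <- numeric(100)
  for (s in 1:100) {
    a <- grow_astrocyte_arbors(m, cfg, seed = 500 + s)
    cnt[s] <- count_line_crossings(ln, a)$count
    # realized length density in a window around the line, inside IIIa
    seg <- curve_segments(a)
    mx <- (seg[, "x0"] + seg[, "x1"]) / 2
    my <- (seg[, "y0"] + seg[, "y1"]) / 2
    inwin <- mx > 700 & mx < 1300 & my > 300 & my < 900
    rho[s] <- sum(sqrt((seg[inwin, "x1"] - seg[inwin, "x0"])^2 +
                         (seg[inwin, "y1"] - seg[inwin, "y0"])^2)) /
      (600 * 600)
  }
  expected <- 2 * 300 * mean(rho) / pi
  expect_lt(abs(mean(cnt) - expected), 3 * sd(cnt) / sqrt(100))
})

test_that("capillary process matches the stereology closed form exactly", {
  m <- lam_map()
  rho <- 0.04
  ln <- astroborder:::make_lines(1000, 300, pi / 5, 400, "t")
  cnt <- numeric(80)
  for (s in 1:80) {
    cap <- sample_capillary_network(m, rho, seed = s)
    cnt[s] <- count_line_crossings(ln, cap)$count
  }
  expect_lt(abs(mean(cnt) - 2 * 400 * rho / pi), 3 * sd(cnt) / sqrt(80))
})

test_that("capillaries ignore borders: septal vs core crossing ratio is 1", {
  sep_cnt <- core_cnt <- numeric(60)
  for (s in 1:60) {
    m <- sample_barrel_map(2, 2, seed = s)
    cap <- sample_capillary_network(m, 0.05, seed = 1000 + s)
    ln <- place_septal_and_core_lines(m)
    tab <- count_line_crossings(ln, cap)
    sep_cnt[s] <- mean(tab$count[tab$class == "septal"])
    core_cnt[s] <- mean(tab$count[tab$class == "core"])
  }
  ratio <- mean(sep_cnt) / mean(core_cnt)
  # delta-method s.e. of the ratio of means
  se <- ratio * sqrt(var(sep_cnt) / 60 / mean(sep_cnt)^2 +
                       var(core_cnt) / 60 / mean(core_cnt)^2)
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("degenerate generator inputs behave per contract", {
  m <- lam_map()
  expect_identical(n_curves(sample_capillary_network(m, 0, seed = 1)), 0L)
  expect_error(generator_config(step_length = -1), "step_length")
  expect_error(generator_config(p_cross = 1.2), "p_cross")
  expect_error(generator_config(retention = 0), "retention")
  expect_error(sample_capillary_network(m, -0.1), "length_density")
  # zero soma intensity -> empty curve set, not an error
  cfg <- generator_config(soma_intensity = c(IIIa = 0))
  expect_identical(n_curves(grow_astrocyte_arbors(m, cfg, 1)), 0L)
})

test_that("thinning is per-polyline Bernoulli with preserved tags", {
  m <- lam_map()
  cfg <- generator_config(fiber_density = c(IIIa = 0.03, IIIb = 0.03))
  a <- grow_astrocyte_arbors(m, cfg, seed = 9)
  expect_identical(thin_by_section(a, 1, seed = 1), a)
  expect_error(thin_by_section(a, 0, seed = 1), "retention")
  kept <- vapply(1:40, function(s)
    n_curves(thin_by_section(a, 0.65, seed = s)), 0L)
  n <- n_curves(a)
  # binomial expectation at 3 sigma
  expect_lt(abs(mean(kept) - 0.65 * n),
            3 * sqrt(n * 0.65 * 0.35 / 40))
  # subset property: every retained polyline is one of the originals
  th <- thin_by_section(a, 0.65, seed = 3)
  expect_true(all(th$xy %in% a$xy))
  expect_lte(n_curves(th), n)
})

test_that("calibrate_generator inverts the crossing identity", {
  expect_identical(calibrate_generator(0, 375), 0)
  expect_equal(calibrate_generator(6, 375), 2 * calibrate_generator(3, 375))
  expect_error(calibrate_generator(-1, 375), "unattainable")
  expect_error(calibrate_generator(3, 0), "line length")
  # inversion recovered by simulation: calibrate, simulate, re-measure
  m <- lam_map()
  target <- 5; L <- 300
  rho <- calibrate_generator(target, L)
  ln <- astroborder:::make_lines(1000, 500, 1.1, L, "t")
  cnt <- numeric(100)
  for (s in 1:100) {
    cap <- sample_capillary_network(m, rho, seed = 7000 + s)
    cnt[s] <- count_line_crossings(ln, cap)$count
  }
  expect_lt(abs(mean(cnt) - target), 3 * sd(cnt) / sqrt(100))
})

test_that("a zero extent yields an empty curve set, not an error", {
  m0 <- astroborder:::new_region_map(
    list(), extent = c(0, 0, 0, 0),
    classify = function(x, y) rep("outside", length(x)),
    areas = list(), layout = list(type = "degenerate"))
  cfg <- generator_config(soma_intensity = c(core = 1e-3))
  expect_identical(n_curves(grow_astrocyte_arbors(m0, cfg, 1)), 0L)
})

test_that("scenes serialize deterministically and rasterize consistently", {
  m <- sample_barrel_map(2, 2, seed = 5)
  cfg <- generator_config(fiber_density = c(core = 0.02, septum = 0.01),
                          capillary_density = 0.01, seed = 5)
  s1 <- synth_scene(m, cfg)
  s2 <- synth_scene(m, cfg)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_scene_geojson(s1, f1); write_scene_geojson(s2, f2)
  expect_identical(readLines(f1), readLines(f2))  # bit-for-bit determinism
  expect_gte(nrow(s1$landmarks), 4L)

  r <- rasterize_scene(s1, pixel_size_um = 5)
  expect_error(rasterize_scene(s1, 1e9), "extent")
  expect_error(rasterize_scene(s1, 0), "positive")
  # foreground pixels ~ fiber length * stroke / pixel area (sparse scene)
  px <- sum(r$astro)
  expect_lt(abs(px - total_length(s1$astro) / 5) / px, 0.15)
  # landmark um -> px -> um roundtrip within one pixel
  back <- landmarks_px_to_um(r$landmarks_px, r)
  expect_lt(max(abs(back - s1$landmarks)), 5)
  # empty scene -> all-background raster
  empty <- synth_scene(m, generator_config(soma_intensity = c(core = 0)))
  r0 <- rasterize_scene(empty, 10)
  expect_identical(sum(r0$astro) + sum(r0$capillary), 0L)
})
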