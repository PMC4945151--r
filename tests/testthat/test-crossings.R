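# Crossing counts against the brute-force oracle, density profiles,
# percent drops, ratios and CO pairing.

test_that("count_line_crossings matches the brute-force oracle exactly", {
  set.seed(123)
  for (rep in 1:60) {
    cs <- random_segments(sample(5:120, 1))
    nl <- sample(1:10, 1)
    ln <- astroborder:::make_lines(runif(nl, -20, 120), runif(nl, -20, 120),
                                   runif(nl, 0, 2 * pi), runif(nl, 5, 150),
                                   "t")
    expect_identical(count_line_crossings(ln, cs)$count,
                     oracle_count_table(ln, cs))
  }
})

test_that("simple crossing cases are exact", {
  # no curves -> all counts zero
  ln <- astroborder:::make_lines(c(10, 20), c(0, 0), c(0, 0), 10, "t")
  expect_identical(count_line_crossings(ln, empty_curve_set())$count,
                   c(0L, 0L))
  # one perpendicular segment through the midpoint -> exactly 1
  seg1 <- new_curve_set(rbind(c(10, -5), c(10, 5)), c(1L, 1L), 1L, "t")
  one <- astroborder:::make_lines(10, 0, 0, 10, "t")
  expect_identical(count_line_crossings(one, seg1)$count, 1L)
  # a zig-zag crossing twice counts twice; dedupe counts the curve once
  zig <- new_curve_set(rbind(c(8, -3), c(9, 3), c(10, -3)), rep(1L, 3), 1L,
                       "t")
  expect_identical(count_line_crossings(one, zig)$count, 2L)
  expect_identical(count_line_crossings(one, zig,
                                        dedupe_per_curve = TRUE)$count, 1L)
  # empty line set -> empty table
  expect_identical(nrow(count_line_crossings(
    astroborder:::make_lines(numeric(0), numeric(0), numeric(0),
                             numeric(0), character(0)), seg1)), 0L)
})

test_that("counts are invariant under vertex re-densification", {
  set.seed(5)
  # random polyline; split every segment in two without moving the curve
  v <- cbind(cumsum(rnorm(15, 2)), cumsum(rnorm(15))) * 8
  mids <- (v[-1, ] + v[-nrow(v), ]) / 2
  dense <- matrix(0, nrow = 29, ncol = 2)
  dense[seq(1, 29, 2), ] <- v
  dense[seq(2, 28, 2), ] <- mids
  c1 <- new_curve_set(v, rep(1L, 15), 1L, "t")
  c2 <- new_curve_set(dense, rep(1L, 29), 1L, "t")
  ln <- astroborder:::make_lines(runif(6, 0, 100), runif(6, -20, 20),
                                 runif(6, 0, pi), runif(6, 30, 90), "t")
  expect_identical(count_line_crossings(ln, c1)$count,
                   count_line_crossings(ln, c2)$count)
})

test_that("band density profiles conserve clipped fiber length", {
  band <- data.frame(band = 1, cx = 0, cy = 0, nx = 0, ny = 1, tx = 1,
                     ty = 0, width = 25, length = 100)
  # empty curves -> all-zero profile on the right grid
  p0 <- band_density_profile(band, empty_curve_set())
  expect_identical(nrow(p0), 100L)
  expect_true(all(p0$density == 0))
  expect_true(all(diff(p0$position) > 0))
  expect_error(band_density_profile(band, empty_curve_set(), step = 0),
               "step")
  # one fiber running the band's full length along the axis: density 1/w
  fib <- new_curve_set(rbind(c(0, -60), c(0, 60)), c(1L, 1L), 1L, "t")
  p1 <- band_density_profile(band, fib)
  expect_equal(p1$density, rep(1 / 25, 100), tolerance = 1e-9)
  # length conservation on random clutter: sum(density * slab area) equals
  # the total clipped length
  set.seed(77)
  cs <- random_segments(300, -80, 80)
  p <- band_density_profile(band, cs)
  got <- sum(p$density * attr(p, "slab_area"))
  seg <- curve_segments(cs)
  cl <- astroborder:::clip_segments_rect(seg[, "y0"], seg[, "x0"],
                                         seg[, "y1"], seg[, "x1"],
                                         c(-50, 50, -12.5, 12.5))
  want <- sum(sqrt((cl$x1 - cl$x0)^2 + (cl$y1 - cl$y0)^2)[cl$keep])
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("profile aggregation is a pointwise mean with flag", {
  band <- data.frame(band = 1, cx = 0, cy = 0, nx = 0, ny = 1, tx = 1,
                     ty = 0, width = 20, length = 50)
  a <- band_density_profile(band, new_curve_set(rbind(c(0, -30), c(0, 30)),
                                                c(1L, 1L), 1L, "t"))
  b <- band_density_profile(band, empty_curve_set())
  ag <- aggregate_profiles(list(a, b))
  expect_true(attr(ag, "aggregate"))
  expect_equal(ag$density, a$density / 2)
  expect_equal(aggregate_profiles(list(a))$density, a$density)
  # permutation invariance
  expect_equal(aggregate_profiles(list(b, a))$density, ag$density)
  bad <- band_density_profile(band, empty_curve_set(), step = 2)
  expect_error(aggregate_profiles(list(a, bad)), "mismatched")
})

test_that("percent_drop arithmetic and signalling", {
  flat <- data.frame(position = seq(-49.5, 49.5, 1), density = 1)
  expect_equal(percent_drop(flat), 0)
  stepped <- flat
  stepped$density <- ifelse(stepped$position < 0, 2, 1)
  expect_equal(percent_drop(stepped), 50)
  expect_error(percent_drop(flat, c(-50, 20), c(10, 50)), "opposite")
  zero <- flat; zero$density <- 0
  expect_error(percent_drop(zero), "zero")
})

test_that("a calibrated 0.63x outer density yields a ~37% drop", {
  m <- sample_area_map("laminar_IIIa_IIIb", list(width = 2500, height = 900))
  b <- find_region_border(m, c("IIIa", "IIIb"))
  bands <- place_density_bands(b, width = 25, length = 100, count = 10,
                               region_map = m, inner_class = "IIIa")
  cfg <- generator_config(fiber_density = c(IIIa = 0.06,
                                            IIIb = 0.06 * 0.63),
                          p_cross = 0)
  drops <- numeric(50)
  for (s in 1:50) {
    a <- grow_astrocyte_arbors(m, cfg, seed = 4200 + s)
    profs <- lapply(seq_len(nrow(bands)), function(k)
      band_density_profile(bands[k, ], a))
    drops[s] <- percent_drop(aggregate_profiles(profs))
  }
  expect_lt(abs(mean(drops) - 37), 3 * sd(drops) / sqrt(50))
})

test_that("septa/core ratio definitions behave", {
  tab <- data.frame(id = 1:8, class = rep(c("septal", "core"), each = 4),
                    pair_key = rep(paste0("p", 1:4), 2),
                    count = c(2, 4, 6, 8, 2, 4, 6, 8))
  expect_equal(septa_core_ratio(tab)$ratio, 1)
  expect_equal(septa_core_ratio(tab, "mean_of_ratios")$ratio, 1)
  tab$count[tab$class == "septal"] <- 0
  expect_equal(septa_core_ratio(tab)$ratio, 0)
  expect_error(septa_core_ratio(tab[tab$class == "core", ]), "pairs")
  # zero-denominator pairs are excluded and counted
  tab2 <- data.frame(id = 1:4, class = rep(c("septal", "core"), each = 2),
                     pair_key = rep(c("a", "b"), 2), count = c(3, 5, 0, 5))
  r <- septa_core_ratio(tab2, "mean_of_ratios")
  expect_identical(r$n_pairs_dropped, 1L)
  expect_equal(r$ratio, 1)
})

test_that("Poisson counts at the published layer-IV means give ratio 0.343", {
  # oracle: direct arithmetic 3.78 / 11.02 = 0.343; simulation recovers it
  set.seed(8)
  reps <- 200
  r <- numeric(reps)
  for (i in 1:reps) {
    tab <- data.frame(id = 1:80,
                      class = rep(c("septal", "core"), each = 40),
                      pair_key = rep(paste0("p", 1:40), 2),
                      count = c(rpois(40, 3.78), rpois(40, 11.02)))
    r[i] <- septa_core_ratio(tab)$ratio
  }
  expect_lt(abs(mean(r) - 3.78 / 11.02), 3 * sd(r) / sqrt(reps))
})

test_that("co_density_series aligns, flags and rejects correctly", {
  # identical series on one grid -> r = 1 exactly downstream
  co <- data.frame(position = 0:100, value = sin(0:100 / 10))
  s <- co_density_series(co, data.frame(position = 0:100,
                                        density = sin(0:100 / 10)))
  expect_false(attr(s, "constant_flag"))
  expect_equal(pearson_r(s$co, s$astro)$statistic, 1, tolerance = 1e-9)
  # resampling onto the overlap grid keeps near-identical series aligned
  astro <- data.frame(position = seq(0, 100, 0.5),
                      density = sin(seq(0, 100, 0.5) / 10))
  s2 <- co_density_series(co, astro)
  expect_gt(pearson_r(s2$co, s2$astro)$statistic, 0.9999)
  flat <- data.frame(position = 0:100, value = 1)
  expect_true(attr(co_density_series(flat, astro), "constant_flag"))
  far <- data.frame(position = 200:300, value = 1:101)
  expect_error(co_density_series(far, data.frame(position = 0:100,
                                                 density = 1:101)),
               "non-overlapping")
  # sinusoidal CO at a 1 mm period, in-phase astrocyte density: positive r
  x <- seq(0, 3000, 10)
  co2 <- data.frame(position = x, value = 1 + 0.5 * sin(2 * pi * x / 1000))
  as2 <- data.frame(position = x,
                    density = 2 + sin(2 * pi * x / 1000) + 0)
  s2 <- co_density_series(co2, as2)
  expect_gt(pearson_r(s2$co, s2$astro)$statistic, 0.9)
})
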