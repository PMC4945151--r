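# Synthetic morphology generator: boundary-confined astrocyte arbors grown
# as persistent random walks, unconfined capillary beds as isotropic Poisson
# segment processes, section-thickness thinning, and full scenes with
# landmarks.
#
# Model summary. Somata are placed by a homogeneous Poisson point process
# with a per-class intensity (count/um^2). Each soma emits Poisson-many
# branches; a branch is a persistent random walk (fixed step, Gaussian
# turning) of exponentially distributed total length. Whenever a step
# changes region class it attempts a border crossing: with probability
# p_cross the step is accepted and growth continues, otherwise the branch
# terminates exactly at the border (processes "abruptly stop" at borders
# rather than reflecting). Leaving the field extent always terminates.

#' Build and validate a generator configuration
#'
#' @param soma_intensity named numeric, somata per um^2 per region class
#'   (classes not named get 0); or a single unnamed number applied to every
#'   class of the map it is used with.
#' @param branches_per_soma mean branch count per soma (Poisson).
#' @param step_length random-walk step in um (> 0).
#' @param turning_sd per-step Gaussian turning spread, radians.
#' @param branch_length_mean mean branch arclength, um (exponential).
#' @param fiber_density optional named numeric, target fiber length density
#'   per class (um/um^2); converted to `soma_intensity` via
#'   `density / (branches_per_soma * branch_length_mean)`.
#' @param p_cross border crossing probability in \[0, 1\].
#' @param capillary_density capillary length density (um/um^2), scalar
#'   (homogeneous) or named per class.
#' @param capillary_segment_length capillary segment length, um.
#' @param retention section retention probability in (0, 1\].
#' @param n_landmarks number of penetrating-arteriole landmarks per scene.
#' @param seed integer root seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(soma_intensity = c(core = 1e-4),
                             branches_per_soma = 5,
                             step_length = 5,
                             turning_sd = 0.3,
                             branch_length_mean = 60,
                             fiber_density = NULL,
                             p_cross = 0,
                             capillary_density = 0,
                             capillary_segment_length = 25,
                             retention = 1,
                             n_landmarks = 6L,
                             seed = 1L) {
  if (!is.null(fiber_density)) {
    if (any(fiber_density < 0)) stop("fiber densities must be >= 0")
    soma_intensity <- fiber_density / (branches_per_soma * branch_length_mean)
  }
  if (any(soma_intensity < 0)) stop("soma intensities must be >= 0")
  if (step_length <= 0) stop("step_length must be positive")
  if (turning_sd < 0) stop("turning_sd must be >= 0")
  if (branch_length_mean <= 0) stop("branch_length_mean must be positive")
  if (p_cross < 0 || p_cross > 1) stop("p_cross must lie in [0, 1]")
  if (any(capillary_density < 0)) stop("capillary_density must be >= 0")
  if (capillary_segment_length <= 0)
    stop("capillary_segment_length must be positive")
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  structure(list(soma_intensity = soma_intensity,
                 branches_per_soma = branches_per_soma,
                 step_length = step_length, turning_sd = turning_sd,
                 branch_length_mean = branch_length_mean,
                 p_cross = p_cross,
                 capillary_density = capillary_density,
                 capillary_segment_length = capillary_segment_length,
                 retention = retention, n_landmarks = as.integer(n_landmarks),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Uniform points inside one class of a region map (rejection from the
# extent). Draws from the current RNG stream; the loop is deterministic
# given that stream.
sample_points_in_class <- function(map, cls, n) {
  ext <- map$extent
  out <- matrix(numeric(0), ncol = 2)
  if (n == 0L) return(out)
  area_ext <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  frac <- max(unlist(map$areas[cls]) / area_ext, 1e-3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac * 1.2) + 16L
    x <- runif(m, ext[1], ext[2])
    y <- runif(m, ext[3], ext[4])
    ok <- map$classify(x, y) == cls
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# Resolve a (possibly scalar / partially named) per-class parameter against
# the classes of a map; unnamed scalar is replicated over all classes.
per_class_values <- function(v, map, exclude_background = TRUE) {
  classes <- unique(vapply(map$polygons, `[[`, "", "class"))
  if (exclude_background) classes <- setdiff(classes, "background")
  if (is.null(names(v)) && length(v) == 1L) {
    out <- rep(as.numeric(v), length(classes))
    names(out) <- classes
    return(out)
  }
  out <- stats::setNames(rep(0, length(classes)), classes)
  common <- intersect(names(v), classes)
  out[common] <- v[common]
  out
}

#' Grow boundary-confined astrocyte arbors
#'
#' Somata are placed per class by a homogeneous Poisson process; each soma
#' emits `Poisson(branches_per_soma)` branches grown as persistent random
#' walks. A step that changes region class (or exits the extent) is a border
#' crossing attempt: it succeeds with probability `config$p_cross`
#' (extent exits never succeed); on failure the branch is truncated exactly
#' at the border and terminates.
#'
#' @param region_map a `region_map`.
#' @param config a `generator_config`.
#' @param seed integer seed; overrides `config$seed` when given.
#' @return a `curve_set` of branch polylines tagged with soma ids.
#' @export
grow_astrocyte_arbors <- function(region_map, config, seed = config$seed) {
  stopifnot(inherits(region_map, "region_map"),
            inherits(config, "generator_config"))
  ext <- region_map$extent
  if ((ext[2] - ext[1]) <= 0 || (ext[4] - ext[3]) <= 0)
    return(empty_curve_set("astrocyte"))
  lam <- per_class_values(config$soma_intensity, region_map)
  somata <- with_seed(derive_seed(seed, "somata"), {
    pts <- matrix(numeric(0), ncol = 2)
    for (cl in names(lam)) {
      if (lam[[cl]] <= 0) next
      n <- stats::rpois(1, lam[[cl]] * region_map$areas[[cl]])
      if (n > 0) pts <- rbind(pts, sample_points_in_class(region_map, cl, n))
    }
    pts
  })
  ns <- nrow(somata)
  if (ns == 0L) return(empty_curve_set("astrocyte"))

  with_seed(derive_seed(seed, "branches"), {
    nb <- stats::rpois(ns, config$branches_per_soma)
    soma_of_branch <- rep(seq_len(ns), nb)
    nbr <- length(soma_of_branch)
    if (nbr == 0L) {
      empty_curve_set("astrocyte")
    } else {
    len <- stats::rexp(nbr, rate = 1 / config$branch_length_mean)
    sl <- config$step_length
    nstep <- pmax(1L, as.integer(ceiling(len / sl)))
    last_len <- len - (nstep - 1L) * sl
    last_len[last_len <= 0] <- sl
    total <- sum(nstep)
    branch_of_step <- rep(seq_len(nbr), nstep)
    within <- sequence(nstep)
    # headings: absolute initial angle, then cumulative Gaussian turns
    turn <- stats::rnorm(total, 0, config$turning_sd)
    turn[within == 1L] <- stats::runif(nbr, 0, 2 * pi)
    ang <- grouped_cumsum(turn, nstep)
    steplen <- ifelse(within == nstep[branch_of_step], last_len[branch_of_step],
                      sl)
    dx <- steplen * cos(ang)
    dy <- steplen * sin(ang)
    px <- somata[soma_of_branch, 1][branch_of_step] + grouped_cumsum(dx, nstep)
    py <- somata[soma_of_branch, 2][branch_of_step] + grouped_cumsum(dy, nstep)

    # long-form vertices: soma vertex then step endpoints, per branch
    nv <- nstep + 1L
    starts <- cumsum(nv) - nv + 1L
    vx <- numeric(sum(nv)); vy <- numeric(sum(nv))
    vx[starts] <- somata[soma_of_branch, 1]
    vy[starts] <- somata[soma_of_branch, 2]
    vx[-starts] <- px
    vy[-starts] <- py
    vcls <- region_map$classify(vx, vy)

    # border-crossing events per step: class change or extent exit
    i0 <- seq_along(vx)[-cumsum(nv)]           # step start vertices
    c0 <- vcls[i0]; c1 <- vcls[i0 + 1L]
    event <- c0 != c1
    u <- stats::runif(total)
    fail <- event & (u >= config$p_cross | c1 == "outside")

    keepn <- nv  # vertices kept per branch
    trunc_at <- rep(NA_integer_, nbr)
    if (any(fail)) {
      f <- which(fail)
      first <- !duplicated(branch_of_step[f])
      f <- f[first]
      b <- branch_of_step[f]
      trunc_at[b] <- within[f]        # step index of first failed crossing
      keepn[b] <- within[f] + 1L
      # bisection for the crossing point on each failed step
      ax <- vx[i0[f]]; ay <- vy[i0[f]]
      bx <- vx[i0[f] + 1L]; by <- vy[i0[f] + 1L]
      cls_in <- vcls[i0[f]]
      tlo <- rep(0, length(f)); thi <- rep(1, length(f))
      for (it in 1:40) {
        tm <- (tlo + thi) / 2
        inside <- region_map$classify(ax + tm * (bx - ax),
                                      ay + tm * (by - ay)) == cls_in
        tlo[inside] <- tm[inside]
        thi[!inside] <- tm[!inside]
      }
      # use the last parameter known to lie on the inside, so the endpoint
      # stays within the origin class (and the extent) to machine precision
      cross_x <- ax + tlo * (bx - ax)
      cross_y <- ay + tlo * (by - ay)
      # overwrite the (to-be-last) vertex with the border point
      last_vid <- starts[b] + keepn[b] - 1L
      vx[last_vid] <- cross_x
      vy[last_vid] <- cross_y
    }
    keep <- sequence(nv) <= keepn[rep(seq_len(nbr), nv)]
    new_curve_set(cbind(vx[keep], vy[keep]),
                  rep(seq_len(nbr), keepn),
                  soma_of_branch, "astrocyte")
    }
  })
}

#' Sample an unconfined capillary bed
#'
#' An isotropic Poisson process of straight segments: midpoints uniform
#' (homogeneous for a scalar density, or per class for a named density),
#' orientations uniform, fixed segment length. Segments freely cross region
#' borders (no border interaction) and are clipped only at the field extent.
#' For a test line of length L placed at least half a segment length from
#' any class border, expected crossings are exactly `2 L rho / pi`.
#'
#' @param region_map a `region_map`.
#' @param length_density fiber length density in um/um^2, scalar or named
#'   per class.
#' @param seed integer seed.
#' @param segment_length segment length, um.
#' @return a `curve_set` of two-vertex polylines (kind "capillary").
#' @export
sample_capillary_network <- function(region_map, length_density, seed = 1L,
                                     segment_length = 25) {
  stopifnot(inherits(region_map, "region_map"))
  if (any(length_density < 0)) stop("length_density must be >= 0")
  if (segment_length <= 0) stop("segment_length must be positive")
  ext <- region_map$extent
  homogeneous <- is.null(names(length_density)) && length(length_density) == 1L
  with_seed(derive_seed(seed, "capillaries"), {
    mids <- matrix(numeric(0), ncol = 2)
    if (homogeneous) {
      area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
      n <- stats::rpois(1, as.numeric(length_density) * area / segment_length)
      if (n > 0) mids <- cbind(runif(n, ext[1], ext[2]),
                               runif(n, ext[3], ext[4]))
    } else {
      dens <- per_class_values(length_density, region_map,
                               exclude_background = FALSE)
      for (cl in names(dens)) {
        if (dens[[cl]] <= 0) next
        n <- stats::rpois(1, dens[[cl]] * region_map$areas[[cl]] /
                            segment_length)
        if (n > 0) mids <- rbind(mids, sample_points_in_class(region_map, cl, n))
      }
    }
    n <- nrow(mids)
    if (n == 0L) {
      empty_curve_set("capillary")
    } else {
      th <- runif(n, 0, pi)  # undirected orientation
      hx <- segment_length / 2 * cos(th)
      hy <- segment_length / 2 * sin(th)
      x0 <- mids[, 1] - hx; y0 <- mids[, 2] - hy
      x1 <- mids[, 1] + hx; y1 <- mids[, 2] + hy
      # clip to the extent (both endpoints; segments stay straight)
      cl <- clip_segments_rect(x0, y0, x1, y1, ext)
      ok <- cl$keep
      m <- sum(ok)
      if (m == 0L) {
        empty_curve_set("capillary")
      } else {
        xy <- matrix(0, nrow = 2L * m, ncol = 2)
        xy[seq(1, 2 * m, by = 2), ] <- cbind(cl$x0[ok], cl$y0[ok])
        xy[seq(2, 2 * m, by = 2), ] <- cbind(cl$x1[ok], cl$y1[ok])
        new_curve_set(xy, rep(seq_len(m), each = 2), seq_len(m), "capillary")
      }
    }
  })
}

# Liang-Barsky clipping of segments to a rectangle c(xmin,xmax,ymin,ymax);
# vectorized over segments.
clip_segments_rect <- function(x0, y0, x1, y1, ext) {
  dx <- x1 - x0; dy <- y1 - y0
  t0 <- rep(0, length(x0)); t1 <- rep(1, length(x0))
  keep <- rep(TRUE, length(x0))
  clip1 <- function(p, q) {
    # p * t <= q constraint
    with_p <- p != 0
    t <- ifelse(with_p, q / p, Inf)
    ent <- with_p & p < 0
    exi <- with_p & p > 0
    t0 <<- ifelse(ent, pmax(t0, t), t0)
    t1 <<- ifelse(exi, pmin(t1, t), t1)
    keep <<- keep & !(!with_p & q < 0)
  }
  clip1(-dx, x0 - ext[1])
  clip1(dx, ext[2] - x0)
  clip1(-dy, y0 - ext[3])
  clip1(dy, ext[4] - y0)
  keep <- keep & (t0 < t1)
  list(x0 = x0 + t0 * dx, y0 = y0 + t0 * dy,
       x1 = x0 + t1 * dx, y1 = y0 + t1 * dy, keep = keep)
}

#' Thin a curve set by section retention
#'
#' Models cutting thinner sections as independent retention of whole
#' polylines with the given probability; structure tags are preserved.
#'
#' @param curves a `curve_set`.
#' @param retention retention probability in (0, 1].
#' @param seed integer seed.
#' @return a thinned `curve_set`.
#' @export
thin_by_section <- function(curves, retention, seed = 1L) {
  stopifnot(inherits(curves, "curve_set"))
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  if (retention == 1) return(curves)
  nc <- n_curves(curves)
  if (nc == 0L) return(curves)
  with_seed(derive_seed(seed, "thinning"), {
    keep <- which(stats::runif(nc) < retention)
    subset_curves(curves, sort(unique(curves$curve_id))[keep])
  })
}

#' Generate a full synthetic scene
#'
#' Region map + confined astrocyte arbors + unconfined capillary bed +
#' landmark points, with the generating configuration retained verbatim for
#' recovery tests.
#'
#' @param region_map a `region_map`.
#' @param config a `generator_config`.
#' @param seed integer root seed; overrides `config$seed` when given.
#' @return a `synthetic_scene`.
#' @export
synth_scene <- function(region_map, config, seed = config$seed) {
  astro <- grow_astrocyte_arbors(region_map, config, seed)
  cap <- if (any(config$capillary_density > 0)) {
    sample_capillary_network(region_map, config$capillary_density, seed,
                             config$capillary_segment_length)
  } else empty_curve_set("capillary")
  if (config$retention < 1) {
    astro <- thin_by_section(astro, config$retention,
                             derive_seed(seed, "thin_astro"))
    cap <- thin_by_section(cap, config$retention,
                           derive_seed(seed, "thin_cap"))
  }
  ext <- region_map$extent
  landmarks <- with_seed(derive_seed(seed, "landmarks"), {
    k <- max(4L, config$n_landmarks)
    cbind(x = stats::runif(k, ext[1], ext[2]),
          y = stats::runif(k, ext[3], ext[4]))
  })
  structure(list(region_map = region_map, astro = astro, capillary = cap,
                 landmarks = landmarks, config = config, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %s map, %d astro polylines, %d capillary segments, %d landmarks, seed %d>\n",
              x$region_map$layout$type, n_curves(x$astro),
              n_curves(x$capillary), nrow(x$landmarks), x$seed))
  invisible(x)
}

#' Rasterize a scene to labeled channel matrices
#'
#' Optional bridge towards image-based inputs: a label channel sampled at
#' pixel centers plus binary astrocyte and capillary channels drawn with a
#' one-pixel stroke. Landmarks are exported in pixel units (column, row of
#' the matrix; row 1 is the top of the field).
#'
#' @param scene a `synthetic_scene`.
#' @param pixel_size_um pixel size in um (> 0, smaller than the extent).
#' @return list with `labels` (character matrix), `astro`, `capillary`
#'   (0/1 integer matrices), `landmarks_px` (n x 2), `pixel_size_um`,
#'   `extent`, and `class_levels`.
#' @export
rasterize_scene <- function(scene, pixel_size_um) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ext <- scene$region_map$extent
  w <- ext[2] - ext[1]; h <- ext[4] - ext[3]
  if (pixel_size_um <= 0) stop("pixel size must be positive")
  if (pixel_size_um > min(w, h)) stop("pixel size larger than the extent")
  nc <- max(1L, as.integer(ceiling(w / pixel_size_um)))
  nr <- max(1L, as.integer(ceiling(h / pixel_size_um)))
  xc <- ext[1] + (seq_len(nc) - 0.5) * pixel_size_um
  yc <- ext[4] - (seq_len(nr) - 0.5) * pixel_size_um  # row 1 at the top
  gx <- rep(xc, each = nr)
  gy <- rep(yc, times = nc)
  labels <- matrix(scene$region_map$classify(gx, gy), nrow = nr)

  burn <- function(curves) {
    m <- matrix(0L, nr, nc)
    seg <- curve_segments(curves)
    if (nrow(seg) == 0L) return(m)
    len <- sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2)
    nsub <- pmax(1L, as.integer(ceiling(len / (pixel_size_um / 2))))
    idx <- rep(seq_len(nrow(seg)), nsub + 1L)
    t <- unlist(lapply(nsub, function(k) seq(0, 1, length.out = k + 1L)),
                use.names = FALSE)
    sx <- seg[idx, "x0"] + t * (seg[idx, "x1"] - seg[idx, "x0"])
    sy <- seg[idx, "y0"] + t * (seg[idx, "y1"] - seg[idx, "y0"])
    col <- pmin(pmax(as.integer(floor((sx - ext[1]) / pixel_size_um)) + 1L, 1L), nc)
    row <- pmin(pmax(as.integer(floor((ext[4] - sy) / pixel_size_um)) + 1L, 1L), nr)
    m[unique(cbind(row, col))] <- 1L
    m
  }
  lm_px <- cbind(col = (scene$landmarks[, 1] - ext[1]) / pixel_size_um + 0.5,
                 row = (ext[4] - scene$landmarks[, 2]) / pixel_size_um + 0.5)
  list(labels = labels, astro = burn(scene$astro),
       capillary = burn(scene$capillary), landmarks_px = lm_px,
       pixel_size_um = pixel_size_um, extent = ext,
       class_levels = sort(unique(as.vector(labels))))
}

#' Convert landmark pixel coordinates back to micrometres
#' @param landmarks_px n x 2 matrix (col, row) as produced by
#'   [rasterize_scene()].
#' @param raster the raster list from [rasterize_scene()].
#' @return n x 2 matrix in um.
#' @export
landmarks_px_to_um <- function(landmarks_px, raster) {
  ps <- raster$pixel_size_um; ext <- raster$extent
  cbind(x = ext[1] + (landmarks_px[, 1] - 0.5) * ps,
        y = ext[4] - (landmarks_px[, 2] - 0.5) * ps)
}
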