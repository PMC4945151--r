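# Crossing counts and density profiles. Counting follows the side-change
# rule: an intersection between a polyline edge and the open measurement
# segment is counted iff the polyline changes side of the line's carrier,
# with points exactly on the carrier assigned to the positive half-plane,
# and the intersection parameter strictly inside the open segment. Each
# geometric crossing therefore counts exactly once, including at shared
# polyline vertices; a branch crossing a line twice counts twice.

#' Count process crossings of measurement lines
#'
#' @param lines a `measurement_lines` set.
#' @param curves a `curve_set` in the same coordinate frame (the caller's
#'   contract; mismatched frames cannot be detected).
#' @param dedupe_per_curve count each polyline at most once per line
#'   (default FALSE: crossings, not unique processes).
#' @return a `crossing_table` data frame: one row per line with its labels
#'   and a non-negative `count`.
#' @export
count_line_crossings <- function(lines, curves, dedupe_per_curve = FALSE) {
  stopifnot(inherits(curves, "curve_set"))
  lines <- as.data.frame(lines)
  out <- lines[, intersect(c("id", "class", "side", "offset", "pair_key",
                             "station", "length"), names(lines)),
               drop = FALSE]
  out$count <- rep(0L, nrow(out))
  if (nrow(lines) == 0L) {
    class(out) <- c("crossing_table", "data.frame")
    return(out)
  }
  seg <- curve_segments(curves)
  if (nrow(seg) > 0L) {
    sxmin <- pmin(seg[, "x0"], seg[, "x1"])
    sxmax <- pmax(seg[, "x0"], seg[, "x1"])
    symin <- pmin(seg[, "y0"], seg[, "y1"])
    symax <- pmax(seg[, "y0"], seg[, "y1"])
    # bucket index on x: each segment registered at its sxmin bucket; a
    # query for [lxmin, lxmax] scans buckets from lxmin - bucket_w onward
    xr <- range(sxmin)
    bucket_w <- max(max(sxmax - sxmin), (xr[2] - xr[1]) / 256, 1e-9)
    bk <- as.integer(floor((sxmin - xr[1]) / bucket_w)) + 1L
    nbk <- max(bk)
    ord <- order(bk)
    bstart <- c(1L, cumsum(tabulate(bk, nbk)) + 1L)  # bucket b: ord[bstart[b]..bstart[b+1]-1]
    for (i in seq_len(nrow(lines))) {
      ax <- lines$x0[i]; ay <- lines$y0[i]
      bx <- lines$x1[i]; by <- lines$y1[i]
      lxmin <- min(ax, bx); lxmax <- max(ax, bx)
      lymin <- min(ay, by); lymax <- max(ay, by)
      b0n <- floor((lxmin - bucket_w - xr[1]) / bucket_w) + 1
      b1n <- floor((lxmax - xr[1]) / bucket_w) + 1
      if (is.na(b0n) || is.na(b1n) || b1n < 1 || b0n > nbk) next
      b0 <- as.integer(max(1, b0n)); b1 <- as.integer(min(nbk, b1n))
      if (b1 < b0) next
      cand <- ord[seq.int(bstart[b0], bstart[b1 + 1L] - 1L)]
      cand <- cand[sxmax[cand] >= lxmin & sxmin[cand] <= lxmax &
                     symin[cand] <= lymax & symax[cand] >= lymin]
      if (length(cand) == 0L) next
      dx <- bx - ax; dy <- by - ay
      c0 <- dx * (seg[cand, "y0"] - ay) - dy * (seg[cand, "x0"] - ax)
      c1 <- dx * (seg[cand, "y1"] - ay) - dy * (seg[cand, "x1"] - ax)
      s0 <- c0 >= 0; s1 <- c1 >= 0     # on-carrier points count as positive
      chg <- s0 != s1
      if (!any(chg)) next
      j <- cand[chg]
      ex <- seg[j, "x1"] - seg[j, "x0"]
      ey <- seg[j, "y1"] - seg[j, "y0"]
      den <- dx * ey - dy * ex
      t <- ((seg[j, "x0"] - ax) * ey - (seg[j, "y0"] - ay) * ex) / den
      hit <- t > 0 & t < 1
      if (dedupe_per_curve) {
        out$count[i] <- length(unique(seg[j[hit], "curve"]))
      } else {
        out$count[i] <- sum(hit)
      }
    }
  }
  class(out) <- c("crossing_table", "data.frame")
  out
}

#' Fiber density profile across a density band
#'
#' For each 1-um (by default) slab perpendicular to the band axis, total
#' fiber arclength clipped to the slab across the band width, divided by the
#' slab area (um/um^2). Positions run from -length/2 to +length/2 along the
#' band axis with the border at 0; the inner side is negative by the band's
#' orientation convention.
#'
#' @param band one row of a `density_bands` data frame (or a list with the
#'   same fields).
#' @param curves a `curve_set` in the same frame.
#' @param step slab thickness along the axis, um (> 0).
#' @return a `density_profile` data frame with `position` (slab centers) and
#'   `density`.
#' @export
band_density_profile <- function(band, curves, step = 1) {
  if (step <= 0) stop("step must be positive")
  band <- as.list(band)
  halfL <- band$length / 2; halfW <- band$width / 2
  nbin <- max(1L, as.integer(round(band$length / step)))
  breaks <- seq(-halfL, halfL, length.out = nbin + 1L)
  dens <- numeric(nbin)
  seg <- curve_segments(curves)
  if (nrow(seg) > 0L) {
    # band coordinates: u along the axis (normal), v along the border tangent
    ux <- band$nx; uy <- band$ny
    vx <- band$tx; vy <- band$ty
    r0x <- seg[, "x0"] - band$cx; r0y <- seg[, "y0"] - band$cy
    r1x <- seg[, "x1"] - band$cx; r1y <- seg[, "y1"] - band$cy
    u0 <- r0x * ux + r0y * uy; v0 <- r0x * vx + r0y * vy
    u1 <- r1x * ux + r1y * uy; v1 <- r1x * vx + r1y * vy
    cl <- clip_segments_rect(u0, v0, u1, v1, c(-halfL, halfL, -halfW, halfW))
    k <- which(cl$keep)
    if (length(k) > 0L) {
      a <- cl$x0[k]; b <- cl$x1[k]
      va <- cl$y0[k]; vb <- cl$y1[k]
      slen <- sqrt((b - a)^2 + (vb - va)^2)
      lo <- pmin(a, b); hi <- pmax(a, b)
      du <- hi - lo
      for (m in seq_along(k)) {
        if (du[m] < 1e-12) {
          # (near-)parallel to the border: all length in one slab
          bin <- min(max(findInterval(lo[m], breaks, rightmost.closed = TRUE),
                         1L), nbin)
          dens[bin] <- dens[bin] + slen[m]
        } else {
          b0 <- min(max(findInterval(lo[m], breaks, rightmost.closed = TRUE),
                        1L), nbin)
          b1 <- min(max(findInterval(hi[m], breaks, rightmost.closed = TRUE),
                        1L), nbin)
          for (bin in b0:b1) {
            ov <- min(hi[m], breaks[bin + 1L]) - max(lo[m], breaks[bin])
            if (ov > 0) dens[bin] <- dens[bin] + slen[m] * ov / du[m]
          }
        }
      }
    }
  }
  widths <- diff(breaks)
  out <- data.frame(position = (breaks[-1] + breaks[-(nbin + 1L)]) / 2,
                    density = dens / (widths * band$width))
  attr(out, "band") <- band$band %||% NA
  attr(out, "aggregate") <- FALSE
  attr(out, "slab_area") <- widths * band$width
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Pointwise mean of density profiles
#'
#' @param profiles list of `density_profile`s on the same station grid.
#' @return the aggregate `density_profile` (aggregate flag set).
#' @export
aggregate_profiles <- function(profiles) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  pos <- profiles[[1]]$position
  for (p in profiles)
    if (length(p$position) != length(pos) ||
        any(abs(p$position - pos) > 1e-9))
      stop("profiles are on mismatched station grids")
  dens <- rowMeans(do.call(cbind, lapply(profiles, `[[`, "density")))
  out <- data.frame(position = pos, density = dens)
  attr(out, "aggregate") <- TRUE
  attr(out, "n") <- length(profiles)
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Percent density drop across a border
#'
#' `100 * (1 - mean(outer) / mean(inner))` over two windows on opposite
#' sides of the border (position 0), excluding a transition zone. Defaults
#' for 100-um bands: inner \[-50, -10\], outer \[+10, +50\] um.
#'
#' @param profile a `density_profile` (typically aggregated).
#' @param inner_window,outer_window position windows in um; must lie on
#'   opposite sides of 0.
#' @return the percent drop (positive when density falls from inner to
#'   outer).
#' @export
percent_drop <- function(profile, inner_window = c(-50, -10),
                         outer_window = c(10, 50)) {
  if (max(inner_window) > 0 || min(outer_window) < 0)
    stop("windows must lie on opposite sides of the border (inner < 0 < outer)")
  inn <- profile$density[profile$position >= inner_window[1] &
                           profile$position <= inner_window[2]]
  out <- profile$density[profile$position >= outer_window[1] &
                           profile$position <= outer_window[2]]
  if (length(inn) == 0L || length(out) == 0L)
    stop("windows select no profile stations")
  mi <- mean(inn)
  if (mi <= 0) stop("undefined percent drop: inner-window mean density is zero")
  100 * (1 - mean(out) / mi)
}

#' Septa/core crossing ratio
#'
#' Primary definition: per scene (or the whole table), mean septal count
#' over mean core count. Secondary: mean over pairs of per-pair ratios,
#' excluding (and logging) zero-denominator pairs.
#'
#' @param crossing_table a `crossing_table` holding `septal` and `core`
#'   rows; an optional `scene` column groups by scene.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return list with `ratio` (overall), `per_scene` (data frame, when a
#'   scene column exists), `n_pairs_dropped`.
#' @export
septa_core_ratio <- function(crossing_table,
                             method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  tab <- as.data.frame(crossing_table)
  if (!all(c("septal", "core") %in% tab$class))
    stop("crossing table holds no septal/core pairs")
  scen <- tab$scene %||% rep(1L, nrow(tab))
  dropped <- 0L
  one <- function(sub) {
    if (method == "ratio_of_means") {
      mc <- mean(sub$count[sub$class == "core"])
      if (mc == 0) return(NA_real_)
      mean(sub$count[sub$class == "septal"]) / mc
    } else {
      s <- sub[sub$class == "septal", c("pair_key", "count")]
      c <- sub[sub$class == "core", c("pair_key", "count")]
      m <- merge(s, c, by = "pair_key", suffixes = c("_s", "_c"))
      bad <- m$count_c == 0
      dropped <<- dropped + sum(bad)
      if (all(bad)) return(NA_real_)
      mean(m$count_s[!bad] / m$count_c[!bad])
    }
  }
  per <- vapply(split(tab, scen), one, 0)
  if (dropped > 0) ab_log("dropped %d zero-denominator pairs", dropped)
  list(ratio = mean(per, na.rm = TRUE),
       per_scene = data.frame(scene = names(per), ratio = as.numeric(per)),
       n_pairs_dropped = dropped, method = method)
}

#' Pair a CO transmission profile with an astrocyte density profile
#'
#' Aligns the two series on a common horizontal grid (linear interpolation
#' onto the overlap of their supports) ready for Pearson correlation.
#'
#' @param co_profile,astro_profile data frames with `position` and a value
#'   column (`density` or `value`).
#' @return data frame with `position`, `co`, `astro`; attribute
#'   `constant_flag` is TRUE when either series is constant (correlation
#'   undefined downstream).
#' @export
co_density_series <- function(co_profile, astro_profile) {
  val <- function(df) df$density %||% df$value
  lo <- max(min(co_profile$position), min(astro_profile$position))
  hi <- min(max(co_profile$position), max(astro_profile$position))
  if (hi <= lo) stop("profiles have non-overlapping supports")
  grid <- sort(unique(c(
    co_profile$position[co_profile$position >= lo & co_profile$position <= hi],
    astro_profile$position[astro_profile$position >= lo &
                             astro_profile$position <= hi])))
  co <- stats::approx(co_profile$position, val(co_profile), xout = grid)$y
  as <- stats::approx(astro_profile$position, val(astro_profile),
                      xout = grid)$y
  out <- data.frame(position = grid, co = co, astro = as)
  attr(out, "constant_flag") <- stats::sd(co) == 0 || stats::sd(as) == 0
  if (isTRUE(attr(out, "constant_flag")))
    ab_log("one paired series is constant; correlation undefined")
  out
}
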