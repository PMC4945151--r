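# Labeled planar region maps (barrel mosaics, disc-in-surround, laminar
# strips, periodic blob patterns). Coordinates are planar micrometres,
# x right / y up. A map carries explicit polygons (for serialization and
# border extraction) plus a fast analytic point classifier used by the
# fiber generator.

new_region_map <- function(polygons, extent, classify, areas, layout) {
  structure(list(polygons = polygons, extent = extent, classify = classify,
                 areas = areas, layout = layout),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map: %s layout, %d polygons, extent [%g,%g]x[%g,%g] um>\n",
              x$layout$type, length(x$polygons),
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  cat("  class areas (um^2):\n")
  for (cl in names(x$areas)) cat(sprintf("    %-10s %.4g\n", cl, x$areas[[cl]]))
  invisible(x)
}

#' Classify points of a region map
#'
#' @param map a `region_map`.
#' @param xy numeric matrix (n x 2) of coordinates in micrometres.
#' @return character vector of class labels; points outside the extent are
#'   labeled `"outside"`.
#' @export
classify_points <- function(map, xy) {
  stopifnot(inherits(map, "region_map"))
  xy <- rbind(xy)
  map$classify(xy[, 1], xy[, 2])
}

#' Total area of each class (um^2)
#' @param map a `region_map`.
#' @return named numeric vector.
#' @export
region_areas <- function(map) unlist(map$areas)

rect_ring <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

ellipse_ring <- function(cx, cy, rx, ry, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Sample a barrel-field region map
#'
#' Lays out `rows` x `arcs` rectangular barrel cores on a grid, each fully
#' surrounded by septum of the given width, inside a background margin.
#' Core spans (column widths and row heights) are drawn uniformly from
#' `core_span`, emulating the natural size variation of large barrels.
#' Rows are lettered from the top (A, B, ...) and arcs numbered from the
#' left, so labels read "A1".."E5" for the default 5 x 5 field.
#'
#' @param rows,arcs number of barrel rows/arcs (>= 1).
#' @param core_span core span window in um: length-2 range (uniform draw) or
#'   a single fixed span. Default c(360, 440).
#' @param septum_width septum width in um (> 0), default 50.
#' @param margin background margin around the barrel field, um.
#' @param seed integer seed for the span draws.
#' @return a `region_map` with classes `core`, `septum`, `background`.
#' @export
sample_barrel_map <- function(rows = 5L, arcs = 5L, core_span = c(360, 440),
                              septum_width = 50, margin = 150, seed = 1L) {
  if (rows < 1 || arcs < 1) stop("rows and arcs must be >= 1")
  if (any(core_span <= 0) || septum_width <= 0 || margin < 0)
    stop("non-positive geometry parameters are not allowed")
  if (length(core_span) == 1L) core_span <- rep(core_span, 2)
  sw <- septum_width
  spans <- with_seed(derive_seed(seed, "barrel_spans"), {
    list(w = runif(arcs, core_span[1], core_span[2]),
         h = runif(rows, core_span[1], core_span[2]))
  })
  # core column x-extents and row y-extents (rows top-down)
  x0 <- margin + sw + c(0, cumsum(spans$w + sw))[seq_len(arcs)]
  x1 <- x0 + spans$w
  block_w <- sum(spans$w) + (arcs + 1) * sw
  block_h <- sum(spans$h) + (rows + 1) * sw
  ytop <- margin + block_h
  y1 <- ytop - sw - c(0, cumsum(spans$h + sw))[seq_len(rows)]  # top edge per row
  y0 <- y1 - spans$h
  extent <- c(0, 2 * margin + block_w, 0, 2 * margin + block_h)

  polys <- list()
  labels <- character(0)
  for (i in seq_len(rows)) for (j in seq_len(arcs)) {
    lab <- paste0(LETTERS[i], j)
    polys[[length(polys) + 1L]] <- list(
      outer = rect_ring(x0[j], x1[j], y0[i], y1[i]),
      holes = list(), class = "core", id = lab)
    labels <- c(labels, lab)
  }
  block <- rect_ring(margin, margin + block_w, margin, ytop)
  polys[[length(polys) + 1L]] <- list(
    outer = block,
    holes = lapply(seq_along(labels), function(k) polys[[k]]$outer),
    class = "septum", id = "septum")
  polys[[length(polys) + 1L]] <- list(
    outer = rect_ring(extent[1], extent[2], extent[3], extent[4]),
    holes = list(block), class = "background", id = "background")

  xb <- as.vector(rbind(x0, x1))  # sorted since columns do not overlap
  yb <- sort(as.vector(rbind(y0, y1)))
  bx <- c(margin, margin + block_w); by <- c(margin, ytop)
  classify <- function(x, y) {
    out <- rep("outside", length(x))
    inside <- x >= extent[1] & x <= extent[2] & y >= extent[3] & y <= extent[4]
    out[inside] <- "background"
    inblock <- inside & x >= bx[1] & x <= bx[2] & y >= by[1] & y <= by[2]
    out[inblock] <- "septum"
    incore <- inblock & (findInterval(x, xb) %% 2L == 1L) &
      (findInterval(y, yb) %% 2L == 1L)
    out[incore] <- "core"
    out
  }
  core_area <- sum(outer(spans$h, spans$w))
  block_area <- block_w * block_h
  areas <- list(core = core_area, septum = block_area - core_area,
                background = (extent[2] - extent[1]) * (extent[4] - extent[3]) -
                  block_area)
  layout <- list(type = "barrel", rows = rows, arcs = arcs,
                 x0 = x0, x1 = x1, y0 = y0, y1 = y1,
                 spans_w = spans$w, spans_h = spans$h,
                 septum_width = sw, labels = matrix(labels, nrow = rows,
                                                    byrow = TRUE))
  new_region_map(polys, extent, classify, areas, layout)
}

#' Sample a two-class or periodic area map
#'
#' Three layouts emulating the non-barrel border geometries:
#' \describe{
#'   \item{`A1_in_A2`}{a disc (primary area) of radius `params$radius`
#'     (default 750 um) centered in a square surround; single closed border.}
#'   \item{`laminar_IIIa_IIIb`}{a horizontal border at y = 0 separating
#'     IIIa (y > 0) from IIIb (y < 0); strip of `params$width` x
#'     `params$height` um.}
#'   \item{`blob_interblob`}{`params$n_blobs` ellipses (semi-axes
#'     `params$blob_rx`, `params$blob_ry`) at period `params$period`
#'     (default 1000 um) along x, centered at y = 0 within a horizontal
#'     strip; emulates the ~1 mm blob spacing.}
#' }
#'
#' @param layout one of `"A1_in_A2"`, `"laminar_IIIa_IIIb"`,
#'   `"blob_interblob"`.
#' @param params named list of layout-specific sizes (um), see Details.
#' @param seed unused for these deterministic layouts; kept for interface
#'   symmetry.
#' @return a `region_map`.
#' @export
sample_area_map <- function(layout = c("A1_in_A2", "laminar_IIIa_IIIb",
                                       "blob_interblob"),
                            params = list(), seed = 1L) {
  layout <- match.arg(layout)
  if (layout == "A1_in_A2") {
    r <- params$radius %||% 750
    pad <- params$pad %||% 400
    if (r <= 0 || pad <= 0) stop("layout sizes must be positive")
    half <- r + pad
    extent <- c(-half, half, -half, half)
    ring <- ellipse_ring(0, 0, r, r, n = params$n_vertices %||% 720L)
    polys <- list(
      list(outer = ring, holes = list(), class = "A1", id = "A1"),
      list(outer = rect_ring(-half, half, -half, half), holes = list(ring),
           class = "A2", id = "A2"))
    classify <- function(x, y) {
      out <- rep("outside", length(x))
      inside <- x >= -half & x <= half & y >= -half & y <= half
      out[inside] <- "A2"
      out[inside & (x^2 + y^2) <= r^2] <- "A1"
      out
    }
    areas <- list(A1 = pi * r^2, A2 = (2 * half)^2 - pi * r^2)
    lay <- list(type = "A1_in_A2", radius = r)
  } else if (layout == "laminar_IIIa_IIIb") {
    w <- params$width %||% 4500
    h <- params$height %||% 1200
    if (w <= 0 || h <= 0) stop("layout sizes must be positive")
    extent <- c(0, w, -h / 2, h / 2)
    ra <- rect_ring(0, w, 0, h / 2)
    rb <- rect_ring(0, w, -h / 2, 0)
    polys <- list(list(outer = ra, holes = list(), class = "IIIa", id = "IIIa"),
                  list(outer = rb, holes = list(), class = "IIIb", id = "IIIb"))
    classify <- function(x, y) {
      out <- rep("outside", length(x))
      inside <- x >= 0 & x <= w & y >= -h / 2 & y <= h / 2
      out[inside & y > 0] <- "IIIa"
      out[inside & y <= 0] <- "IIIb"
      out
    }
    areas <- list(IIIa = w * h / 2, IIIb = w * h / 2)
    lay <- list(type = "laminar", width = w, height = h)
  } else {
    period <- params$period %||% 1000
    nb <- params$n_blobs %||% 5L
    rx <- params$blob_rx %||% 200
    ry <- params$blob_ry %||% 300
    h <- params$height %||% 800
    if (period <= 0 || nb < 1 || rx <= 0 || ry <= 0 || h <= 0)
      stop("layout sizes must be positive")
    if (2 * rx >= period) stop("blob diameter must be smaller than the period")
    if (2 * ry > h) stop("blob height exceeds the strip height")
    extent <- c(0, nb * period, -h / 2, h / 2)
    centers <- (seq_len(nb) - 0.5) * period
    polys <- list()
    rings <- list()
    for (k in seq_len(nb)) {
      ring <- ellipse_ring(centers[k], 0, rx, ry,
                           n = params$n_vertices %||% 360L)
      rings[[k]] <- ring
      polys[[k]] <- list(outer = ring, holes = list(), class = "blob",
                         id = paste0("blob", k))
    }
    polys[[nb + 1L]] <- list(outer = rect_ring(extent[1], extent[2],
                                               extent[3], extent[4]),
                             holes = rings, class = "interblob",
                             id = "interblob")
    classify <- function(x, y) {
      out <- rep("outside", length(x))
      inside <- x >= extent[1] & x <= extent[2] & y >= extent[3] &
        y <= extent[4]
      out[inside] <- "interblob"
      # nearest blob center along x
      k <- pmin(pmax(round(x / period + 0.5), 1), nb)
      inblob <- inside & ((x - centers[k]) / rx)^2 + (y / ry)^2 <= 1
      out[inblob] <- "blob"
      out
    }
    blob_area <- nb * pi * rx * ry
    areas <- list(blob = blob_area,
                  interblob = (extent[2] - extent[1]) *
                    (extent[4] - extent[3]) - blob_area)
    lay <- list(type = "blob", period = period, n_blobs = nb, rx = rx,
                ry = ry, centers = centers, height = h)
  }
  new_region_map(polys, extent, classify, areas, lay)
}
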