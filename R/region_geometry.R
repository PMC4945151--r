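# Border extraction and placement of every measurement construct: septal /
# core line matrices, offset lines, blob lines, perpendicular density bands,
# and landmark-based rigid alignment. All placement is deterministic given a
# region map (no RNG in this module).

# ---- border polylines -------------------------------------------------------

border_polyline <- function(vertices, classes, closed) {
  n <- nrow(vertices)
  d <- if (closed) {
    nxt <- rbind(vertices[-1, , drop = FALSE], vertices[1, , drop = FALSE])
    prv <- rbind(vertices[n, , drop = FALSE], vertices[-n, , drop = FALSE])
    nxt - prv
  } else {
    nxt <- rbind(vertices[-1, , drop = FALSE], vertices[n, , drop = FALSE])
    prv <- rbind(vertices[1, , drop = FALSE], vertices[-n, , drop = FALSE])
    nxt - prv
  }
  tang <- d / pmax(rownorm(d), .Machine$double.eps)
  seg <- diff(vertices)
  len <- sum(rownorm(seg))
  if (closed) len <- len + sqrt(sum((vertices[1, ] - vertices[n, ])^2))
  structure(list(vertices = vertices, classes = classes, closed = closed,
                 tangents = tang, length = len),
            class = "border_polyline")
}

#' @export
print.border_polyline <- function(x, ...) {
  cat(sprintf("<border_polyline: %s | %s, %d vertices, length %.4g um, %s>\n",
              x$classes[1], x$classes[2], nrow(x$vertices), x$length,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

edge_key <- function(p, q) {
  a <- sprintf("%.6f,%.6f", p[1], p[2])
  b <- sprintf("%.6f,%.6f", q[1], q[2])
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  cbind(from = seq_len(n), to = c(seq_len(n)[-1], 1L))
}

#' Extract border polylines of a region map
#'
#' Edges shared by two polygons of different classes become a border between
#' those classes, represented exactly once; edges owned by a single
#' non-background polygon become a border against `"background"`. Edges of
#' the extent boundary are dropped. Zero-area polygons are skipped with a
#' warning.
#'
#' @param region_map a `region_map`.
#' @return list of `border_polyline` objects with unit tangents.
#' @export
extract_borders <- function(region_map) {
  stopifnot(inherits(region_map, "region_map"))
  ext <- region_map$extent
  # collect all ring edges with owning class
  epts <- list(); eclass <- character(0)
  for (poly in region_map$polygons) {
    rings <- c(list(poly$outer), poly$holes)
    if (polygon_area(poly$outer) <= 0) {
      warning(sprintf("skipping degenerate zero-area polygon '%s'", poly$id))
      next
    }
    for (ring in rings) {
      ed <- ring_edges(ring)
      for (k in seq_len(nrow(ed))) {
        epts[[length(epts) + 1L]] <- rbind(ring[ed[k, 1], ], ring[ed[k, 2], ])
        eclass <- c(eclass, poly$class)
      }
    }
  }
  keys <- vapply(epts, function(e) edge_key(e[1, ], e[2, ]), "")
  groups <- split(seq_along(keys), keys)
  on_extent <- function(e) {
    (e[1, 1] == e[2, 1] && (e[1, 1] == ext[1] || e[1, 1] == ext[2])) ||
      (e[1, 2] == e[2, 2] && (e[1, 2] == ext[3] || e[1, 2] == ext[4]))
  }
  pair_of <- character(length(groups))
  edge_idx <- integer(length(groups))
  keep <- logical(length(groups))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    cls <- unique(eclass[ids])
    e <- epts[[ids[1]]]
    if (length(cls) >= 2) {
      cls <- sort(cls)[1:2]
    } else if (eclass[ids[1]] != "background" && !on_extent(e)) {
      cls <- c(sort(c(eclass[ids[1]], "background")))
    } else {
      next
    }
    pair_of[g] <- paste(cls, collapse = "|")
    edge_idx[g] <- ids[1]
    keep[g] <- TRUE
  }
  borders <- list()
  for (pr in unique(pair_of[keep])) {
    sel <- which(keep & pair_of == pr)
    segs <- lapply(edge_idx[sel], function(i) epts[[i]])
    chains <- chain_edges(segs)
    cls <- strsplit(pr, "|", fixed = TRUE)[[1]]
    for (ch in chains)
      borders[[length(borders) + 1L]] <- border_polyline(ch$vertices, cls,
                                                         ch$closed)
  }
  borders
}

# Chain undirected edges (list of 2x2 matrices) into polylines / rings.
chain_edges <- function(segs) {
  key <- function(p) sprintf("%.6f,%.6f", p[1], p[2])
  inc <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) {
    for (r in 1:2) {
      k <- key(segs[[i]][r, ])
      assign(k, c(if (exists(k, inc)) get(k, inc), i), inc)
    }
  }
  used <- rep(FALSE, length(segs))
  chains <- list()
  deg <- vapply(ls(inc), function(k) length(get(k, inc)), 0L)
  start_keys <- ls(inc)[deg == 1L]
  walk <- function(i, from_key) {
    verts <- list()
    repeat {
      used[i] <<- TRUE
      e <- segs[[i]]
      k1 <- key(e[1, ]); k2 <- key(e[2, ])
      nxt_key <- if (k1 == from_key) k2 else k1
      verts[[length(verts) + 1L]] <- if (k1 == from_key) e[1, ] else e[2, ]
      cand <- get(nxt_key, inc)
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) {
        verts[[length(verts) + 1L]] <- if (k1 == from_key) e[2, ] else e[1, ]
        break
      }
      from_key <- nxt_key
      i <- cand[1]
    }
    do.call(rbind, verts)
  }
  for (sk in start_keys) {
    for (i in get(sk, inc)) {
      if (used[i]) next
      v <- walk(i, sk)
      chains[[length(chains) + 1L]] <- list(vertices = v, closed = FALSE)
    }
  }
  for (i in seq_along(segs)) {
    if (used[i]) next
    v <- walk(i, key(segs[[i]][1, ]))
    # closed ring: first vertex repeats at the end; drop the duplicate
    if (all(abs(v[1, ] - v[nrow(v), ]) < 1e-9)) v <- v[-nrow(v), , drop = FALSE]
    chains[[length(chains) + 1L]] <- list(vertices = v, closed = TRUE)
  }
  chains
}

# Arclength stations of a border polyline.
border_cumlen <- function(border) {
  v <- border$vertices
  if (border$closed) v <- rbind(v, v[1, ])
  c(0, cumsum(rownorm(diff(v))))
}

# Point and footprint-averaged tangent at arclength s (vectorized over s).
border_point_tangent <- function(border, s, footprint = 0) {
  v <- border$vertices
  if (border$closed) v <- rbind(v, v[1, ])
  cl <- c(0, cumsum(rownorm(diff(v))))
  L <- cl[length(cl)]
  s <- pmin(pmax(s, 0), L)
  seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE), nrow(v) - 1L)
  t <- (s - cl[seg]) / pmax(cl[seg + 1L] - cl[seg], .Machine$double.eps)
  pt <- v[seg, , drop = FALSE] + t * (v[seg + 1L, , drop = FALSE] -
                                        v[seg, , drop = FALSE])
  tangent <- matrix(0, length(s), 2)
  for (k in seq_along(s)) {
    a <- s[k] - footprint / 2; b <- s[k] + footprint / 2
    if (border$closed) {
      a <- a %% L; b <- b %% L           # footprint wraps around the ring
    } else {
      a <- max(a, 0); b <- min(b, L)
      if (b <= a) { a <- s[k]; b <- s[k] }
    }
    if (b == a) {
      d <- v[seg[k] + 1L, ] - v[seg[k], ]
    } else {
      pa <- border_point_tangent(border, a)$points
      pb <- border_point_tangent(border, b)$points
      d <- as.vector(pb - pa)
      if (sum(d^2) < 1e-12) d <- v[seg[k] + 1L, ] - v[seg[k], ]
    }
    tangent[k, ] <- d / sqrt(sum(d^2))
  }
  list(points = pt, tangents = tangent)
}

# ---- measurement lines ------------------------------------------------------

make_lines <- function(cx, cy, angle, length, class, side = NA_character_,
                       offset = NA_real_, pair_key = NA_character_,
                       station = NA_real_, id = NULL) {
  if (length(cx) == 0L) {
    df <- data.frame(id = character(0), class = character(0), x0 = numeric(0),
                     y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                     length = numeric(0), angle = numeric(0),
                     side = character(0), offset = numeric(0),
                     pair_key = character(0), station = numeric(0),
                     stringsAsFactors = FALSE)
    class(df) <- c("measurement_lines", "data.frame")
    return(df)
  }
  hx <- length / 2 * cos(angle); hy <- length / 2 * sin(angle)
  df <- data.frame(
    id = id %||% paste0(class, "_", seq_along(cx)),
    class = class, x0 = cx - hx, y0 = cy - hy, x1 = cx + hx, y1 = cy + hy,
    length = length, angle = angle, side = side, offset = offset,
    pair_key = pair_key, station = station, stringsAsFactors = FALSE)
  class(df) <- c("measurement_lines", "data.frame")
  df
}

#' Bind measurement line sets
#' @param ... `measurement_lines` objects.
#' @return a combined `measurement_lines` data frame.
#' @export
bind_lines <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(dfs) == 0L) return(make_lines(numeric(0), numeric(0),
                                           numeric(0), numeric(0),
                                           character(0)))
  out <- do.call(rbind, lapply(dfs, as.data.frame))
  out$id <- make.unique(out$id)
  class(out) <- c("measurement_lines", "data.frame")
  out
}

#' Place septal and core measurement lines on a barrel map
#'
#' One septal line per inter-barrel border between adjacent qualifying
#' cores, centered on the septum centerline (the midline between the two
#' facing core edges) at its arclength midpoint and oriented along the
#' border. Each septal line is paired with a core line of identical length
#' and orientation at the centroid of its first adjacent core. Barrels
#' qualify when their facing span lies within `core_span_window`.
#'
#' @param region_map a barrel-layout `region_map`.
#' @param line_length line length in um (default 375).
#' @param core_span_window qualifying span window in um (default c(350, 450)).
#' @return a `measurement_lines` set with classes `septal` and `core` and
#'   matching `pair_key`s.
#' @export
place_septal_and_core_lines <- function(region_map, line_length = 375,
                                        core_span_window = c(350, 450)) {
  stopifnot(inherits(region_map, "region_map"))
  lay <- region_map$layout
  if (!identical(lay$type, "barrel"))
    stop("septal/core line placement requires a barrel-layout region map")
  rows <- lay$rows; arcs <- lay$arcs
  qual_w <- lay$spans_w >= core_span_window[1] & lay$spans_w <= core_span_window[2]
  qual_h <- lay$spans_h >= core_span_window[1] & lay$spans_h <= core_span_window[2]
  sep <- list(); core <- list(); keys <- character(0)
  add_pair <- function(cx, cy, angle, span, key, core_i, core_j) {
    if (span < line_length) {
      ab_log("septum at %s shorter than the line; skipped", key)
      return(invisible(NULL))
    }
    sep[[length(sep) + 1L]] <<- c(cx, cy, angle)
    ccx <- (lay$x0[core_j] + lay$x1[core_j]) / 2
    ccy <- (lay$y0[core_i] + lay$y1[core_i]) / 2
    core[[length(core) + 1L]] <<- c(ccx, ccy, angle)
    keys <<- c(keys, key)
  }
  # vertical septa between horizontally adjacent cores (same row)
  for (i in seq_len(rows)) for (j in seq_len(arcs - 1L)) {
    if (!(qual_h[i] && qual_w[j] && qual_w[j + 1L])) next
    key <- paste0("sep_", lay$labels[i, j], "_", lay$labels[i, j + 1L])
    add_pair((lay$x1[j] + lay$x0[j + 1L]) / 2,
             (lay$y0[i] + lay$y1[i]) / 2, pi / 2, lay$spans_h[i], key, i, j)
  }
  # horizontal septa between vertically adjacent cores (same arc)
  for (i in seq_len(rows - 1L)) for (j in seq_len(arcs)) {
    if (!(qual_w[j] && qual_h[i] && qual_h[i + 1L])) next
    key <- paste0("sep_", lay$labels[i, j], "_", lay$labels[i + 1L, j])
    add_pair((lay$x0[j] + lay$x1[j]) / 2,
             (lay$y0[i] + lay$y1[i + 1L]) / 2,
             0, lay$spans_w[j], key, i, j)
  }
  if (length(sep) == 0L)
    return(make_lines(numeric(0), numeric(0), numeric(0), numeric(0),
                      character(0)))
  sm <- do.call(rbind, sep); cm <- do.call(rbind, core)
  bind_lines(
    make_lines(sm[, 1], sm[, 2], sm[, 3], line_length, "septal",
               pair_key = keys, id = paste0(keys, "_S")),
    make_lines(cm[, 1], cm[, 2], cm[, 3], line_length, "core",
               pair_key = keys, id = paste0(keys, "_C")))
}

#' Place offset lines parallel to a border
#'
#' At stations spaced `station_spacing` apart along the border arclength,
#' lines of `line_length` are placed at each `offset` on both sides,
#' parallel to the local tangent (averaged over the line's footprint). Side
#' labels come from classifying the line center in `region_map`. Lines whose
#' endpoints leave the extent are dropped (logged).
#'
#' @param region_map the `region_map` providing extent and side labels.
#' @param border a `border_polyline`.
#' @param offsets offset distances in um (default c(50, 200)); offset 0 puts
#'   the line on the border itself (used in tests).
#' @param line_length line length in um (default 50; the laminar variant
#'   uses 375).
#' @param station_spacing arclength between stations, um; default
#'   `2 * line_length`. Stations are tie-broken toward the lower arclength.
#' @return a `measurement_lines` set with class `"offset"`, `side` and
#'   `offset` filled, and one pairing key per station.
#' @export
place_offset_lines <- function(region_map, border, offsets = c(50, 200),
                               line_length = 50,
                               station_spacing = 2 * line_length) {
  stopifnot(inherits(border, "border_polyline"))
  L <- border$length
  if (border$closed) {
    s <- seq(0, L - station_spacing / 2, by = station_spacing)
  } else {
    s <- seq(line_length / 2, L - line_length / 2, by = station_spacing)
  }
  if (length(s) == 0L)
    stop("border too short for the requested line length")
  pt <- border_point_tangent(border, s, footprint = line_length)
  ext <- region_map$extent
  out <- list()
  for (k in seq_along(s)) {
    tg <- pt$tangents[k, ]
    nrm <- c(-tg[2], tg[1])
    angle <- atan2(tg[2], tg[1])
    for (off in offsets) for (sgn in (if (off == 0) 1 else c(-1, 1))) {
      ctr <- pt$points[k, ] + sgn * off * nrm
      hx <- line_length / 2 * tg
      p0 <- ctr - hx; p1 <- ctr + hx
      if (any(c(p0, p1)[c(1, 3)] < ext[1]) || any(c(p0, p1)[c(1, 3)] > ext[2]) ||
          any(c(p0, p1)[c(2, 4)] < ext[3]) || any(c(p0, p1)[c(2, 4)] > ext[4])) {
        ab_log("offset line at station %.0f um leaves the extent; dropped",
               s[k])
        next
      }
      side <- region_map$classify(ctr[1], ctr[2])
      out[[length(out) + 1L]] <- make_lines(
        ctr[1], ctr[2], angle, line_length, "offset", side = side,
        offset = off, pair_key = sprintf("station_%04.0f", s[k]),
        station = s[k],
        id = sprintf("off_%s_%g_%04.0f", side, off, s[k]))
    }
  }
  do.call(bind_lines, out)
}

#' Place vertical lines at blob centers, inter-blob centers and margins
#'
#' Vertical lines (default 500 um) centered on the blob band (y = 0): one at
#' each blob centroid x, one at each midpoint between consecutive blobs
#' (inter-blob center), and one at each blob's right edge plus `margin_gap`
#' (the left margin of the following inter-blob). Lines too close to the
#' extent edge are skipped (logged).
#'
#' @param blob_map a blob-layout `region_map`.
#' @param line_length line length in um (default 500).
#' @param margin_gap gap between a blob edge and the margin line, um.
#' @return a `measurement_lines` set with classes `blob_center`,
#'   `interblob_center`, `interblob_margin`.
#' @export
place_blob_lines <- function(blob_map, line_length = 500, margin_gap = 50) {
  stopifnot(inherits(blob_map, "region_map"))
  lay <- blob_map$layout
  if (!identical(lay$type, "blob"))
    stop("blob line placement requires a blob-layout region map")
  ext <- blob_map$extent
  if (line_length / 2 > ext[4] || -line_length / 2 < ext[3])
    stop("line length exceeds the strip height")
  centers <- lay$centers
  xs <- list()
  ok_x <- function(x) x >= ext[1] && x <= ext[2]
  add <- function(x, cls, k) {
    if (!ok_x(x)) {
      ab_log("%s line %d too close to the extent edge; skipped", cls, k)
      return(invisible(NULL))
    }
    xs[[length(xs) + 1L]] <<- data.frame(x = x, cls = cls, k = k)
  }
  for (k in seq_along(centers)) add(centers[k], "blob_center", k)
  if (length(centers) > 1L) {
    for (k in seq_len(length(centers) - 1L))
      add((centers[k] + centers[k + 1L]) / 2, "interblob_center", k)
  }
  for (k in seq_along(centers))
    add(centers[k] + lay$rx + margin_gap, "interblob_margin", k)
  df <- do.call(rbind, xs)
  make_lines(df$x, rep(0, nrow(df)), rep(pi / 2, nrow(df)), line_length,
             df$cls, pair_key = sprintf("blobstation_%02d", df$k),
             id = sprintf("%s_%02d", df$cls, df$k))
}

# ---- density bands ----------------------------------------------------------

#' Place density bands perpendicular to a border
#'
#' `count` rectangular bands of `width` x `length` um, centers evenly spaced
#' along the border, long axis perpendicular to the local tangent. The band
#' axis is oriented so that positive positions point away from `inner_class`
#' (when given), putting the inner side at negative positions.
#'
#' @param border a `border_polyline`.
#' @param width band width (along the border), um; 25 for the rodent preset,
#'   30 for the human preset.
#' @param length band length (across the border), um.
#' @param count number of bands (default 10).
#' @param region_map optional `region_map` used to orient the axis via
#'   `inner_class`.
#' @param inner_class optional class label to place at negative positions.
#' @return a data frame of class `density_bands`: one row per band with
#'   center, unit axis (`nx, ny`), unit tangent, width and length.
#' @export
place_density_bands <- function(border, width = 25, length = 100, count = 10,
                                region_map = NULL, inner_class = NULL) {
  stopifnot(inherits(border, "border_polyline"))
  L <- border$length
  need <- count * width
  if (L < need) {
    count2 <- max(1L, floor(L / width))
    warning(sprintf("border length %.0f um holds only %d non-overlapping bands (requested %d)",
                    L, count2, count))
    count <- count2
  }
  s <- if (border$closed) seq(0, L, length.out = count + 1L)[seq_len(count)]
       else seq(width / 2, L - width / 2, length.out = count)
  pt <- border_point_tangent(border, s, footprint = width)
  nx <- -pt$tangents[, 2]; ny <- pt$tangents[, 1]
  if (!is.null(inner_class) && !is.null(region_map)) {
    eps <- length / 20
    inner_lab <- region_map$classify(pt$points[, 1] - eps * nx,
                                     pt$points[, 2] - eps * ny)
    flip <- inner_lab != inner_class
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  }
  df <- data.frame(band = seq_len(count), cx = pt$points[, 1],
                   cy = pt$points[, 2], nx = nx, ny = ny,
                   tx = pt$tangents[, 1], ty = pt$tangents[, 2],
                   width = width, length = length)
  class(df) <- c("density_bands", "data.frame")
  df
}

# ---- rigid / similarity transforms -----------------------------------------

#' Least-squares landmark transform (rigid or similarity)
#'
#' Closed-form 2-D Procrustes fit of `target ~ R %*% source + t` over
#' corresponding point pairs, optionally with a uniform scale. Reflections
#' are not allowed. The RMS landmark residual is reported.
#'
#' @param source_points,target_points n x 2 matrices, n >= 2, matching row
#'   order.
#' @param allow_scale fit a similarity (uniform scale) instead of a rigid
#'   transform.
#' @return a `rigid_transform`: list(rotation, translation, scale, rms).
#' @export
estimate_landmark_transform <- function(source_points, target_points,
                                        allow_scale = FALSE) {
  src <- rbind(source_points); dst <- rbind(target_points)
  if (nrow(src) != nrow(dst)) stop("point sets must have equal cardinality")
  if (nrow(src) < 2L) stop("at least 2 point pairs are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  a <- sweep(src, 2, cs); b <- sweep(dst, 2, cd)
  if (sum(a^2) < 1e-12 || sum(b^2) < 1e-12)
    stop("degenerate landmark configuration (coincident points)")
  # 2-D Kabsch via the angle closed form (no reflection)
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  theta <- atan2(num, den)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s <- 1
  if (allow_scale) {
    ar <- a %*% t(R)
    s <- sum(ar * b) / sum(a^2)
    if (s <= 0) stop("degenerate landmark configuration (non-positive scale)")
  }
  t <- cd - s * as.vector(R %*% cs)
  fit <- s * a %*% t(R)
  rms <- sqrt(mean(rowSums((fit - b)^2)))
  structure(list(rotation = theta, translation = t, scale = s, rms = rms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: rotation %.6g rad, translation (%.6g, %.6g) um, scale %.6g, rms %.3g um>\n",
              x$rotation, x$translation[1], x$translation[2], x$scale, x$rms))
  invisible(x)
}

#' Invert a rigid/similarity transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  th <- -transform$rotation
  s <- 1 / transform$scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  structure(list(rotation = th,
                 translation = as.vector(-s * R %*% transform$translation),
                 scale = s, rms = transform$rms),
            class = "rigid_transform")
}

transform_xy <- function(transform, xy) {
  th <- transform$rotation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(transform$scale * xy %*% t(R), 2, transform$translation, `+`)
}

#' Apply a transform to curves, lines or points
#'
#' Maps all coordinates; polyline lengths are preserved under rigid
#' transforms (isometry).
#'
#' @param transform a `rigid_transform`.
#' @param obj a `curve_set`, `measurement_lines`, or n x 2 matrix of points.
#' @return the same type of object, transformed.
#' @export
apply_transform <- function(transform, obj) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(obj, "curve_set")) {
    out <- obj
    out$xy <- transform_xy(transform, obj$xy)
    out
  } else if (inherits(obj, "measurement_lines")) {
    p0 <- transform_xy(transform, cbind(obj$x0, obj$y0))
    p1 <- transform_xy(transform, cbind(obj$x1, obj$y1))
    out <- obj
    out$x0 <- p0[, 1]; out$y0 <- p0[, 2]
    out$x1 <- p1[, 1]; out$y1 <- p1[, 2]
    out$angle <- atan2(p1[, 2] - p0[, 2], p1[, 1] - p0[, 1])
    out$length <- sqrt(rowSums((p1 - p0)^2))
    out
  } else if (is.matrix(obj)) {
    transform_xy(transform, obj)
  } else stop("unsupported object type for apply_transform")
}
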