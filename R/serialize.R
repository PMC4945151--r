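# Serialization. Scenes travel as GeoJSON FeatureCollections (regions as
# Polygons with a "class" property, fibers as LineStrings with
# "structure_id" and "kind", landmarks as Points), lengths in micrometres;
# the generative ground truth goes to a JSON sidecar. Configs are YAML with
# an explicit seed. Crossing tables and profiles are plain CSV with frozen
# headers.

ring_coords <- function(ring, digits = 10) {
  r <- rbind(ring, ring[1, ])  # GeoJSON rings close explicitly
  lapply(seq_len(nrow(r)), function(i) round(as.numeric(r[i, ]), digits))
}

#' Write a synthetic scene as GeoJSON (+ ground-truth sidecar)
#'
#' @param scene a `synthetic_scene`.
#' @param path output path (".geojson"); the generator ground truth is
#'   written alongside as `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_scene_geojson <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  feats <- list()
  for (poly in scene$region_map$polygons) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = c(list(ring_coords(poly$outer)),
                                      lapply(poly$holes, ring_coords))),
      properties = list(kind = "region", class = poly$class, id = poly$id))
  }
  add_curves <- function(curves, kind) {
    if (n_curves(curves) == 0L) return(invisible(NULL))
    ids <- unique(curves$curve_id)
    sid <- curves$structure_id
    for (k in seq_along(ids)) {
      sel <- curves$curve_id == ids[k]
      coords <- lapply(which(sel), function(i)
        round(as.numeric(curves$xy[i, ]), 10))
      feats[[length(feats) + 1L]] <<- list(
        type = "Feature",
        geometry = list(type = "LineString", coordinates = coords),
        properties = list(kind = kind, structure_id = sid[k],
                          curve_id = ids[k]))
    }
  }
  add_curves(scene$astro, "astrocyte")
  add_curves(scene$capillary, "capillary")
  for (i in seq_len(nrow(scene$landmarks))) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = round(as.numeric(scene$landmarks[i, ]), 10)),
      properties = list(kind = "landmark", id = i))
  }
  fc <- list(type = "FeatureCollection",
             bbox = as.numeric(scene$region_map$extent[c(1, 3, 2, 4)]),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  truth <- unclass(scene$config)
  truth$scene_seed <- scene$seed
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Ray-casting point-in-ring test, vectorized over points.
points_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Generic classifier for polygon-based maps (used for imported scenes).
generic_classify <- function(polygons, extent) {
  force(polygons); force(extent)
  function(x, y) {
    out <- rep("outside", length(x))
    inb <- x >= extent[1] & x <= extent[2] & y >= extent[3] & y <= extent[4]
    for (poly in polygons) {
      cand <- which(inb & out %in% c("outside", "background"))
      if (length(cand) == 0L) next
      hit <- points_in_ring(x[cand], y[cand], poly$outer)
      for (h in poly$holes)
        hit <- hit & !points_in_ring(x[cand], y[cand], h)
      out[cand[hit]] <- poly$class
    }
    out[inb & out == "outside"] <- "background"
    out
  }
}

#' Read a scene written by [write_scene_geojson()]
#'
#' Reconstructs the region map (with a generic point-in-polygon classifier),
#' both curve sets and the landmarks; the ground-truth sidecar is attached
#' when present.
#'
#' @param path a ".geojson" path.
#' @return a `synthetic_scene` (its `config` is the sidecar list, or NULL).
#' @export
read_scene_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  ext <- as.numeric(unlist(fc$bbox))[c(1, 3, 2, 4)]
  polys <- list()
  curves <- list(astrocyte = list(), capillary = list())
  landmarks <- list()
  for (f in fc$features) {
    kind <- f$properties$kind
    if (identical(kind, "region")) {
      rings <- lapply(f$geometry$coordinates, function(rr) {
        m <- do.call(rbind, lapply(rr, function(p) as.numeric(unlist(p))))
        m[-nrow(m), , drop = FALSE]  # drop closing vertex
      })
      polys[[length(polys) + 1L]] <- list(outer = rings[[1]],
                                          holes = rings[-1],
                                          class = f$properties$class,
                                          id = f$properties$id)
    } else if (identical(kind, "landmark")) {
      landmarks[[length(landmarks) + 1L]] <-
        as.numeric(unlist(f$geometry$coordinates))
    } else {
      m <- do.call(rbind, lapply(f$geometry$coordinates,
                                 function(p) as.numeric(unlist(p))))
      curves[[kind]][[length(curves[[kind]]) + 1L]] <-
        list(xy = m, structure_id = f$properties$structure_id)
    }
  }
  build_cs <- function(lst, kind) {
    if (length(lst) == 0L) return(empty_curve_set(kind))
    nv <- vapply(lst, function(c) nrow(c$xy), 0L)
    new_curve_set(do.call(rbind, lapply(lst, `[[`, "xy")),
                  rep(seq_along(lst), nv),
                  vapply(lst, function(c) as.integer(c$structure_id), 0L),
                  kind)
  }
  areas <- list()
  for (p in polys) {
    a <- polygon_area(p$outer) - sum(vapply(p$holes, polygon_area, 0))
    areas[[p$class]] <- (areas[[p$class]] %||% 0) + a
  }
  map <- new_region_map(polys, ext, generic_classify(polys, ext), areas,
                        list(type = "imported"))
  truth_path <- paste0(path, ".truth.json")
  cfg <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  structure(list(region_map = map,
                 astro = build_cs(curves$astrocyte, "astrocyte"),
                 capillary = build_cs(curves$capillary, "capillary"),
                 landmarks = do.call(rbind, landmarks),
                 config = cfg, seed = cfg$scene_seed %||% NA_integer_),
            class = "synthetic_scene")
}

#' Write measurement lines as GeoJSON LineStrings
#' @param lines a `measurement_lines` set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  lines <- as.data.frame(lines)
  feats <- lapply(seq_len(nrow(lines)), function(i) list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(lines$x0[i], lines$y0[i]),
                                       c(lines$x1[i], lines$y1[i]))),
    properties = list(id = lines$id[i], class = lines$class[i],
                      side = lines$side[i], offset = lines$offset[i],
                      pair_key = lines$pair_key[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a rigid transform as JSON
#' @param transform a `rigid_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path the JSON path.
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(rotation = as.numeric(x$rotation),
                 translation = as.numeric(unlist(x$translation)),
                 scale = as.numeric(x$scale), rms = as.numeric(x$rms)),
            class = "rigid_transform")
}

#' Write / read a crossing table as CSV
#'
#' Frozen header: id, class, side, offset, pair_key, station, length,
#' count, plus group/scene columns when present.
#'
#' @param table a `crossing_table`.
#' @param path CSV path.
#' @return `path` (write) / a `crossing_table` (read).
#' @export
write_crossing_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crossing_table
#' @export
read_crossing_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("crossing_table", "data.frame")
  out
}

#' Write a rasterized scene as plain-text PGM pages
#'
#' One P2 (ASCII) PGM file per channel — `<stem>_labels.pgm` (class levels
#' coded 0..k), `<stem>_astro.pgm`, `<stem>_capillary.pgm` — plus
#' `<stem>_landmarks.csv` with the pixel coordinates. A plain-text stand-in
#' for multi-page TIFF output, which has no writer in this R stack.
#'
#' @param raster the list produced by [rasterize_scene()].
#' @param stem output path stem (no extension).
#' @return character vector of the written paths, invisibly.
#' @export
write_raster_pgm <- function(raster, stem) {
  write_pgm <- function(m, path, maxval) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
                 sprintf("%d", maxval)), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    path
  }
  lv <- raster$class_levels
  lab <- matrix(match(raster$labels, lv) - 1L, nrow = nrow(raster$labels))
  paths <- c(
    write_pgm(lab, paste0(stem, "_labels.pgm"), max(1L, length(lv) - 1L)),
    write_pgm(raster$astro, paste0(stem, "_astro.pgm"), 1L),
    write_pgm(raster$capillary, paste0(stem, "_capillary.pgm"), 1L))
  lmp <- paste0(stem, "_landmarks.csv")
  utils::write.csv(data.frame(col = raster$landmarks_px[, 1],
                              row = raster$landmarks_px[, 2]),
                   lmp, row.names = FALSE)
  invisible(c(paths, lmp))
}

#' Read a YAML run configuration
#'
#' @param path YAML file; must carry an explicit integer `seed`.
#' @return named list of overrides.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  cfg
}

#' Write a run configuration as YAML
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Built-in calibration constants
#'
#' Published per-line group means and related constants for every
#' experiment preset, stored in `inst/extdata/calibration.yaml` so targets
#' are auditable and changeable without code edits.
#'
#' @return nested named list of calibration constants.
#' @export
calibration_constants <- function() {
  yaml::read_yaml(system.file("extdata", "calibration.yaml",
                              package = "astroborder", mustWork = TRUE))
}
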