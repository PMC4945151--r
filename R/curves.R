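# CurveSet: a set of 2-D polylines in micrometres, each tagged with the id
# of its parent structure (astrocyte soma or capillary). Stored column-wise
# as one big vertex matrix plus a per-vertex curve index, which keeps
# segment extraction and crossing counting fully vectorized.

new_curve_set <- function(xy, curve_id, structure_id, kind = "astrocyte") {
  stopifnot(is.matrix(xy), ncol(xy) == 2, length(curve_id) == nrow(xy))
  structure(list(xy = xy, curve_id = as.integer(curve_id),
                 structure_id = structure_id, kind = kind),
            class = "curve_set")
}

#' An empty curve set
#' @param kind structure kind tag.
#' @return a `curve_set` with zero polylines.
#' @export
empty_curve_set <- function(kind = "astrocyte") {
  new_curve_set(matrix(numeric(0), ncol = 2), integer(0),
                integer(0), kind)
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set: %d polylines, %d vertices, total length %.4g um, kind %s>\n",
              n_curves(x), nrow(x$xy), total_length(x), x$kind))
  invisible(x)
}

#' Number of polylines in a curve set
#' @param curves a `curve_set`.
#' @return integer count.
#' @export
n_curves <- function(curves) {
  if (length(curves$curve_id) == 0L) return(0L)
  length(unique(curves$curve_id))
}

#' Total polyline arclength (um)
#' @param curves a `curve_set`.
#' @return numeric scalar.
#' @export
total_length <- function(curves) {
  s <- curve_segments(curves)
  if (nrow(s) == 0L) return(0)
  sum(sqrt((s[, "x1"] - s[, "x0"])^2 + (s[, "y1"] - s[, "y0"])^2))
}

#' Extract the segment table of a curve set
#'
#' @param curves a `curve_set`.
#' @return numeric matrix with columns `x0,y0,x1,y1,curve` (one row per
#'   polyline segment).
#' @export
curve_segments <- function(curves) {
  n <- nrow(curves$xy)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1", "curve"))))
  }
  same <- curves$curve_id[-n] == curves$curve_id[-1]
  i <- which(same)
  cbind(x0 = curves$xy[i, 1], y0 = curves$xy[i, 2],
        x1 = curves$xy[i + 1L, 1], y1 = curves$xy[i + 1L, 2],
        curve = as.numeric(curves$curve_id[i]))
}

# Combine curve sets, re-indexing curve ids.
combine_curve_sets <- function(a, b) {
  if (n_curves(a) == 0L) return(b)
  if (n_curves(b) == 0L) return(a)
  off <- max(a$curve_id)
  soff <- if (length(a$structure_id)) max(a$structure_id) else 0L
  new_curve_set(rbind(a$xy, b$xy),
                c(a$curve_id, b$curve_id + off),
                c(a$structure_id, b$structure_id + soff),
                a$kind)
}

# Subset whole polylines by curve index (logical or integer over curves).
subset_curves <- function(curves, keep_curve_ids) {
  if (length(keep_curve_ids) == 0L) return(empty_curve_set(curves$kind))
  sel <- curves$curve_id %in% keep_curve_ids
  ids <- curves$curve_id[sel]
  # structure_id is per curve, indexed by sorted unique curve id
  uc <- sort(unique(curves$curve_id))
  keep_pos <- match(sort(unique(ids)), uc)
  new_curve_set(curves$xy[sel, , drop = FALSE],
                match(ids, sort(unique(ids))),
                curves$structure_id[keep_pos], curves$kind)
}
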