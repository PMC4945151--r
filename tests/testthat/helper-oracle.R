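# Independent oracles used across the suite. These deliberately re-derive
# the quantities with different formulations (explicit loops, parametric
# solves, numeric optimization) so agreement with the package is a real
# cross-check, not a tautology.

# Brute-force all-pairs crossing count for one line against a segment
# matrix (x0, y0, x1, y1): side-change rule with on-carrier points positive,
# intersection parameter strictly inside the open measurement segment.
oracle_crossings <- function(ax, ay, bx, by, seg) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    p0 <- c(seg[i, 1], seg[i, 2]); p1 <- c(seg[i, 3], seg[i, 4])
    d <- c(bx - ax, by - ay)
    side <- function(p) {
      cr <- d[1] * (p[2] - ay) - d[2] * (p[1] - ax)
      if (cr >= 0) 1L else -1L
    }
    if (side(p0) == side(p1)) next
    e <- p1 - p0
    den <- d[1] * e[2] - d[2] * e[1]
    t <- ((p0[1] - ax) * e[2] - (p0[2] - ay) * e[1]) / den
    if (t > 0 && t < 1) n <- n + 1L
  }
  n
}

# Count a whole measurement_lines set against a curve_set via the oracle.
oracle_count_table <- function(lines, curves) {
  seg <- curve_segments(curves)
  vapply(seq_len(nrow(lines)), function(k)
    oracle_crossings(lines$x0[k], lines$y0[k], lines$x1[k], lines$y1[k],
                     seg), 0L)
}

# Random segment soup as a curve_set.
random_segments <- function(n, lo = 0, hi = 100) {
  m <- cbind(runif(n, lo, hi), runif(n, lo, hi),
             runif(n, lo, hi), runif(n, lo, hi))
  new_curve_set(matrix(t(m), ncol = 2, byrow = TRUE),
                rep(seq_len(n), each = 2), seq_len(n), "test")
}

# Numeric least-squares rigid fit by direct optimization (oracle for the
# closed-form Procrustes solution).
oracle_rigid_fit <- function(src, dst) {
  obj <- function(par) {
    R <- matrix(c(cos(par[1]), sin(par[1]), -sin(par[1]), cos(par[1])), 2, 2)
    sum((sweep(src %*% t(R), 2, par[2:3], `+`) - dst)^2)
  }
  best <- NULL
  for (th0 in seq(-pi, pi, length.out = 8)) {
    fit <- stats::optim(c(th0, 0, 0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(rotation = atan2(sin(best$par[1]), cos(best$par[1])),
       translation = best$par[2:3],
       rms = sqrt(best$value / nrow(src)))
}

# Minimal straight horizontal border for band/offset tests.
straight_border <- function(x0 = 0, x1 = 1000, y = 0,
                            classes = c("IIIa", "IIIb")) {
  astroborder:::border_polyline(cbind(c(x0, x1), c(y, y)), classes,
                                closed = FALSE)
}
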