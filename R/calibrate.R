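# Generator calibration. For isotropic fibers the line-intercept identity
# E[crossings] = 2 L rho / pi inverts analytically (rho = pi m / (2 L)); the
# capillary process satisfies it exactly. Confined arbors lose fiber length
# to border truncation, so their per-class soma intensity is rescaled by a
# pilot run of the full scene -> place -> count chain (expected crossings
# are exactly linear in soma intensity). Border confinement strength can be
# solved by bisection against simulated septal-line means.

#' Invert the line-intercept identity for fiber length density
#'
#' For isotropic fibers, a straight test line of length L crosses fibers of
#' length density rho (um/um^2) at expected rate 2 L rho / pi; so the
#' density reproducing a target mean is `rho = pi * m / (2 * L)`.
#'
#' @param target_mean_crossings target expected crossings per line (>= 0),
#'   scalar or named vector (one per region class).
#' @param line_length_um test line length in um (> 0).
#' @return fiber length densities in um/um^2, same names as the targets.
#' @export
calibrate_generator <- function(target_mean_crossings, line_length_um) {
  if (any(target_mean_crossings < 0))
    stop("unattainable target: mean crossings must be >= 0")
  if (line_length_um <= 0) stop("line length must be positive")
  pi * target_mean_crossings / (2 * line_length_um)
}

#' Solve the border crossing probability against simulated septal means
#'
#' Bisection on `p_cross` so that the simulated mean septal-line crossing
#' count matches a target, holding the rest of the configuration fixed.
#' The septal mean is non-decreasing in `p_cross`, so bisection applies;
#' each evaluation averages `n_scenes` simulated barrel scenes.
#'
#' @param config a `generator_config` (its `p_cross` is ignored).
#' @param target_septal_mean target mean crossings per septal line.
#' @param make_map function(seed) -> barrel `region_map`.
#' @param line_length septal line length, um.
#' @param n_scenes scenes per bisection evaluation.
#' @param iterations bisection iterations (the answer is noisy at the
#'   simulation s.e.; 8 iterations locate p to ~1/256).
#' @param seed integer seed.
#' @return list(p_cross, achieved_mean, iterations).
#' @export
calibrate_p_cross <- function(config, target_septal_mean, make_map,
                              line_length = 375, n_scenes = 10L,
                              iterations = 8L, seed = 1L) {
  eval_p <- function(p, it) {
    cfg <- config
    cfg$p_cross <- p
    means <- numeric(n_scenes)
    for (s in seq_len(n_scenes)) {
      sd_s <- derive_seed(seed, sprintf("pcross_%d_%d", it, s))
      map <- make_map(sd_s)
      astro <- grow_astrocyte_arbors(map, cfg, sd_s)
      ln <- place_septal_and_core_lines(map, line_length = line_length)
      tab <- count_line_crossings(ln[ln$class == "septal", ], astro)
      means[s] <- mean(tab$count)
    }
    mean(means)
  }
  lo <- 0; hi <- 1
  m_lo <- eval_p(0, 0L); m_hi <- eval_p(1, 99L)
  if (target_septal_mean <= m_lo) return(list(p_cross = 0, achieved_mean = m_lo,
                                              iterations = 0L))
  if (target_septal_mean >= m_hi) return(list(p_cross = 1, achieved_mean = m_hi,
                                              iterations = 0L))
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    m <- eval_p(mid, it)
    if (m < target_septal_mean) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  list(p_cross = p, achieved_mean = eval_p(p, iterations + 1L),
       iterations = iterations)
}
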