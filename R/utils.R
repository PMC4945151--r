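# Internal utilities: seeding, logging, grouped cumulative sums.

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' Each generator component (somata, branches, capillaries, thinning, ...)
#' draws from its own named stream so that adding a component does not
#' perturb the others. The derivation is a simple string hash folded into
#' the root seed, kept below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  p <- 2147483587  # prime < 2^31
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% p
  as.integer((abs(seed) %% p * 7919 + h + 1) %% p)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One structured log line per pipeline stage; silenced unless
# options(astroborder.verbose = TRUE).
ab_log <- function(fmt, ...) {
  if (isTRUE(getOption("astroborder.verbose", FALSE)))
    message(sprintf(paste0("[astroborder] ", fmt), ...))
  invisible(NULL)
}

# Cumulative sum restarting at each group, for groups given by run lengths.
# x must be ordered so that each group's elements are contiguous.
grouped_cumsum <- function(x, lengths) {
  if (length(x) == 0L) return(x)
  ends <- cumsum(lengths)
  cs <- cumsum(x)
  base <- rep(c(0, cs[ends[-length(ends)]]), lengths)
  cs - base
}

# Row-wise Euclidean norm of a 2-column matrix.
rownorm <- function(m) sqrt(m[, 1]^2 + m[, 2]^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
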