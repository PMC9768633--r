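#' @importFrom rlang .data
#' @importFrom stats coef lm median na.omit quantile rnorm rpois runif sd setNames
#' @importFrom stats aggregate as.formula density weighted.mean predict rlnorm vcov
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without mutating global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

abort_di <- function(msg, class) {
  stop(rlang::error_cnd(c(class, "deprindex_error"), message = msg))
}

warn_di <- function(msg, class) {
  rlang::warn(msg, class = c(class, "deprindex_warning"))
}

#' Count modes of a distribution via kernel density
#'
#' Bimodality diagnostic used after the East-West correction: local maxima of
#' a Gaussian kernel density estimate, keeping only peaks whose height exceeds
#' `prominence` times the maximum density, and whose separating valley drops
#' below `valley` times the smaller of the two peak heights.
#'
#' @param x numeric vector.
#' @param prominence minimum peak height relative to the tallest peak.
#' @param valley maximum valley height (relative to the lower adjacent peak)
#'   for two peaks to count as distinct modes.
#' @return integer number of modes (>= 1 for non-degenerate input).
#' @export
count_density_modes <- function(x, prominence = 0.1, valley = 0.9) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || sd(x) == 0) return(1L)
  d <- stats::density(x, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] >= prominence * max(y)]
  if (length(peaks) <= 1) return(max(1L, length(peaks)))
  # merge peaks not separated by a deep enough valley
  keep <- peaks[1]
  for (p in peaks[-1]) {
    prev <- keep[length(keep)]
    v <- min(y[prev:p])
    if (v < valley * min(y[prev], y[p])) {
      keep <- c(keep, p)
    } else if (y[p] > y[prev]) {
      keep[length(keep)] <- p
    }
  }
  length(keep)
}

#' Flag a distribution as bimodal
#'
#' @inheritParams count_density_modes
#' @return logical, `TRUE` if more than one mode is detected.
#' @export
is_bimodal <- function(x, prominence = 0.1, valley = 0.9) {
  count_density_modes(x, prominence, valley) > 1L
}
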