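`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code under a temporary RNG seed
#'
#' Internal wrapper around [withr::with_seed()] that tolerates a `NULL` seed
#' (code then runs under the session RNG stream).
#'
#' @param seed integer seed or `NULL`.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Locate threshold crossings of a sampled curve
#'
#' Finds all positions where the piecewise-linear interpolant of `(x, y)`
#' crosses `level`, by linear interpolation between adjacent samples.
#'
#' @param x increasing numeric vector of positions.
#' @param y numeric vector of values, same length as `x`.
#' @param level numeric threshold.
#' @return data.frame with columns `position` and `direction`
#'   (`"rising"`/`"falling"`), ordered by position.
#' @noRd
threshold_crossings <- function(x, y, level) {
  n <- length(y)
  if (n < 2L) {
    return(data.frame(position = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  lo <- y[-n]
  hi <- y[-1L]
  rising <- lo < level & hi >= level
  falling <- lo >= level & hi < level
  idx <- which(rising | falling)
  if (length(idx) == 0L) {
    return(data.frame(position = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  frac <- (level - y[idx]) / (y[idx + 1L] - y[idx])
  pos <- x[idx] + frac * (x[idx + 1L] - x[idx])
  out <- data.frame(position = pos,
                    direction = ifelse(rising[idx], "rising", "falling"),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Three-point moving average with edge replication
#' @noRd
smooth_ma <- function(y, width = 3L) {
  width <- as.integer(width)
  if (width <= 1L) return(y)
  n <- length(y)
  half <- (width - 1L) %/% 2L
  padded <- c(rep(y[1L], half), y, rep(y[n], half))
  stats::filter(padded, rep(1 / width, width), sides = 2)[(half + 1L):(half + n)]
}

#' Strict local maxima of a sampled curve
#'
#' @param y numeric vector.
#' @return integer indices i with y[i] > y[i-1] and y[i] > y[i+1].
#' @noRd
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
}

#' Logistic missing-not-at-random dropout probability
#'
#' Probability that a measurement of log2 intensity `x` drops out, under a
#' logistic curve decreasing in intensity: low-abundance signals are lost
#' preferentially. A `midpoint` of `-Inf` means no dropout at all.
#'
#' @param x numeric, log2 intensities.
#' @param midpoint log2 intensity at which dropout probability is 0.5.
#' @param slope logistic steepness per log2 unit; must be >= 0.
#' @return dropout probabilities in `[0, 1]`.
#' @export
mnar_dropout_prob <- function(x, midpoint, slope) {
  if (slope < 0) stop_input("mnar slope must be >= 0, got %g", slope)
  if (is.infinite(midpoint) && midpoint < 0) return(rep(0, length(x)))
  stats::plogis(slope * (midpoint - x))
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
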