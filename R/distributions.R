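# Discrete probability mass functions on a uniform integer day grid.
#
# The empirical lifespan distribution of a control cohort lives here, and its
# n-fold convolution gives the exact null distribution of the sum (hence mean)
# of n control animals drawn i.i.d. from that cohort.

#' Discrete distribution on an integer day grid
#'
#' A `ddist` is a probability mass function supported on consecutive grid
#' points `origin, origin + step_days, ...` (days). Leading and trailing zero
#' masses are trimmed so the first and last entries are strictly positive.
#'
#' @param pmf Numeric vector of non-negative masses summing to 1 (within 1e-9).
#' @param origin Integer day of the first support point.
#' @param step_days Positive integer grid step in days (default 1).
#' @return An object of class `ddist` with fields `pmf`, `origin`, `step_days`.
#' @examples
#' d <- ddist(c(0.5, 0.5), origin = 0)
#' ddist_moments(d)
#' @export
ddist <- function(pmf, origin, step_days = 1L) {
  if (!is.numeric(pmf) || length(pmf) == 0L) stop("no observations")
  if (any(!is.finite(pmf)) || any(pmf < 0)) stop("pmf must be finite and non-negative")
  s <- sum(pmf)
  if (abs(s - 1) > 1e-9) stop("pmf must sum to 1 (got ", format(s), ")")
  if (step_days < 1 || step_days != round(step_days)) stop("step_days must be a positive integer")
  # trim zero padding at the ends; keep origin consistent
  nz <- which(pmf > 0)
  first <- nz[1L]; last <- nz[length(nz)]
  pmf <- pmf[first:last]
  origin <- origin + (first - 1L) * step_days
  structure(
    list(pmf = pmf, origin = as.integer(origin), step_days = as.integer(step_days)),
    class = "ddist"
  )
}

#' Empirical distribution of observed lifespans
#'
#' Places mass count/N on each observed day. Non-integer values are rounded to
#' the nearest day (ties to even), matching daily inspection resolution.
#'
#' @param values Numeric vector of lifespans in days (all `>= 0`).
#' @return A [ddist] on the integer day grid.
#' @examples
#' ddist_from_samples(c(2, 2, 4))
#' @export
ddist_from_samples <- function(values) {
  if (length(values) == 0L) stop("no observations")
  if (any(!is.finite(values)) || any(values < 0)) stop("invalid lifespan")
  days <- as.integer(round(values))      # round() is half-to-even
  lo <- min(days); hi <- max(days)
  counts <- tabulate(days - lo + 1L, nbins = hi - lo + 1L)
  ddist(counts / length(days), origin = lo)
}

#' @export
print.ddist <- function(x, ...) {
  m <- ddist_moments(x)
  cat(sprintf(
    "<ddist> %d support points on days %d..%d (step %d)\n  mean %.4f  variance %.4f\n",
    length(x$pmf), x$origin, x$origin + (length(x$pmf) - 1L) * x$step_days,
    x$step_days, m[["mean"]], m[["variance"]]
  ))
  invisible(x)
}

#' @export
as.data.frame.ddist <- function(x, ...) {
  data.frame(day = support_days(x), probability = x$pmf)
}

#' Support of a discrete distribution, in days
#' @param d A [ddist].
#' @return Numeric vector of the grid day values carrying mass.
#' @export
support_days <- function(d) {
  stopifnot(inherits(d, "ddist"))
  d$origin + (seq_along(d$pmf) - 1) * d$step_days
}

# Direct dense convolution; loops over the shorter operand so cost is
# O(min(na, nb) vectorized adds of the longer length).
conv_direct <- function(a, b) {
  if (length(b) < length(a)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a) + length(b) - 1L)
  nb <- length(b)
  for (i in seq_along(a)) {
    idx <- i:(i + nb - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# FFT-accelerated convolution, zero-padded to a highly composite length so the
# transform stays O(N log N). Round-off can leave tiny negatives, which are
# clipped and the mass renormalized. Agreement with conv_direct is a tested
# invariant.
conv_fft <- function(a, b) {
  n_out <- length(a) + length(b) - 1L
  n_pad <- stats::nextn(n_out, c(2L, 3L, 5L))
  fa <- stats::fft(c(a, numeric(n_pad - length(a))))
  fb <- stats::fft(c(b, numeric(n_pad - length(b))))
  out <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n_out)] / n_pad
  neg <- out < 0
  if (any(out[neg] < -1e-9)) stop("FFT convolution produced a large negative mass")
  out[neg] <- 0
  out / sum(out)
}

#' Convolution of two discrete distributions
#'
#' Distribution of the sum of independent draws from `a` and `b`. The `"auto"`
#' method uses the direct dense path for small problems and the FFT path
#' (validated against the direct path) for large ones.
#'
#' @param a,b [ddist] objects on the same grid step.
#' @param method `"auto"`, `"direct"` or `"fft"`.
#' @return A [ddist] with `origin = a$origin + b$origin`.
#' @examples
#' coin <- ddist(c(0.5, 0.5), origin = 0)
#' ddist_convolve(coin, coin)  # 0.25, 0.5, 0.25 on 0..2
#' @export
ddist_convolve <- function(a, b, method = c("auto", "direct", "fft")) {
  stopifnot(inherits(a, "ddist"), inherits(b, "ddist"))
  method <- match.arg(method)
  if (a$step_days != b$step_days) stop("incompatible grids")
  if (method == "auto") {
    method <- if (as.double(length(a$pmf)) * length(b$pmf) <= 1e6) "direct" else "fft"
  }
  out <- switch(method,
    direct = conv_direct(a$pmf, b$pmf),
    fft = conv_fft(a$pmf, b$pmf)
  )
  ddist(out / sum(out), origin = a$origin + b$origin, step_days = a$step_days)
}

#' n-fold convolution: distribution of the sum of n i.i.d. draws
#'
#' Computed by binary exponentiation over [ddist_convolve], so `n = 60` costs
#' about `2 log2(n)` convolutions rather than `n - 1`.
#'
#' @param d A [ddist].
#' @param n Positive integer number of draws.
#' @param method Convolution backend, see [ddist_convolve].
#' @return The [ddist] of the sum; its mean is `n * mean(d)` and its variance
#'   `n * var(d)` (a tested invariant).
#' @export
ddist_nfold <- function(d, n, method = c("auto", "direct", "fft")) {
  stopifnot(inherits(d, "ddist"))
  method <- match.arg(method)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) stop("invalid fold count")
  n <- as.integer(n)
  result <- NULL
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- if (is.null(result)) base else ddist_convolve(result, base, method)
    }
    n <- n %/% 2L
    if (n > 0L) base <- ddist_convolve(base, base, method)
  }
  result
}

#' Mean and variance of a discrete distribution
#' @param d A [ddist].
#' @return Named numeric vector `c(mean = , variance = )` in days and days^2.
#' @export
ddist_moments <- function(d) {
  stopifnot(inherits(d, "ddist"))
  x <- support_days(d)
  m <- sum(x * d$pmf)
  v <- sum((x - m)^2 * d$pmf)
  c(mean = m, variance = v)
}

#' Inclusive tail probability
#'
#' `side = "upper"` returns `P(X >= x)`, `side = "lower"` returns `P(X <= x)`;
#' mass exactly at the boundary is always included ("the same or more
#' extreme"). Support days are exact integers so no floating-point fuzz is
#' applied to the comparison.
#'
#' @param d A [ddist].
#' @param x Threshold (days).
#' @param side `"upper"` or `"lower"`.
#' @return A probability in `[0, 1]`.
#' @export
ddist_tail_prob <- function(d, x, side = c("upper", "lower")) {
  stopifnot(inherits(d, "ddist"), is.numeric(x), length(x) == 1L, is.finite(x))
  side <- match.arg(side)
  days <- support_days(d)
  p <- if (side == "upper") sum(d$pmf[days >= x]) else sum(d$pmf[days <= x])
  min(max(p, 0), 1)
}
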