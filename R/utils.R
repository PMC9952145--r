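#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish failure modes.
abort_ppg <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ppg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Locate local maxima with a prominence threshold
#'
#' A peak's prominence is its height above the higher of the two minima
#' separating it from taller terrain on either side (or from the signal
#' boundary). Plateaus count once, at their first index.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence for a peak to be reported.
#' @return integer vector of peak indices, increasing.
#' @keywords internal
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse exact plateaus so sign changes are detectable
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  cand <- which(s[-1] < 0 & s[-length(s)] > 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, peak_prominence, numeric(1), x = x)
  cand[prom >= min_prominence]
}

peak_prominence <- function(x, i) {
  h <- x[i]
  # walk left until strictly higher ground or boundary, tracking the minimum
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  rmin <- h
  j <- i + 1L
  while (j <= length(x) && x[j] <= h) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  h - max(lmin, rmin)
}

#' Locate local minima with a prominence threshold
#' @keywords internal
find_troughs <- function(x, min_prominence = 0) {
  find_peaks(-x, min_prominence = min_prominence)
}

## Parabolic refinement of an extremum found on a uniform grid: fit a
## quadratic through (i-1, i, i+1) and return the sub-grid vertex.
refine_extremum <- function(tt, yy, i) {
  n <- length(yy)
  if (i <= 1L || i >= n) return(list(t = tt[i], y = yy[i]))
  y1 <- yy[i - 1L]; y2 <- yy[i]; y3 <- yy[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps) return(list(t = tt[i], y = yy[i]))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 1), -1)
  h <- tt[2] - tt[1]
  list(t = tt[i] + delta * h,
       y = y2 - 0.25 * (y1 - y3) * delta)
}

## Sample variance with the n-1 denominator, NA-dropping; NA if < 2 values.
sample_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::var(x)
}

sample_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean(x)
}
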