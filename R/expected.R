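#' Distance-decay expected profile P(s)
#'
#' Estimates the expected contact value as a function of bin separation:
#' `P(s)` is the mean over all unmasked bin pairs `(i, j)` with
#' `|i - j| == s` (each unordered pair counted once, the diagonal included at
#' `s = 0`). Separations with no unmasked pair are `NA` (undefined). On a map
#' whose values depend only on `|i - j|` the estimate is exact.
#'
#' An optional log-spaced smoothing pools sparse long-range separations into
#' geometrically growing windows; it is off by default and flagged in the
#' output.
#'
#' @param map a normalized [contact_map()].
#' @param smooth logical; apply log-spaced smoothing (default `FALSE`).
#' @param smooth_base window growth factor when smoothing (> 1).
#' @return an object of class `expected_profile`: list with `grid`, `values`
#'   (`P(s)` for `s = 0 .. n_bins-1`), `n_pairs` per separation, and
#'   `smoothed` flag.
#' @export
estimate_expected <- function(map, smooth = FALSE, smooth_base = 1.25) {
  stopifnot(inherits(map, "contact_map"))
  n <- map$grid$n_bins
  ok <- !map$masked
  if (!any(ok))
    stop("map is fully masked; expected profile undefined")
  v <- map$values
  p <- rep(NA_real_, n)
  np <- integer(n)
  okn <- as.numeric(ok)
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    j <- i + s
    w <- okn[i] * okn[j]
    cnt <- sum(w)
    np[s + 1] <- cnt
    if (cnt > 0)
      p[s + 1] <- sum(v[cbind(i, j)] * w) / cnt
  }
  if (smooth) {
    sm <- p
    s <- 1
    while (s < n) {
      hi <- min(n, max(s + 1, ceiling(s * smooth_base)))
      win <- (s + 1):hi                 # indices for separations s .. hi-1
      wts <- np[win]
      if (sum(wts) > 0)
        sm[win] <- sum(p[win] * wts, na.rm = TRUE) / sum(wts[!is.na(p[win])])
      s <- hi
    }
    p <- sm
  }
  structure(list(grid = map$grid, values = p, n_pairs = np,
                 smoothed = smooth),
            class = "expected_profile")
}

#' @export
print.expected_profile <- function(x, ...) {
  def <- sum(!is.na(x$values))
  cat(sprintf("<expected_profile> %s | defined at %d/%d separations%s\n",
              format(x$grid), def, length(x$values),
              if (x$smoothed) " | smoothed" else ""))
  cat(sprintf("  P(0)=%.4g  P(1)=%.4g  P(%d)=%.4g\n",
              x$values[1], x$values[2], def - 1, x$values[def]))
  invisible(x)
}

#' @export
plot.expected_profile <- function(x, ...) {
  s <- seq_along(x$values) - 1
  graphics::plot(s[-1], x$values[-1], log = "xy", type = "l",
                 xlab = "separation s (bins)", ylab = "P(s)", ...)
  invisible(x)
}

## P evaluated at separation s (bins, >= 0); NA outside profile support
expected_at <- function(expected, s) {
  out <- rep(NA_real_, length(s))
  inr <- s >= 0 & s < length(expected$values)
  out[inr] <- expected$values[s[inr] + 1]
  out
}
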