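#' Differential contact-enrichment statistic D(k, f)
#'
#' For every bin `k`, `D(k, f)` is the arithmetic mean of natural-log ratios
#' `log(V[i,j] / V*[i,j])` over the pairs spanning `k` within a window of `f`
#' bins on each side — `i` in `[k-f, k)` and `j` in `(k, k+f]` (0-based bin
#' arithmetic; windows are truncated at the chromosome ends) — restricted to
#' pairs where both values are positive. `V` is the observed map and `V*` the
#' liftover-derived null prediction. Before taking ratios, both maps are
#' scaled to a common total (the mean of their totals over jointly positive
#' pairs), so a sequencing-depth difference does not shift every `D` by a
#' constant. The defined `D` values are then Z-score transformed across all
#' `k`; a gain of cross-`k` contacts in the observed map gives positive `Z`.
#' If the defined `D` values have zero variance (e.g. identical inputs), `Z`
#' is reported as all-zero rather than NaN.
#'
#' @param observed observed [contact_map()].
#' @param liftovered null-prediction [contact_map()] on the same grid with
#'   the same normalization state.
#' @param f window half-width in bins (`>= 1`, `< n_bins`). The default 20
#'   corresponds to 100 kb at 5 kb resolution.
#' @return an object of class `diff_insulation_track`: list with `grid`, `f`,
#'   per-bin `d` (NA where no valid pair), `z`, `n_pairs`, and the
#'   `scale_factors` applied to the two maps.
#' @export
d_score <- function(observed, liftovered, f = 20) {
  check_same_grid(observed, liftovered)
  n <- observed$grid$n_bins
  f <- as.integer(f)
  if (f < 1) stop("f must be >= 1")
  if (f >= n) stop("f must be smaller than the number of bins (", n, ")")
  va <- observed$values
  vb <- liftovered$values
  pos <- va > 0 & vb > 0
  if (!any(pos)) stop("no pair is positive in both maps")
  ta <- sum(va[pos]); tb <- sum(vb[pos])
  target <- (ta + tb) / 2
  sa <- target / ta; sb <- target / tb
  lr <- matrix(NA_real_, n, n)
  lr[pos] <- log((va[pos] * sa) / (vb[pos] * sb))
  d <- rep(NA_real_, n)
  npairs <- integer(n)
  for (k in seq_len(n)) {
    if (k == 1L || k == n) next      # a side window is empty
    i <- max(1L, k - f):(k - 1L)
    j <- (k + 1L):min(n, k + f)
    sub <- lr[i, j, drop = FALSE]
    m <- sum(!is.na(sub))
    npairs[k] <- m
    if (m > 0) d[k] <- mean(sub, na.rm = TRUE)
  }
  def <- !is.na(d)
  z <- rep(NA_real_, n)
  if (any(def)) {
    mu <- mean(d[def])
    sdv <- stats::sd(d[def])
    z[def] <- if (sum(def) >= 2 && sdv > 0) (d[def] - mu) / sdv else 0
  }
  structure(list(grid = observed$grid, f = f, d = d, z = z,
                 n_pairs = npairs,
                 scale_factors = c(observed = sa, liftovered = sb)),
            class = "diff_insulation_track")
}

#' @export
print.diff_insulation_track <- function(x, ...) {
  def <- sum(!is.na(x$d))
  cat(sprintf("<diff_insulation_track> %s | f=%d bins | D defined at %d/%d bins\n",
              format(x$grid), x$f, def, x$grid$n_bins))
  if (def)
    cat(sprintf("  Z range [%.3f, %.3f] | max |Z| at bin %d (%s:%0.f)\n",
                min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE),
                which.max(abs(x$z)), x$grid$chrom,
                bin_starts(x$grid)[which.max(abs(x$z))]))
  invisible(x)
}

#' @export
summary.diff_insulation_track <- function(object, z_threshold = 2, ...) {
  calls <- call_insulation_changes(object, z_threshold)
  cat(sprintf("D(k,f) track, f = %d bins (%g kb window each side)\n",
              object$f, object$f * object$grid$bin_size / 1000))
  cat(sprintf("scale factors: observed %.4g, liftovered %.4g\n",
              object$scale_factors[1], object$scale_factors[2]))
  cat(sprintf("%d insulation-change call(s) at |Z| >= %g\n",
              nrow(calls), z_threshold))
  if (nrow(calls)) print(calls)
  invisible(calls)
}

#' @export
plot.diff_insulation_track <- function(x, z_threshold = 2, ...) {
  graphics::plot(bin_starts(x$grid), x$z, type = "h",
                 xlab = x$grid$chrom, ylab = "Z(D)", ...)
  graphics::abline(h = c(-z_threshold, z_threshold), lty = 2, col = "grey40")
  invisible(x)
}

#' Call insulation-change intervals from a Z track
#'
#' Merges maximal runs of contiguous bins with `|Z| >= z_threshold` and
#' constant sign into BED-style intervals; each call carries the peak
#' (signed, extreme) Z and a gain/loss label (gain = more cross-boundary
#' contacts in the observed map than the distance-only null predicts, i.e.
#' lost insulation).
#'
#' @param track a [d_score()] result.
#' @param z_threshold absolute Z threshold (default 2).
#' @return data.frame with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `peak_z`, `sign` (`"gain"`/`"loss"`), `n_bins`.
#' @export
call_insulation_changes <- function(track, z_threshold = 2) {
  z <- track$z
  state <- ifelse(is.na(z) | abs(z) < z_threshold, 0L, ifelse(z > 0, 1L, -1L))
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    peak_z = numeric(), sign = character(),
                    n_bins = integer(), stringsAsFactors = FALSE)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g <- track$grid
  for (q in which(r$values != 0L)) {
    bins <- starts[q]:ends[q]
    pk <- z[bins][which.max(abs(z[bins]))]
    out[nrow(out) + 1L, ] <- list(g$chrom, bin_starts(g)[starts[q]],
                                  bin_ends(g)[ends[q]], pk,
                                  if (r$values[q] > 0) "gain" else "loss",
                                  length(bins))
  }
  out
}

#' Export a Z track as bedGraph
#'
#' One bedGraph line per bin where `D(k, f)` is defined, carrying the Z
#' score; undefined bins are omitted. A `track type=bedGraph` header line is
#' always written.
#'
#' @param track a [d_score()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
enrichment_track_export <- function(track, path) {
  write_bedgraph(track$grid, ifelse(is.na(track$d), NA_real_, track$z),
                 path, name = sprintf("Z_D_f%d", track$f))
}
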