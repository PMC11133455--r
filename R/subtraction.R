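#' Subtraction map between two depth-matched contact maps
#'
#' Scales both maps to a common total over bins valid in both (the arithmetic
#' mean of the two totals, so that swapping the inputs exactly negates the
#' result), optionally aggregates to a coarser bin size by summation, and
#' returns the signed difference `observed - liftovered`. Gains in the
#' observed map are positive, losses negative.
#'
#' @param observed,liftovered two [contact_map()]s on the same grid with the
#'   same normalization state.
#' @param out_bin_size output bin size in bp; must be an integer multiple of
#'   the input bin size (default: no coarsening).
#' @return an object of class `subtraction_map`: list with the coarse `grid`,
#'   the signed `values` matrix, per-bin `masked` flags, and the two
#'   `scale_factors` applied.
#' @export
subtraction_map <- function(observed, liftovered,
                            out_bin_size = observed$grid$bin_size) {
  check_same_grid(observed, liftovered)
  g <- observed$grid
  fac <- out_bin_size / g$bin_size
  if (fac != round(fac) || fac < 1)
    stop("out_bin_size must be an integer multiple of the input bin size")
  fac <- as.integer(fac)
  both_ok <- !(observed$masked | liftovered$masked)
  ta <- sum(observed$values[both_ok, both_ok])
  tb <- sum(liftovered$values[both_ok, both_ok])
  if (ta <= 0 || tb <= 0)
    stop("cannot scale: a map has zero total over jointly valid bins")
  target <- (ta + tb) / 2
  sa <- target / ta
  sb <- target / tb
  va <- observed$values * sa
  vb <- liftovered$values * sb
  va[!both_ok, ] <- 0; va[, !both_ok] <- 0
  vb[!both_ok, ] <- 0; vb[, !both_ok] <- 0
  diffm <- va - vb
  grp <- (seq_len(g$n_bins) - 1L) %/% fac + 1L
  if (fac > 1L) {
    diffm <- t(rowsum(t(rowsum(diffm, grp)), grp))
    masked_out <- as.logical(tapply(!both_ok, grp, all))
  } else {
    masked_out <- !both_ok
  }
  out_grid <- bin_grid(g$chrom, g$chrom_length, out_bin_size)
  dimnames(diffm) <- NULL
  structure(list(grid = out_grid, values = diffm, masked = masked_out,
                 scale_factors = c(observed = sa, liftovered = sb)),
            class = "subtraction_map")
}

#' @export
print.subtraction_map <- function(x, ...) {
  cat(sprintf("<subtraction_map> %s | %d bins | range [%.4g, %.4g]\n",
              format(x$grid), x$grid$n_bins, min(x$values), max(x$values)))
  cat(sprintf("  scale factors: observed=%.4g liftovered=%.4g\n",
              x$scale_factors[1], x$scale_factors[2]))
  invisible(x)
}

#' @export
plot.subtraction_map <- function(x, zlim = NULL, ...) {
  v <- x$values
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(v))
  graphics::image(bin_starts(x$grid), bin_starts(x$grid), v, zlim = zlim,
                  useRaster = TRUE, xlab = x$grid$chrom, ylab = x$grid$chrom,
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}
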