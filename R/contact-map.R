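#' Binned contact map
#'
#' Container for a symmetric, non-negative matrix of contact values over a
#' [bin_grid()], with a per-bin validity mask, a normalization state and a
#' role tag distinguishing observed maps from liftover-derived null
#' predictions. Masked bins always carry all-zero rows and columns.
#'
#' @param grid a [bin_grid()].
#' @param values symmetric numeric matrix, `n_bins x n_bins`, finite, >= 0.
#' @param masked logical vector of length `n_bins`; `TRUE` marks bins with no
#'   usable signal (e.g. the deleted interval of a mutant map expressed in
#'   reference coordinates). Rows/columns of masked bins are zeroed.
#' @param normalization `"raw"` or `"vc_sqrt"`.
#' @param role `"observed"` or `"liftovered"`.
#' @param genome free-text genome/assembly label used for liftover direction
#'   bookkeeping (composing a liftover whose synteny source label differs
#'   from the map's label is an error).
#' @return an object of class `contact_map`.
#' @seealso [read_contact_map()], [vc_sqrt_normalize()], [estimate_expected()]
#' @export
contact_map <- function(grid, values,
                        masked = rep(FALSE, grid$n_bins),
                        normalization = c("raw", "vc_sqrt"),
                        role = c("observed", "liftovered"),
                        genome = "ref") {
  normalization <- match.arg(normalization)
  role <- match.arg(role)
  stopifnot(inherits(grid, "bin_grid"))
  values <- as.matrix(values)
  n <- grid$n_bins
  if (!all(dim(values) == c(n, n)))
    stop("values must be a ", n, " x ", n, " matrix for this grid")
  if (!all(is.finite(values)))
    stop("contact values must be finite")
  if (any(values < 0))
    stop("contact values must be non-negative")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("contact values must be symmetric")
  values <- (values + t(values)) / 2   # enforce exact symmetry
  masked <- as.logical(masked)
  stopifnot(length(masked) == n)
  if (any(masked)) {
    values[masked, ] <- 0
    values[, masked] <- 0
  }
  dimnames(values) <- NULL
  structure(list(grid = grid, values = values, masked = masked,
                 normalization = normalization, role = role,
                 genome = genome),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s | %d bins | %s | role=%s | genome=%s\n",
              format(x$grid), x$grid$n_bins, x$normalization, x$role,
              x$genome))
  cat(sprintf("  total=%.6g | masked bins=%d | max=%.6g\n",
              sum(x$values), sum(x$masked), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.contact_map <- function(x, ...) x$values

#' @export
plot.contact_map <- function(x, log = TRUE, ...) {
  v <- x$values
  if (log) v <- log10(v + 1)
  graphics::image(bin_starts(x$grid), bin_starts(x$grid), v,
                  useRaster = TRUE, xlab = x$grid$chrom, ylab = x$grid$chrom,
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE), ...)
  invisible(x)
}

## internal: check two maps are comparable
check_same_grid <- function(a, b) {
  if (!grids_equal(a$grid, b$grid))
    stop("contact maps are on different grids")
  if (a$normalization != b$normalization)
    stop("contact maps have different normalization states (",
         a$normalization, " vs ", b$normalization, ")")
  invisible(TRUE)
}
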