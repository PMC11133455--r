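#' Binned genome grid
#'
#' A `bin_grid` tiles one chromosome (or an extracted capture region treated
#' as its own coordinate system) with fixed-size bins. All coordinates are
#' 0-based, half-open, BED-compatible; bin `i` (1-based index) covers
#' `[(i-1) * bin_size, min(i * bin_size, chrom_length))`. The last bin may be
#' partial.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome (or region) length in bp.
#' @param bin_size bin width in bp, e.g. 5000.
#' @return an object of class `bin_grid` with fields `chrom`, `chrom_length`,
#'   `bin_size` and `n_bins == ceiling(chrom_length / bin_size)`.
#' @examples
#' g <- bin_grid("chr5", 2275000, 5000)
#' g$n_bins   # 455
#' @export
bin_grid <- function(chrom, chrom_length, bin_size) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(chrom_length), chrom_length > 0,
            is.numeric(bin_size), bin_size > 0)
  structure(list(chrom = chrom,
                 chrom_length = as.numeric(chrom_length),
                 bin_size = as.numeric(bin_size),
                 n_bins = as.integer(ceiling(chrom_length / bin_size)),
                 coords = "0-based half-open"),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s:0-%s | bin %s bp | %d bins (%s)\n",
              x$chrom, format(x$chrom_length, big.mark = ","),
              format(x$bin_size, big.mark = ","), x$n_bins, x$coords))
  invisible(x)
}

#' @export
format.bin_grid <- function(x, ...) {
  sprintf("%s:0-%g/%g", x$chrom, x$chrom_length, x$bin_size)
}

grids_equal <- function(a, b) {
  a$chrom == b$chrom && a$chrom_length == b$chrom_length &&
    a$bin_size == b$bin_size
}

#' Bin start coordinates of a grid
#'
#' @param grid a [bin_grid()].
#' @return numeric vector of 0-based bin start positions (bp).
#' @export
bin_starts <- function(grid) {
  (seq_len(grid$n_bins) - 1) * grid$bin_size
}

#' Bin end coordinates of a grid (half-open, clipped at chromosome end)
#' @inheritParams bin_starts
#' @return numeric vector of bin end positions (bp).
#' @export
bin_ends <- function(grid) {
  pmin(seq_len(grid$n_bins) * grid$bin_size, grid$chrom_length)
}

## bp position -> 1-based bin index (position must lie in [0, chrom_length))
pos_to_bin <- function(grid, pos) {
  as.integer(pos %/% grid$bin_size) + 1L
}

#' Parse a genome-browser region string
#'
#' Region strings such as `"chr5:74,135,000-76,410,000"` follow the browser
#' convention of 1-based inclusive coordinates; they are converted to the
#' package's internal 0-based half-open convention.
#'
#' @param region a string `chrom:start-end` (commas allowed).
#' @return list with `chrom`, `start`, `end` (0-based half-open) and
#'   `length = end - start`.
#' @examples
#' parse_region("chr5:74,135,000-76,410,000")$length  # 2275001
#' @export
parse_region <- function(region) {
  region <- gsub(",", "", region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string: ", region)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (start1 < 1 || end1 < start1)
    stop("invalid region coordinates: ", region)
  list(chrom = m[2], start = start1 - 1, end = end1,
       length = end1 - (start1 - 1))
}
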