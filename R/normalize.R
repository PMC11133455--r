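#' Vanilla-coverage square-root (VC_SQRT) normalization
#'
#' Balances a raw contact map by dividing each entry by the square roots of
#' its two bin marginals, `W[i,j] = V[i,j] / sqrt(r_i * r_j)` with `r_i` the
#' row sum of `V` over unmasked bins, then rescales by one global constant so
#' the total matrix sum is preserved. Bins with zero marginal are masked in
#' the output and their rows/columns zeroed.
#'
#' Total-sum preservation is this package's scale convention: it keeps
#' normalized maps, and the subtraction maps derived from them, in count-like
#' units.
#'
#' @param map a raw [contact_map()] with at least one positive value.
#' @return a [contact_map()] tagged `normalization = "vc_sqrt"`.
#' @examples
#' g <- bin_grid("chrT", 10000, 5000)
#' m <- contact_map(g, matrix(c(4, 2, 2, 1), 2))
#' vc_sqrt_normalize(m)$values
#' @export
vc_sqrt_normalize <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (map$normalization != "raw")
    stop("map is already normalized (", map$normalization,
         "); refusing to normalize twice")
  v <- map$values
  total <- sum(v)
  if (total <= 0)
    stop("map has no positive values")
  r <- rowSums(v)          # masked bins already have zero rows
  masked <- map$masked | r == 0
  sr <- sqrt(r)
  sr[sr == 0] <- Inf       # zero-marginal bins -> zero after division
  w <- v / (sr %o% sr)
  w[masked, ] <- 0
  w[, masked] <- 0
  w <- w * (total / sum(w))
  contact_map(map$grid, w, masked = masked, normalization = "vc_sqrt",
              role = map$role, genome = map$genome)
}
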