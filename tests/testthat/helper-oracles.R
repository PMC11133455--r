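# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/aggregated code paths: liftover is enumerated at base-pair
# resolution, D(k,f) with a plain double loop, and the Mann-Whitney null by
# full arrangement enumeration.

# Per-entry VC_SQRT formula, then global rescale to the input total.
oracle_vc_sqrt <- function(v) {
  r <- rowSums(v)
  n <- nrow(v)
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (r[i] > 0 && r[j] > 0) w[i, j] <- v[i, j] / sqrt(r[i] * r[j])
  w * sum(v) / sum(w)
}

# Mean over unordered unmasked pairs at each separation.
oracle_expected <- function(v, masked = rep(FALSE, nrow(v))) {
  n <- nrow(v)
  p <- rep(NA_real_, n)
  for (s in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - s)) {
      j <- i + s
      if (!masked[i] && !masked[j]) vals <- c(vals, v[i, j])
    }
    if (length(vals)) p[s + 1] <- mean(vals)
  }
  p
}

# bp -> bp coordinate map implied by a synteny map (NA where unmapped).
oracle_bp_map <- function(synteny, src_len) {
  out <- rep(NA_real_, src_len)
  for (b in seq_len(nrow(synteny$blocks))) {
    blk <- synteny$blocks[b, ]
    xs <- blk$src_start:(blk$src_end - 1)
    ys <- if (blk$orientation == "+")
      blk$tgt_start + (xs - blk$src_start)
    else blk$tgt_end - 1 - (xs - blk$src_start)
    out[xs + 1] <- ys
  }
  out
}

# Base-pair-level liftover enumeration. For every ordered bp pair (x, y) the
# source-pair value density V[i,j] / (w_i * w_j) is deposited at the target
# bin pair, optionally rescaled by P(|a-b|) / P(|i-j|) (balanced model).
oracle_liftover <- function(v, synteny, src_grid, tgt_grid,
                            expected = NULL, src_masked = NULL) {
  n_s <- src_grid$n_bins; n_t <- tgt_grid$n_bins
  if (is.null(src_masked)) src_masked <- rep(FALSE, n_s)
  bp <- oracle_bp_map(synteny, src_grid$chrom_length)
  width <- bin_ends(src_grid) - bin_starts(src_grid)
  # mapped base pairs, their source and target bins
  xs <- which(!is.na(bp)) - 1
  i_of <- xs %/% src_grid$bin_size + 1
  a_of <- bp[xs + 1] %/% tgt_grid$bin_size + 1
  live <- !src_masked[i_of]
  xs <- xs[live]; i_of <- i_of[live]; a_of <- a_of[live]
  out <- matrix(0, n_t, n_t)
  exp_at <- function(s) {  # P at bin separation s, NA outside support
    p <- rep(NA_real_, length(s))
    ok <- s < length(expected)
    p[ok] <- expected[s[ok] + 1]
    p
  }
  for (q in seq_along(xs)) {   # one source bp against all mapped bps
    i <- i_of[q]; a <- a_of[q]
    contrib <- v[i, i_of] / (width[i] * width[i_of])
    if (!is.null(expected)) {
      ratio <- exp_at(abs(a - a_of)) / exp_at(abs(i - i_of))
      ratio[!is.finite(ratio)] <- 0
      contrib <- contrib * ratio
    }
    acc <- rowsum(contrib, a_of)
    out[a, as.integer(rownames(acc))] <-
      out[a, as.integer(rownames(acc))] + as.numeric(acc)
  }
  out
}

# Plain double-loop D(k, f) with the same mutual-scaling contract.
oracle_dscore <- function(va, vb, f) {
  n <- nrow(va)
  pos <- va > 0 & vb > 0
  target <- (sum(va[pos]) + sum(vb[pos])) / 2
  va <- va * target / sum(va[pos])
  vb <- vb * target / sum(vb[pos])
  d <- rep(NA_real_, n)
  for (k in 1:n) {
    vals <- c()
    for (i in 1:n) for (j in 1:n) {
      # 0-based window: i0 in [k0-f, k0), j0 in (k0, k0+f]
      i0 <- i - 1; j0 <- j - 1; k0 <- k - 1
      if (i0 >= k0 - f && i0 < k0 && j0 > k0 && j0 <= k0 + f &&
          va[i, j] > 0 && vb[i, j] > 0)
        vals <- c(vals, log(va[i, j] / vb[i, j]))
    }
    if (length(vals)) d[k] <- mean(vals)
  }
  d
}

# Exact two-tailed Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled values.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  centre <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# Random small contact map (distance-decayed Poisson counts, all bins live).
random_toy_map <- function(grid, seed, normalization = "vc_sqrt") {
  set.seed(seed)
  n <- grid$n_bins
  e <- 50 / (1 + abs(outer(1:n, 1:n, "-")))
  v <- matrix(0, n, n)
  ut <- upper.tri(v, diag = TRUE)
  v[ut] <- rpois(sum(ut), e[ut]) + 1   # +1 keeps every bin live
  v <- v + t(v) - diag(diag(v))
  contact_map(grid, v, normalization = normalization, genome = "src")
}

# Random 2-3 block synteny map between genomes of given lengths, block
# boundaries aligned to `align` bp, optionally with inverted blocks.
random_synteny <- function(src_len, seed, align = 10, allow_invert = TRUE) {
  set.seed(seed)
  n_blocks <- sample(2:3, 1)
  # partition source into blocks with gaps, all multiples of align
  units <- src_len %/% align
  cuts <- sort(sample(1:(units - 1), 2 * n_blocks - 1))
  bounds <- c(0, cuts, units) * align
  starts <- bounds[seq(1, by = 2, length.out = n_blocks)]
  ends <- bounds[seq(2, by = 2, length.out = n_blocks)]
  lens <- ends - starts
  tgt_gap <- sample(0:3, n_blocks, replace = TRUE) * align
  tgt_starts <- cumsum(tgt_gap) + c(0, cumsum(lens))[seq_len(n_blocks)]
  ori <- if (allow_invert) sample(c("+", "-"), n_blocks, replace = TRUE)
         else rep("+", n_blocks)
  synteny_map(data.frame(src_chrom = "chrT", src_start = starts,
                         src_end = ends, tgt_chrom = "chrT",
                         tgt_start = tgt_starts,
                         tgt_end = tgt_starts + lens,
                         orientation = ori),
              source_genome = "src", target_genome = "tgt")
}
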