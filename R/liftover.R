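## Bin-to-bin weight table implied by a synteny map.
##
## Each source bin is intersected with every block; the covered segment is
## mapped into target coordinates (reversed for inverted blocks) and
## distributed over the target bins it overlaps, weighted by the fraction of
## the source bin it represents. With equal bin sizes a mapped segment spans
## at most two target bins. Returns data.frame(src, tgt, w).
synteny_bin_weights <- function(synteny, src_grid, tgt_grid) {
  if (src_grid$bin_size != tgt_grid$bin_size)
    stop("bin size mismatch between source and target grids")
  bs <- src_grid$bin_size
  src_lo <- bin_starts(src_grid)
  src_hi <- bin_ends(src_grid)
  width <- src_hi - src_lo
  rows <- vector("list", nrow(synteny$blocks) * 4L)
  nr <- 0L
  for (b in seq_len(nrow(synteny$blocks))) {
    blk <- synteny$blocks[b, ]
    first <- max(1L, pos_to_bin(src_grid, blk$src_start))
    last <- min(src_grid$n_bins, pos_to_bin(src_grid, blk$src_end - 1))
    if (last < first) next
    i <- first:last
    ov_lo <- pmax(src_lo[i], blk$src_start)
    ov_hi <- pmin(src_hi[i], blk$src_end)
    keep <- ov_hi > ov_lo
    i <- i[keep]; ov_lo <- ov_lo[keep]; ov_hi <- ov_hi[keep]
    if (!length(i)) next
    if (blk$orientation == "+") {
      t_lo <- blk$tgt_start + (ov_lo - blk$src_start)
      t_hi <- blk$tgt_start + (ov_hi - blk$src_start)
    } else {
      t_lo <- blk$tgt_end - (ov_hi - blk$src_start)
      t_hi <- blk$tgt_end - (ov_lo - blk$src_start)
    }
    # split each mapped segment over the (<= 2) target bins it overlaps
    for (part in 1:2) {
      b1 <- as.integer(t_lo %/% bs) + part
      cut_lo <- pmax(t_lo, (b1 - 1) * bs)
      cut_hi <- pmin(t_hi, b1 * bs)
      keep2 <- cut_hi > cut_lo & b1 >= 1L & b1 <= tgt_grid$n_bins
      if (any(keep2)) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(src = i[keep2], tgt = b1[keep2],
                                 w = (cut_hi - cut_lo)[keep2] /
                                   width[i[keep2]])
      }
    }
  }
  if (nr == 0L)
    return(data.frame(src = integer(), tgt = integer(), w = numeric()))
  out <- do.call(rbind, rows[seq_len(nr)])
  # collapse duplicates from the two-part split
  key <- paste(out$src, out$tgt)
  if (anyDuplicated(key)) {
    agg <- rowsum(out$w, key)
    sp <- do.call(rbind, strsplit(rownames(agg), " "))
    out <- data.frame(src = as.integer(sp[, 1]), tgt = as.integer(sp[, 2]),
                      w = as.numeric(agg))
  }
  out[order(out$src, out$tgt), , drop = FALSE]
}

check_liftover_direction <- function(map, synteny) {
  if (!identical(map$genome, synteny$source_genome))
    stop("direction mismatch: map genome '", map$genome,
         "' is not the synteny source genome '", synteny$source_genome, "'")
}

#' Coordinate-only ("easy") liftover of binned contacts
#'
#' Remaps contact values from a source to a target genome through a synteny
#' map. Each source bin's signal is reassigned to the target bins it maps to,
#' with overlap-fraction weighting; inverted blocks reverse orientation.
#' Values are **not** rescaled, so total contact mass over fully mapped pairs
#' is conserved. Target bins receiving no signal from any unmasked source bin
#' (e.g. the deleted interval when mapping mutant to reference) are masked.
#'
#' @param map a [contact_map()] whose `genome` matches the synteny source.
#' @param synteny a [synteny_map()].
#' @param target_grid the [bin_grid()] of the target genome (same bin size).
#' @return a [contact_map()] on `target_grid`, normalization and role
#'   preserved, `genome` set to the synteny target label.
#' @export
liftover_easy <- function(map, synteny, target_grid) {
  check_liftover_direction(map, synteny)
  wtab <- synteny_bin_weights(synteny, map$grid, target_grid)
  n_t <- target_grid$n_bins
  S <- matrix(0, map$grid$n_bins, n_t)
  S[cbind(wtab$src, wtab$tgt)] <- wtab$w
  S[map$masked, ] <- 0
  vout <- t(S) %*% map$values %*% S
  masked_out <- colSums(S) == 0
  contact_map(target_grid, vout, masked = masked_out,
              normalization = map$normalization, role = map$role,
              genome = synteny$target_genome)
}

#' Distance-decay-rescaled ("balanced") liftover
#'
#' As [liftover_easy()] for coordinates, but every remapped pair is
#' additionally multiplied by `P(s') / P(s)`, the ratio of the expected
#' contact value at its new (target) bin separation `s'` to that at its old
#' (source) separation `s`. This realizes the null model in which a deletion
#' affects chromatin architecture only by changing genomic distances: pairs
#' whose separation is unchanged keep their values exactly, while pairs drawn
#' closer gain contacts according to the distance decay. Pairs whose `P(s)`
#' is undefined or zero are dropped (set to zero).
#'
#' @param map a normalized [contact_map()] (`vc_sqrt`).
#' @param synteny a [synteny_map()] with source matching the map's genome.
#' @param expected the [estimate_expected()] profile of `map` itself.
#' @param target_grid target [bin_grid()] (same bin size).
#' @return a [contact_map()] on `target_grid` tagged `role = "liftovered"`.
#' @export
liftover_balanced <- function(map, synteny, expected, target_grid) {
  check_liftover_direction(map, synteny)
  if (map$normalization == "raw")
    stop("balanced liftover requires a normalized map")
  if (!grids_equal(expected$grid, map$grid))
    stop("expected profile grid mismatch")
  wtab <- synteny_bin_weights(synteny, map$grid, target_grid)
  wtab <- wtab[!map$masked[wtab$src], , drop = FALSE]
  n_t <- target_grid$n_bins
  vout <- matrix(0, n_t, n_t)
  masked_out <- rep(TRUE, n_t)
  if (nrow(wtab)) {
    masked_out[unique(wtab$tgt)] <- FALSE
    src <- wtab$src; tgt <- wtab$tgt; w <- wtab$w
    s_src <- abs(outer(src, src, "-"))
    s_tgt <- abs(outer(tgt, tgt, "-"))
    ps <- expected_at(expected, s_src)
    pt <- expected_at(expected, s_tgt)
    ratio <- pt / ps
    ratio[!is.finite(ratio)] <- 0      # P(s) zero/undefined -> drop pair
    contrib <- map$values[src, src, drop = FALSE] * (w %o% w) * ratio
    m1 <- rowsum(contrib, tgt)
    m2 <- rowsum(t(m1), tgt)
    ut <- sort(unique(tgt))
    vout[ut, ut] <- (m2 + t(m2)) / 2   # exact symmetry
  }
  contact_map(target_grid, vout, masked = masked_out,
              normalization = map$normalization, role = "liftovered",
              genome = synteny$target_genome)
}

#' Distance-only null prediction of a deletion's contact map
#'
#' Composes the study's null model for a deletion: estimate the wild-type
#' distance-decay profile, lift the wild-type contacts onto the deleted
#' genome under the balanced model (rescaling each pair by `P(s')/P(s)`),
#' then lift back to reference coordinates under the easy model. The result
#' `V*` is the contact map expected if the deletion acted *only* through
#' genomic distance, expressed in reference coordinates and masked over the
#' deleted interval — directly comparable to an observed mutant map mapped to
#' the reference.
#'
#' @param wt normalized wild-type [contact_map()] in reference coordinates.
#' @param deletion a [deletion_spec()].
#' @return a [contact_map()] on the wild-type grid, `role = "liftovered"`.
#' @export
simulate_wt_under_deletion <- function(wt, deletion) {
  stopifnot(inherits(wt, "contact_map"), inherits(deletion, "deletion_spec"))
  g <- wt$grid
  del_len <- deletion$end - deletion$start
  if (del_len >= g$chrom_length)
    stop("deletion removes the whole chromosome")
  syn <- deletion_to_synteny(deletion, g$chrom_length,
                             source_genome = wt$genome)
  mut_grid <- bin_grid(g$chrom, g$chrom_length - del_len, g$bin_size)
  expected <- estimate_expected(wt)
  bal <- liftover_balanced(wt, syn, expected, mut_grid)
  out <- liftover_easy(bal, invert_synteny(syn), g)
  out$role <- "liftovered"
  out
}
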