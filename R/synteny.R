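#' Deletion specification
#'
#' @param chrom chromosome name.
#' @param start,end deletion interval, 0-based half-open, `start < end`
#'   (`start == end` encodes a zero-length deletion, i.e. no change).
#' @param label free-text label (e.g. `"KitD30k"`).
#' @return object of class `deletion_spec`.
#' @export
deletion_spec <- function(chrom, start, end, label = "deletion") {
  stopifnot(start >= 0, end >= start)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), label = label),
            class = "deletion_spec")
}

#' @export
print.deletion_spec <- function(x, ...) {
  cat(sprintf("<deletion_spec> %s:%.0f-%.0f (%s, %.0f bp)\n",
              x$chrom, x$start, x$end, x$label, x$end - x$start))
  invisible(x)
}

#' Synteny map between two genomes
#'
#' An ordered set of aligned interval pairs. Each block aligns a source
#' interval to an equal-length target interval, either codirected (`+`) or
#' inverted (`-`). Source intervals must be pairwise non-overlapping, and
#' likewise target intervals, so the map is invertible.
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`, `src_end`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation` (`"+"`/`"-"`);
#'   coordinates 0-based half-open.
#' @param source_genome,target_genome genome labels used for direction
#'   bookkeeping in liftover.
#' @return object of class `synteny_map`.
#' @export
synteny_map <- function(blocks, source_genome = "source",
                        target_genome = "target") {
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start",
            "tgt_end", "orientation")
  stopifnot(all(need %in% names(blocks)))
  blocks <- blocks[, need]
  if (any(blocks$src_end <= blocks$src_start))
    stop("blocks must have start < end")
  if (any((blocks$src_end - blocks$src_start) !=
          (blocks$tgt_end - blocks$tgt_start)))
    stop("source and target block lengths differ")
  if (!all(blocks$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  check_disjoint <- function(s, e, what) {
    o <- order(s)
    if (any(s[o][-1] < e[o][-length(e)]))
      stop(what, " intervals overlap")
  }
  if (nrow(blocks) > 1) {
    check_disjoint(blocks$src_start, blocks$src_end, "source")
    check_disjoint(blocks$tgt_start, blocks$tgt_end, "target")
  }
  blocks <- blocks[order(blocks$src_start), ]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, source_genome = source_genome,
                 target_genome = target_genome),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat(sprintf("<synteny_map> %s -> %s | %d block(s)\n",
              x$source_genome, x$target_genome, nrow(x$blocks)))
  print(x$blocks)
  invisible(x)
}

#' Invert a synteny map (swap source and target)
#' @param map a [synteny_map()].
#' @return the inverse [synteny_map()].
#' @export
invert_synteny <- function(map) {
  b <- map$blocks
  synteny_map(data.frame(src_chrom = b$tgt_chrom, src_start = b$tgt_start,
                         src_end = b$tgt_end, tgt_chrom = b$src_chrom,
                         tgt_start = b$src_start, tgt_end = b$src_end,
                         orientation = b$orientation),
              source_genome = map$target_genome,
              target_genome = map$source_genome)
}

#' Synteny map induced by a deletion
#'
#' A deletion `[start, end)` on a chromosome of length `L` induces a
#' two-block codirected synteny map from the reference genome to the deleted
#' genome: `[0, start) -> [0, start)` and `[end, L) -> [start, L - (end -
#' start))`. A zero-length deletion yields the one-block identity map;
#' deletions touching a chromosome end yield a single block.
#'
#' @param deletion a [deletion_spec()].
#' @param chrom_length reference chromosome length (bp).
#' @param source_genome,target_genome genome labels (target defaults to the
#'   deletion label).
#' @return a [synteny_map()] reference -> deleted genome.
#' @export
deletion_to_synteny <- function(deletion, chrom_length,
                                source_genome = "ref",
                                target_genome = deletion$label) {
  stopifnot(inherits(deletion, "deletion_spec"),
            deletion$end <= chrom_length)
  s <- deletion$start; e <- deletion$end; L <- chrom_length
  blocks <- data.frame(src_chrom = character(), src_start = numeric(),
                       src_end = numeric(), tgt_chrom = character(),
                       tgt_start = numeric(), tgt_end = numeric(),
                       orientation = character())
  if (e == s) {
    blocks[1, ] <- list(deletion$chrom, 0, L, deletion$chrom, 0, L, "+")
  } else {
    if (s > 0)
      blocks[nrow(blocks) + 1, ] <-
        list(deletion$chrom, 0, s, deletion$chrom, 0, s, "+")
    if (e < L)
      blocks[nrow(blocks) + 1, ] <-
        list(deletion$chrom, e, L, deletion$chrom, s, L - (e - s), "+")
  }
  synteny_map(blocks, source_genome = source_genome,
              target_genome = target_genome)
}

#' Bridge small gaps between codirected synteny blocks
#'
#' Consecutive codirected blocks separated by gaps smaller than `max_gap` on
#' **both** the source and the target side, with the two gaps of equal
#' length, are merged into one block (the gap is "mechanically filled").
#' Inverted blocks and larger or asymmetric gaps are left unchanged.
#'
#' @param map a [synteny_map()].
#' @param max_gap maximum gap width to bridge (bp), default 1 Mb.
#' @return a [synteny_map()] with qualifying blocks merged.
#' @export
fill_codirected_gaps <- function(map, max_gap = 1e6) {
  b <- map$blocks
  if (nrow(b) < 2) return(map)
  out <- b[1, ]
  for (r in 2:nrow(b)) {
    last <- nrow(out)
    src_gap <- b$src_start[r] - out$src_end[last]
    tgt_gap <- b$tgt_start[r] - out$tgt_end[last]
    if (out$orientation[last] == "+" && b$orientation[r] == "+" &&
        src_gap >= 0 && tgt_gap >= 0 &&
        src_gap < max_gap && tgt_gap < max_gap && src_gap == tgt_gap) {
      out$src_end[last] <- b$src_end[r]
      out$tgt_end[last] <- b$tgt_end[r]
    } else {
      out <- rbind(out, b[r, ])
    }
  }
  synteny_map(out, source_genome = map$source_genome,
              target_genome = map$target_genome)
}
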