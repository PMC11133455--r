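#' Read a binned contact map from text
#'
#' Two dialects are supported. The sparse *triplet* dialect has
#' whitespace-separated rows `chrom start1 start2 value` where the starts are
#' 0-based bin start coordinates; rows for pair `(a, b)` are mirrored to
#' `(b, a)` and duplicate pairs (including a mirrored duplicate) are summed.
#' The *dense* dialect is an `n_bins x n_bins` whitespace-separated numeric
#' matrix. Lines starting with `#` or `track` are ignored.
#'
#' @param path path to the text file.
#' @param grid the [bin_grid()] the coordinates refer to.
#' @param dialect `"auto"` (default), `"triplet"` or `"dense"`.
#' @inheritParams contact_map
#' @return a [contact_map()] with `normalization = "raw"` unless overridden.
#' @export
read_contact_map <- function(path, grid, dialect = c("auto", "triplet", "dense"),
                             normalization = "raw", role = "observed",
                             genome = "ref") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track)", lines) & nzchar(trimws(lines))]
  n <- grid$n_bins
  if (dialect == "auto") {
    if (length(lines) == 0L) {
      dialect <- "triplet"
    } else {
      first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
      dialect <- if (length(first) == 4L && is.na(suppressWarnings(as.numeric(first[1]))))
        "triplet" else "dense"
    }
  }
  if (dialect == "dense") {
    v <- as.matrix(utils::read.table(text = lines))
    if (!all(dim(v) == c(n, n)))
      stop("dense matrix is ", nrow(v), " x ", ncol(v),
           " but grid has ", n, " bins")
    return(contact_map(grid, v, normalization = normalization, role = role,
                       genome = genome))
  }
  v <- matrix(0, n, n)
  if (length(lines) > 0L) {
    tab <- utils::read.table(text = lines, col.names = c("chrom", "s1", "s2", "value"),
                             colClasses = c("character", "numeric", "numeric", "numeric"))
    bad <- tab$chrom != grid$chrom
    if (any(bad))
      stop("row refers to chromosome ", tab$chrom[which(bad)[1]],
           " but grid is ", grid$chrom)
    for (cc in c("s1", "s2")) {
      pos <- tab[[cc]]
      if (any(pos < 0 | pos >= grid$chrom_length))
        stop("coordinate out of range [0, ", grid$chrom_length, "): ",
             pos[which(pos < 0 | pos >= grid$chrom_length)[1]])
      if (any(pos %% grid$bin_size != 0))
        stop("coordinate not a multiple of bin size ", grid$bin_size, ": ",
             pos[which(pos %% grid$bin_size != 0)[1]])
    }
    if (any(tab$value < 0))
      stop("negative contact value at row ", which(tab$value < 0)[1])
    i <- pos_to_bin(grid, tab$s1)
    j <- pos_to_bin(grid, tab$s2)
    for (r in seq_along(i)) {          # mirror-sum rule
      v[i[r], j[r]] <- v[i[r], j[r]] + tab$value[r]
      if (i[r] != j[r]) v[j[r], i[r]] <- v[j[r], i[r]] + tab$value[r]
    }
  }
  contact_map(grid, v, normalization = normalization, role = role,
              genome = genome)
}

#' Write a contact map to text
#'
#' In the triplet dialect only the upper triangle (including the diagonal) of
#' nonzero entries is emitted, one `chrom start1 start2 value` row per pair,
#' so that [read_contact_map()] reproduces the map exactly.
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @param dialect `"triplet"` (default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, dialect = c("triplet", "dense")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    utils::write.table(map$values, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact map | %s | bin_size=%g | normalization=%s",
                     map$grid$chrom, map$grid$bin_size, map$normalization), con)
  idx <- which(upper.tri(map$values, diag = TRUE) & map$values != 0,
               arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    starts <- bin_starts(map$grid)
    writeLines(sprintf("%s\t%.0f\t%.0f\t%.17g", map$grid$chrom,
                       starts[idx[, 1]], starts[idx[, 2]],
                       map$values[idx]), con)
  }
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' @param grid a [bin_grid()].
#' @param values numeric vector (length `n_bins`); `NA` bins are omitted.
#' @param path output path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(grid, values, path, name = "track") {
  stopifnot(length(values) == grid$n_bins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  keep <- which(!is.na(values))
  if (length(keep))
    writeLines(sprintf("%s\t%.0f\t%.0f\t%.6f", grid$chrom,
                       bin_starts(grid)[keep], bin_ends(grid)[keep],
                       values[keep]), con)
  invisible(path)
}

#' Read a synteny map from TSV
#'
#' Expected columns:
#' `src_chrom src_start src_end tgt_chrom tgt_start tgt_end orientation`,
#' with orientation `+` (codirected) or `-` (inverted); coordinates 0-based
#' half-open.
#'
#' @param path input TSV path.
#' @param source_genome,target_genome genome labels.
#' @return a [synteny_map()].
#' @export
read_synteny_map <- function(path, source_genome = "source",
                             target_genome = "target") {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("src_chrom", "src_start", "src_end",
                                         "tgt_chrom", "tgt_start", "tgt_end",
                                         "orientation"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "numeric",
                                          "character"))
  synteny_map(tab, source_genome = source_genome,
              target_genome = target_genome)
}

#' Write a synteny map to TSV
#' @param map a [synteny_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synteny_map <- function(map, path) {
  utils::write.table(map$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read deletion specifications from BED3(+label)
#' @param path BED path (3 or 4 columns, 0-based half-open).
#' @return list of [deletion_spec()] objects.
#' @export
read_deletions_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  lapply(seq_len(nrow(tab)), function(r) {
    deletion_spec(tab[r, 1], as.numeric(tab[r, 2]), as.numeric(tab[r, 3]),
                  label = if (ncol(tab) >= 4) tab[r, 4] else
                    sprintf("del_%d", r))
  })
}
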