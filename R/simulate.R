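#' TAD-block model of a capture Hi-C locus
#'
#' Parametric model for the expected contact matrix of a capture region
#' organized in TADs: a power-law distance decay `P(s) = A * (1 + s)^(-alpha)`
#' multiplied, for each pair, by the insulation multiplier `delta` of every
#' boundary lying between the two bins, plus optional Gaussian "loop" bumps.
#' `delta = 1` means no boundary effect; small `delta` means strong
#' insulation.
#'
#' @param grid a [bin_grid()].
#' @param alpha distance-decay exponent (`> 0`).
#' @param boundaries data.frame with columns `bin` (1-based index of the bin
#'   whose left edge carries the boundary; a pair `(i, j)`, `i < j`, crosses
#'   it when `i < bin <= j`) and `delta` in `(0, 1]`.
#' @param loops optional data.frame with columns `bin1`, `bin2`, `amplitude`,
#'   `width` (bins); each adds `amplitude * exp(-d2/(2 width^2))` relative
#'   enrichment around the anchor pair.
#' @param depth expected total read count of a simulated map.
#' @return object of class `tad_model`.
#' @seealso [kit_locus_model()], [simulate_contact_map()]
#' @export
tad_model <- function(grid, alpha = 1, boundaries = NULL, loops = NULL,
                      depth = 5e6) {
  stopifnot(inherits(grid, "bin_grid"), alpha > 0, depth > 0)
  if (is.null(boundaries))
    boundaries <- data.frame(bin = integer(), delta = numeric())
  stopifnot(all(c("bin", "delta") %in% names(boundaries)),
            all(boundaries$delta > 0), all(boundaries$delta <= 1),
            all(boundaries$bin >= 1), all(boundaries$bin <= grid$n_bins))
  if (!is.null(loops))
    stopifnot(all(c("bin1", "bin2", "amplitude", "width") %in% names(loops)))
  structure(list(grid = grid, alpha = alpha,
                 boundaries = boundaries[order(boundaries$bin), , drop = FALSE],
                 loops = loops, depth = depth),
            class = "tad_model")
}

#' @export
print.tad_model <- function(x, ...) {
  cat(sprintf("<tad_model> %s | alpha=%g | depth=%.3g | %d boundary(ies), %d loop(s)\n",
              format(x$grid), x$alpha, x$depth, nrow(x$boundaries),
              if (is.null(x$loops)) 0L else nrow(x$loops)))
  if (nrow(x$boundaries)) print(x$boundaries)
  invisible(x)
}

#' Expected contact matrix of a TAD model
#'
#' Returns the per-pair Poisson means, globally scaled so the sum over
#' unordered pairs (diagonal included) equals the model depth.
#'
#' @param model a [tad_model()].
#' @return symmetric numeric matrix `n_bins x n_bins`.
#' @export
expected_matrix <- function(model) {
  n <- model$grid$n_bins
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- (1 + s)^(-model$alpha)
  for (b in seq_len(nrow(model$boundaries))) {
    p <- model$boundaries$bin[b]
    delta <- model$boundaries$delta[b]
    cross <- outer(seq_len(n) < p, seq_len(n) >= p, "&")
    e[cross | t(cross)] <- e[cross | t(cross)] * delta
  }
  if (!is.null(model$loops)) {
    idx <- seq_len(n)
    for (l in seq_len(nrow(model$loops))) {
      lp <- model$loops[l, ]
      d2 <- outer((idx - lp$bin1)^2, (idx - lp$bin2)^2, "+")
      bump <- lp$amplitude * exp(-d2 / (2 * lp$width^2))
      e <- e * (1 + bump + t(bump))
    }
  }
  # scale so the expected total count over unordered pairs equals depth
  e * (model$depth / sum(e[upper.tri(e, diag = TRUE)]))
}

#' Default three-TAD locus template
#'
#' A 455-bin, 5-kb model of a ~2.275 Mb capture region containing three
#' adjacent TADs (as around a locus where three genes each occupy their own
#' TAD), with two strongly insulating main boundaries and two weaker nested
#' sub-TAD boundaries inside the middle TAD.
#'
#' @param depth expected total read count (default 5e6).
#' @param alpha distance-decay exponent (default 1).
#' @param delta_main insulation multiplier of the two main TAD boundaries
#'   (default 0.2).
#' @param delta_sub insulation multiplier of the nested sub-TAD boundaries
#'   (default 0.6).
#' @return a [tad_model()] on `bin_grid("chrS", 2275000, 5000)` with main
#'   boundaries at bins 150 and 290 and sub-boundaries at bins 200 and 245.
#' @export
kit_locus_model <- function(depth = 5e6, alpha = 1, delta_main = 0.2,
                            delta_sub = 0.6) {
  g <- bin_grid("chrS", 2275000, 5000)
  tad_model(g, alpha = alpha,
            boundaries = data.frame(bin = c(150L, 200L, 245L, 290L),
                                    delta = c(delta_main, delta_sub,
                                              delta_sub, delta_main)),
            depth = depth)
}

#' Simulate a raw contact map from a TAD model
#'
#' Draws one count per unordered bin pair independently from a Poisson law
#' with mean given by [expected_matrix()] (expected total = depth), mirrors
#' to a symmetric matrix, and wraps it as a raw [contact_map()].
#' Reproducible for a fixed seed.
#'
#' @param model a [tad_model()].
#' @param seed integer random seed.
#' @param genome genome label for the output map.
#' @return a raw [contact_map()].
#' @export
simulate_contact_map <- function(model, seed, genome = "ref") {
  e <- expected_matrix(model)
  n <- nrow(e)
  ut <- upper.tri(e, diag = TRUE)
  v <- matrix(0, n, n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  v[ut] <- stats::rpois(sum(ut), e[ut])
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  v <- v + t(v) - diag(diag(v))
  contact_map(model$grid, v, genome = genome)
}

#' Deletion-experiment specification
#'
#' Bundles a wild-type [tad_model()], a [deletion_spec()], the `fused` flag
#' (whether the boundary at/inside the deletion loses its insulating effect
#' in the mutant, `delta -> 1`) and a seed, defining one synthetic wild-type
#' vs mutant experiment.
#'
#' @param model wild-type [tad_model()].
#' @param deletion a [deletion_spec()] inside the model grid.
#' @param fused logical: remove the boundary overlapping the deletion in the
#'   mutant model (`TRUE`) or retain its insulation at the fusion point
#'   (`FALSE`).
#' @param depth per-sample expected total count (defaults to the model's).
#' @param seed integer seed; wild type uses `seed`, mutant `seed + 1`.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(model, deletion, fused = FALSE,
                            depth = model$depth, seed = 1L) {
  stopifnot(inherits(model, "tad_model"), inherits(deletion, "deletion_spec"),
            deletion$end <= model$grid$chrom_length)
  structure(list(model = model, deletion = deletion, fused = isTRUE(fused),
                 depth = depth, seed = as.integer(seed)),
            class = "experiment_spec")
}

## Mutant model on the deleted genome: collapse coordinates, drop/shift
## boundaries and loops. A boundary whose bin lies inside the deletion is
## dropped when fused, else re-attached at the fusion point.
mutant_model <- function(spec) {
  m <- spec$model
  g <- m$grid
  del <- spec$deletion
  del_len <- del$end - del$start
  mut_grid <- bin_grid(g$chrom, g$chrom_length - del_len, g$bin_size)
  shift_pos <- function(pos_bp) {          # reference bp -> mutant bp (NA inside)
    ifelse(pos_bp < del$start, pos_bp,
           ifelse(pos_bp >= del$end, pos_bp - del_len, NA_real_))
  }
  bnd <- m$boundaries
  if (nrow(bnd)) {
    pos_bp <- (bnd$bin - 1) * g$bin_size   # boundary at the bin's left edge
    new_bp <- shift_pos(pos_bp)
    inside <- is.na(new_bp)
    if (any(inside)) {
      if (spec$fused) {
        bnd <- bnd[!inside, , drop = FALSE]
        new_bp <- new_bp[!inside]
      } else {
        new_bp[inside] <- del$start        # insulation retained at fusion point
      }
    }
    bnd$bin <- pmin(mut_grid$n_bins, as.integer(new_bp %/% g$bin_size) + 1L)
    bnd <- bnd[bnd$bin >= 2, , drop = FALSE]      # boundary at edge is void
    bnd <- bnd[!duplicated(bnd$bin), , drop = FALSE]
  }
  loops <- m$loops
  if (!is.null(loops) && nrow(loops)) {
    for (cc in c("bin1", "bin2")) {
      bp <- (loops[[cc]] - 1) * g$bin_size
      nb <- shift_pos(bp)
      loops[[cc]] <- as.integer(nb %/% g$bin_size) + 1L
    }
    loops <- loops[stats::complete.cases(loops), , drop = FALSE]
    if (nrow(loops) == 0L) loops <- NULL
  }
  tad_model(mut_grid, alpha = m$alpha, boundaries = bnd, loops = loops,
            depth = spec$depth)
}

#' Simulate a wild-type / deletion-mutant capture Hi-C pair
#'
#' The wild-type map is simulated from the model on the reference grid. The
#' mutant map is simulated on the deleted-genome grid from the mutant model
#' (distances recomputed after collapsing the deletion; the overlapped
#' boundary removed if `fused`), then re-expressed in reference coordinates
#' through the inverse deletion coordinate map — emulating mutant reads
#' mapped to the reference assembly — with the deleted interval masked.
#'
#' @param spec an [experiment_spec()].
#' @return list with raw [contact_map()]s `wt` and `mutant_in_ref` (both on
#'   the reference grid), plus `mutant_native` on the deleted-genome grid and
#'   the `mutant_model` used.
#' @export
simulate_deletion_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  wt_model <- spec$model
  wt_model$depth <- spec$depth
  wt <- simulate_contact_map(wt_model, spec$seed, genome = "ref")
  mm <- mutant_model(spec)
  mut_label <- spec$deletion$label
  mut <- simulate_contact_map(mm, spec$seed + 1L, genome = mut_label)
  syn_back <- invert_synteny(
    deletion_to_synteny(spec$deletion, wt_model$grid$chrom_length,
                        source_genome = "ref", target_genome = mut_label))
  mutant_in_ref <- liftover_easy(mut, syn_back, wt_model$grid)
  list(wt = wt, mutant_in_ref = mutant_in_ref, mutant_native = mut,
       mutant_model = mm)
}

#' Simulate per-SNP allele counts for one gene
#'
#' Each SNP's musculus count is Binomial(`coverage_per_snp`,
#' `true_ratio / (1 + true_ratio)`); the castaneus count is the remainder.
#'
#' @param gene gene id.
#' @param n_snps number of SNPs (`>= 1`).
#' @param coverage_per_snp total reads per SNP (`>= 0`).
#' @param true_ratio true musculus/castaneus expression ratio (`> 0`).
#' @param seed integer seed.
#' @param genotype genotype label for the rows.
#' @return a [snp_coverage_table()] with `n_snps` rows.
#' @export
simulate_snp_counts <- function(gene, n_snps, coverage_per_snp, true_ratio,
                                seed, genotype = "Wt") {
  stopifnot(n_snps >= 1, coverage_per_snp >= 0, true_ratio > 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  mus <- stats::rbinom(n_snps, coverage_per_snp,
                       true_ratio / (1 + true_ratio))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  snp_coverage_table(data.frame(gene = gene,
                                pos = seq_len(n_snps) * 1000L,
                                mus_count = mus,
                                cast_count = coverage_per_snp - mus,
                                genotype = genotype,
                                stringsAsFactors = FALSE))
}
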