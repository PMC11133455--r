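#' Pseudocount-normalized allele expression ratio
#'
#' For one SNP in an F1 *M. musculus* x *M. castaneus* hybrid, the relative
#' activity of the musculus allele is `(mus + 1) / (cast + 1)`: a pseudocount
#' of 1 is added to each allele's SNP coverage before taking the ratio, so
#' the result is always finite and positive (a SNP with no coverage scores
#' exactly 1, i.e. balance).
#'
#' @param mus_count,cast_count non-negative allele read counts (vectorized).
#' @return numeric ratio(s), `> 0`.
#' @examples
#' normalized_allele_expression(9, 4)   # 2
#' normalized_allele_expression(0, 0)   # 1
#' @export
normalized_allele_expression <- function(mus_count, cast_count) {
  if (any(mus_count < 0) || any(cast_count < 0))
    stop("allele counts must be non-negative")
  (mus_count + 1) / (cast_count + 1)
}

#' Convert an allele ratio to an allele fraction
#'
#' Maps a musculus/castaneus expression ratio `r` to the fraction of
#' transcripts attributed to the musculus allele, `r / (1 + r)`. A ratio of
#' 49.71 corresponds to a 98% musculus fraction.
#'
#' @param ratio non-negative ratio(s).
#' @return fraction(s) in `[0, 1)`, strictly increasing in `ratio`.
#' @examples
#' round(100 * allele_fraction(49.71))  # 98
#' @export
allele_fraction <- function(ratio) {
  if (any(ratio < 0)) stop("ratio must be non-negative")
  ratio / (1 + ratio)
}

#' Read a SNP allele-coverage table
#'
#' @param path TSV with columns `gene pos mus_count cast_count genotype`
#'   (header optional; detected). Genotypes are free labels, typically `Wt`
#'   and a mutant label.
#' @return data.frame of class `snp_coverage_table` with an added
#'   `ratio` column of pseudocount-normalized allele ratios.
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           col.names = c("gene", "pos", "mus_count",
                                         "cast_count", "genotype"),
                           stringsAsFactors = FALSE)
  snp_coverage_table(tab)
}

#' Construct/validate a SNP coverage table
#'
#' @param tab data.frame with columns `gene`, `pos`, `mus_count`,
#'   `cast_count`, `genotype`.
#' @return the validated data.frame with a `ratio` column, classed
#'   `snp_coverage_table`.
#' @export
snp_coverage_table <- function(tab) {
  need <- c("gene", "pos", "mus_count", "cast_count", "genotype")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$mus_count < 0) || any(tab$cast_count < 0))
    stop("allele counts must be non-negative")
  if (any(tab$mus_count != round(tab$mus_count)) ||
      any(tab$cast_count != round(tab$cast_count)))
    stop("allele counts must be integers")
  key <- paste(tab$gene, tab$pos, tab$genotype)
  if (anyDuplicated(key))
    stop("duplicate (gene, position, genotype) row: ",
         key[anyDuplicated(key)])
  tab$ratio <- normalized_allele_expression(tab$mus_count, tab$cast_count)
  class(tab) <- c("snp_coverage_table", "data.frame")
  tab
}

#' Per-gene, per-genotype summary of allele ratios
#'
#' Mean and sample standard deviation of the per-SNP pseudocount-normalized
#' ratios for one gene and genotype. With a single SNP the standard deviation
#' is reported as 0 and flagged.
#'
#' @param table a [snp_coverage_table()].
#' @param gene gene id.
#' @param genotype genotype label.
#' @return list with `gene`, `genotype`, `mean`, `sd`, `n`.
#' @export
gene_allelic_summary <- function(table, gene, genotype) {
  r <- table$ratio[table$gene == gene & table$genotype == genotype]
  if (length(r) == 0L)
    stop("no SNPs for gene '", gene, "' and genotype '", genotype, "'")
  list(gene = gene, genotype = genotype, mean = mean(r),
       sd = if (length(r) > 1L) stats::sd(r) else 0, n = length(r))
}

## Exact or tie-corrected-normal two-tailed Mann-Whitney U test.
## Exact null (via the U distribution) when min(n1, n2) <= exact_max and no
## ties across the pooled sample; otherwise normal approximation with the
## standard tie-corrected variance.
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # U statistic of x
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && min(n1, n2) <= exact_max) {
    lo <- min(u, n1 * n2 - u)
    p <- 2 * stats::pwilcox(lo, n1, n2)
    # both tails overlap at the centre; cap
    method <- "exact"
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    nn <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) /
                                (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal-tie-corrected"
  }
  list(u = u, p = min(1, max(p, .Machine$double.xmin)), method = method)
}

#' Compare allele ratios between genotypes for one gene
#'
#' Two-sample two-tailed Mann-Whitney U test on the per-SNP
#' pseudocount-normalized ratio sets of the two genotypes. The null
#' distribution is exact when the smaller group has at most 8 observations
#' and there are no ties; otherwise a normal approximation with tie-corrected
#' variance is used. SNPs are the sampling unit.
#'
#' @param table a [snp_coverage_table()] containing both genotypes for the
#'   gene.
#' @param gene gene id.
#' @param genotypes length-2 character vector naming the two genotypes to
#'   compare (default: the two present, reference first if labelled `"Wt"`).
#' @return an object of class `allelic_result`: list with `gene`, per-group
#'   summaries (`mean`, `sd`, `n`), `u` (U of the first group), two-tailed
#'   `p`, and the test `method`.
#' @export
compare_alleles <- function(table, gene, genotypes = NULL) {
  sub <- table[table$gene == gene, , drop = FALSE]
  if (is.null(genotypes)) {
    genotypes <- unique(sub$genotype)
    if ("Wt" %in% genotypes)
      genotypes <- c("Wt", setdiff(genotypes, "Wt"))
  }
  if (length(genotypes) != 2L)
    stop("need exactly two genotypes for gene '", gene, "'; found: ",
         paste(unique(sub$genotype), collapse = ", "))
  r1 <- sub$ratio[sub$genotype == genotypes[1]]
  r2 <- sub$ratio[sub$genotype == genotypes[2]]
  if (length(r1) == 0L || length(r2) == 0L)
    stop("genotype missing for gene '", gene, "': ",
         genotypes[c(length(r1) == 0L, length(r2) == 0L)])
  mw <- mann_whitney(r1, r2)
  structure(list(gene = gene, genotypes = genotypes,
                 group1 = gene_allelic_summary(table, gene, genotypes[1]),
                 group2 = gene_allelic_summary(table, gene, genotypes[2]),
                 u = mw$u, p = mw$p, method = mw$method),
            class = "allelic_result")
}

#' @export
print.allelic_result <- function(x, ...) {
  cat(sprintf("<allelic_result> %s: %s %.3f +/- %.3f (n=%d) vs %s %.3f +/- %.3f (n=%d)\n",
              x$gene, x$genotypes[1], x$group1$mean, x$group1$sd, x$group1$n,
              x$genotypes[2], x$group2$mean, x$group2$sd, x$group2$n))
  cat(sprintf("  Mann-Whitney U = %g, two-tailed p = %.4g (%s)\n",
              x$u, x$p, x$method))
  invisible(x)
}

#' Write allelic comparison results as TSV
#'
#' @param results list of [compare_alleles()] results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allelic_results <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(x) {
    data.frame(gene = x$gene,
               genotype1 = x$genotypes[1], mean1 = x$group1$mean,
               sd1 = x$group1$sd, n1 = x$group1$n,
               genotype2 = x$genotypes[2], mean2 = x$group2$mean,
               sd2 = x$group2$sd, n2 = x$group2$n,
               U = x$u, p = x$p, method = x$method)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
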