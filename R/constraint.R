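# Selective-constraint metrics and cohort QC statistics: singleton and
# high-pLI proportions with Wald intervals, donor-gene enrichment, intronic
# orientation bias, SNV missingness filtering, downsampling z-scores, and a
# median-expression filter.

.wald_ci <- function(p_hat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(estimate = p_hat, half_width = half,
    lower = p_hat - half, upper = p_hat + half)
}

#' Proportion of singleton variants with a Wald interval
#'
#' A singleton is a variant carried by exactly one individual in the
#' analysis subset.
#'
#' @param carrier_counts Integer vector: number of carriers per variant
#'   (>= 1 each; non-empty).
#' @return Named vector: `estimate`, `half_width`, `lower`, `upper`, `n`.
#' @export
singleton_proportion <- function(carrier_counts) {
  if (length(carrier_counts) == 0) stop("empty variant set")
  stopifnot(all(carrier_counts >= 1))
  n <- length(carrier_counts)
  c(.wald_ci(mean(carrier_counts == 1L), n), n = n)
}

#' Proportion of variants in LoF-intolerant genes with a Wald interval
#'
#' @param pli Numeric vector of pLI scores of the containing gene, one per
#'   variant (restrict to variants inside genes with a defined pLI before
#'   calling).
#' @param cutoff High-pLI threshold (default 0.9, exclusive).
#' @return Named vector as in [singleton_proportion()], or `NA`s with a
#'   warning on an empty input.
#' @export
pli_proportion <- function(pli, cutoff = 0.9) {
  if (length(pli) == 0) {
    warning("no variants with a defined pLI; proportion undefined")
    return(c(estimate = NA_real_, half_width = NA_real_, lower = NA_real_,
             upper = NA_real_, n = 0))
  }
  n <- length(pli)
  c(.wald_ci(mean(pli > cutoff), n), n = n)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return Two-sided exact p-value; a table with any zero margin returns 1
#'   with a warning.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  fisher.test(m)$p.value
}

#' Chi-squared test for orientation bias of intronic insertions
#'
#' Goodness of fit of sense/antisense counts against a 50:50 expectation
#' (1 df, no continuity correction).
#'
#' @param sense,antisense Counts of insertions in each orientation
#'   (`sense + antisense > 0`).
#' @return List with `chisq` and `p`.
#' @export
orientation_bias_test <- function(sense, antisense) {
  n <- sense + antisense
  if (n <= 0) stop("sense + antisense must be positive")
  e <- n / 2
  stat <- (sense - e)^2 / e + (antisense - e)^2 / e
  list(chisq = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' SNV genotype missingness filter
#'
#' Site-level prefilters remove variants with `VQSLOD < -2`. Each remaining
#' genotype is set missing when `GQ < 20`, `DP < 8`, or (for heterozygous
#' calls) the two-sided exact binomial allelic-balance p-value of alt reads
#' against 0.5 is below `ad_p`. Variants with more than `max_missing` of
#' genotypes missing are dropped.
#'
#' @param genotypes Long data frame: `variant_id`, `sample`, `gt` (0/1/2),
#'   `gq`, `dp`, `ad_ref`, `ad_alt`.
#' @param sites Data frame: `variant_id`, `vqslod` (optional; when absent no
#'   site prefilter is applied).
#' @param min_gq,min_dp,ad_p,max_missing,min_vqslod Thresholds (defaults 20,
#'   8, 0.001, 0.5, -2).
#' @return List: `keep` (character vector of retained variant ids),
#'   `genotypes` (input with a logical `missing` column),
#'   `dropped` (named character vector mapping dropped variant ids to the
#'   reason, `"vqslod"` or `"missingness"`).
#' @export
snv_missingness_filter <- function(genotypes, sites = NULL, min_gq = 20,
                                   min_dp = 8, ad_p = 0.001,
                                   max_missing = 0.5, min_vqslod = -2) {
  g <- genotypes
  bal_p <- rep(1, nrow(g))
  het <- !is.na(g$gt) & g$gt == 1L
  if (any(het)) {
    tot <- g$ad_alt + g$ad_ref
    bal_p[het] <- mapply(function(x, n)
      if (n > 0) binom.test(x, n, 0.5)$p.value else 1,
      g$ad_alt[het], tot[het])
  }
  g$missing <- g$gq < min_gq | g$dp < min_dp | (het & bal_p < ad_p)
  dropped <- character(0)
  vids <- unique(g$variant_id)
  if (!is.null(sites) && "vqslod" %in% names(sites)) {
    bad <- sites$variant_id[sites$vqslod < min_vqslod]
    dropped <- c(dropped, setNames(rep("vqslod", length(bad)), bad))
    vids <- setdiff(vids, bad)
  }
  miss_frac <- vapply(vids, function(v)
    mean(g$missing[g$variant_id == v]), numeric(1))
  bad2 <- vids[miss_frac > max_missing]
  dropped <- c(dropped, setNames(rep("missingness", length(bad2)), bad2))
  list(keep = setdiff(vids, bad2), genotypes = g, dropped = dropped)
}

#' Downsampling z-score of an external reference count
#'
#' Repeatedly samples `subset_size` individuals from the cohort genotype
#' matrix, counts sites still segregating in the subset, and expresses an
#' external reference count as a z-score of that distribution, per class.
#'
#' @param callset A call set (`sites` + `geno`).
#' @param reference_counts Named vector: external site count per ME class.
#' @param subset_size Individuals per draw (strictly smaller than the
#'   cohort).
#' @param reps Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Data frame: `class`, `reference`, `mean`, `sd`, `z`.
#' @export
downsample_zscore <- function(callset, reference_counts, subset_size,
                              reps = 1000L, seed = 1L) {
  samples <- colnames(callset$geno)
  if (subset_size >= length(samples))
    stop("subset_size must be smaller than the cohort")
  set.seed(seed)
  classes <- names(reference_counts)
  counts <- matrix(0L, reps, length(classes),
                   dimnames = list(NULL, classes))
  carrier <- !is.na(callset$geno) & callset$geno >= 1L
  for (r in seq_len(reps)) {
    sub <- sample(samples, subset_size)
    seg <- rowSums(carrier[, sub, drop = FALSE]) > 0
    for (cl in classes)
      counts[r, cl] <- sum(seg & callset$sites$class == cl)
  }
  sds <- apply(counts, 2, sd)
  if (any(sds == 0)) stop("degenerate downsampling distribution (SD = 0)")
  data.frame(class = classes, reference = as.numeric(reference_counts),
             mean = colMeans(counts), sd = sds,
             z = (as.numeric(reference_counts) - colMeans(counts)) / sds,
             stringsAsFactors = FALSE)
}

#' Genes expressed by median-expression threshold
#'
#' @param expression_matrix Gene x sample expression matrix (e.g. RPKM).
#' @param threshold Minimum row median (default 1, inclusive).
#' @return Character vector of expressed gene ids; genes with no
#'   non-missing values are excluded with a warning.
#' @export
median_expression_filter <- function(expression_matrix, threshold = 1) {
  stopifnot(nrow(expression_matrix) > 0)
  med <- apply(expression_matrix, 1, median, na.rm = TRUE)
  if (any(is.na(med)))
    warning(sum(is.na(med)), " gene(s) with no expression values excluded")
  rownames(expression_matrix)[!is.na(med) & med >= threshold]
}
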