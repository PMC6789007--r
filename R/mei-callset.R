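# Post-discovery filtering and summarisation of MELT-style MEI call sets.
#
# A call set is a list with `sites` (data frame: site_id, chrom, pos0, class,
# assess, sr, filter, ...) and `geno` (integer matrix sites x samples with
# values 0/1/2 and NA for missing), as produced by gen_mei_cohort() or
# read_mei_vcf().

#' Flag a low-complexity reference window
#'
#' An insertion is considered low complexity when the reference window
#' around it (insertion point +/- 50 bp) contains a run of >= `min_run` bp
#' composed of two or fewer distinct nucleotides. `N` breaks runs; any other
#' non-ACGTN symbol is an error.
#'
#' @param window_sequence Nucleotide string (the +/- 50 bp reference window).
#' @param min_run Minimum run length (default 15).
#' @return `TRUE` if any window of `min_run` bp uses <= 2 distinct
#'   nucleotides.
#' @export
#' @examples
#' low_complexity_flag("GGCATATATATATATATAGGC")  # TRUE (AT run)
low_complexity_flag <- function(window_sequence, min_run = 15L) {
  chars <- strsplit(toupper(window_sequence), "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("window contains non-ACGTN symbols")
  if (length(chars) < min_run) return(FALSE)
  segments <- strsplit(paste(chars, collapse = ""), "N", fixed = TRUE)[[1]]
  for (seg in segments) {
    s <- strsplit(seg, "")[[1]]
    n <- length(s)
    if (n < min_run) next
    # sliding window over distinct-nucleotide counts
    for (i in seq_len(n - min_run + 1L)) {
      if (length(unique(s[i:(i + min_run - 1L)])) <= 2L) return(TRUE)
    }
  }
  FALSE
}

#' Add the low-complexity filter to a call set from a reference sequence
#'
#' Scans the +/- `flank` bp reference window around every insertion point
#' and appends `"lc"` to the FILTER of flagged records.
#'
#' @param callset A call set (`sites` + `geno`).
#' @param ref A [Biostrings::DNAStringSet] reference (names = chromosomes).
#' @param flank Window half-width in bp (default 50).
#' @return The call set with updated `sites$filter`.
#' @export
flag_low_complexity_sites <- function(callset, ref, flank = 50L) {
  s <- callset$sites
  for (i in seq_len(nrow(s))) {
    chrom_seq <- ref[[s$chrom[i]]]
    lo <- max(1L, s$pos0[i] + 1L - flank)
    hi <- min(length(chrom_seq), s$pos0[i] + 1L + flank)
    win <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
    if (low_complexity_flag(win)) {
      has <- vapply(strsplit(s$filter[i], ";"), function(f) "lc" %in% f,
                    logical(1))
      if (!has) s$filter[i] <- paste(s$filter[i], "lc", sep = ";")
    }
  }
  callset$sites <- s
  callset
}

#' Apply the call-set retention filters
#'
#' Retains records that (in this fixed order of attribution) are not
#' low-complexity flagged, were genotyped in at least `min_call_rate` of the
#' cohort, have more than `min_sr - 1` split reads, an ASSESS score of at
#' least `min_assess`, and no FILTER value other than `PASS` or `rSD`.
#' The ledger attributes each removal to the first failing criterion.
#'
#' @param callset A call set (`sites` + `geno`).
#' @param cohort_size Number of samples in the cohort (defaults to
#'   `ncol(callset$geno)`); must be positive.
#' @param min_call_rate Minimum fraction of genotyped individuals
#'   (default 0.25).
#' @param min_sr Minimum split-read support (default 3, i.e. records with
#'   <= 2 split reads are removed).
#' @param min_assess Minimum ASSESS score (default 3).
#' @param allowed_filters FILTER values that pass (default `PASS`, `rSD`;
#'   the `lc` flag is always disqualifying).
#' @return The filtered call set, with the removal ledger in
#'   `attr(, "ledger")` (named counts: `lc`, `call_rate`, `split_reads`,
#'   `assess`, `filter`, `retained`).
#' @export
apply_callset_filters <- function(callset, cohort_size = ncol(callset$geno),
                                  min_call_rate = 0.25, min_sr = 3L,
                                  min_assess = 3L,
                                  allowed_filters = c("PASS", "rSD")) {
  if (is.null(cohort_size) || cohort_size == 0)
    stop("cohort_size must be positive")
  s <- callset$sites
  filt_sets <- strsplit(s$filter, ";", fixed = TRUE)
  has_lc <- vapply(filt_sets, function(f) "lc" %in% f, logical(1))
  call_rate <- if (nrow(s)) rowSums(!is.na(callset$geno)) / cohort_size
  else numeric(0)
  fail_cr <- call_rate < min_call_rate
  fail_sr <- s$sr < min_sr
  fail_as <- s$assess < min_assess
  fail_fl <- vapply(filt_sets, function(f)
    any(!f %in% c(allowed_filters, "lc")), logical(1))
  first_fail <- rep(NA_character_, nrow(s))
  first_fail[fail_fl] <- "filter"
  first_fail[fail_as] <- "assess"
  first_fail[fail_sr] <- "split_reads"
  first_fail[fail_cr] <- "call_rate"
  first_fail[has_lc] <- "lc"
  keep <- is.na(first_fail) & !fail_fl & !fail_as & !fail_sr & !fail_cr
  ledger <- c(lc = sum(first_fail == "lc", na.rm = TRUE),
              call_rate = sum(first_fail == "call_rate", na.rm = TRUE),
              split_reads = sum(first_fail == "split_reads", na.rm = TRUE),
              assess = sum(first_fail == "assess", na.rm = TRUE),
              filter = sum(first_fail == "filter", na.rm = TRUE),
              retained = sum(keep))
  out <- callset
  out$sites <- s[keep, , drop = FALSE]
  out$geno <- callset$geno[keep, , drop = FALSE]
  if (!is.null(out$truth)) {
    out$truth$denovo <-
      out$truth$denovo[out$truth$denovo$site_id %in% out$sites$site_id, ,
                       drop = FALSE]
    out$truth$mosaic <-
      out$truth$mosaic[out$truth$mosaic$site_id %in% out$sites$site_id, ,
                       drop = FALSE]
  }
  attr(out, "ledger") <- ledger
  out
}

#' Recompute allele frequencies on a sample subset
#'
#' `AF = alt allele count / (2 x non-missing diploid samples)` within the
#' subset; missing genotypes are excluded from the denominator.
#'
#' @param callset A call set (`sites` + `geno`).
#' @param subset Sample ids to use (default: all samples).
#' @return Numeric vector of allele frequencies (one per site); sites with
#'   no called genotype get `NA` with a warning.
#' @export
recompute_af <- function(callset, subset = colnames(callset$geno)) {
  if (length(subset) == 0) stop("subset must be non-empty")
  g <- callset$geno[, subset, drop = FALSE]
  called <- rowSums(!is.na(g))
  af <- rowSums(g, na.rm = TRUE) / (2 * called)
  if (any(called == 0)) {
    warning(sum(called == 0), " site(s) with all genotypes missing; AF NA")
    af[called == 0] <- NA_real_
  }
  unname(af)
}

#' Per-individual site-count summary and Poisson goodness of fit
#'
#' Counts carried sites (genotype >= 1) per individual for each ME class and
#' for all classes combined, and tests the count distribution against a
#' Poisson with the fitted mean by a chi-squared goodness-of-fit test
#' (tail bins pooled to an expected count of at least `min_expected`).
#'
#' @param callset A call set (`sites` + `geno`).
#' @param samples Samples to summarise (default: all).
#' @param min_expected Minimum expected bin count for the chi-squared test.
#' @return Data frame, one row per class plus `"all"`: `class`, `n_sites`,
#'   `mean`, `sd`, `gof_p`. Single-individual cohorts report `sd = 0` with a
#'   warning.
#' @export
per_individual_count_summary <- function(callset,
                                         samples = colnames(callset$geno),
                                         min_expected = 5) {
  g <- callset$geno[, samples, drop = FALSE]
  if (ncol(g) == 1) warning("single individual: SD reported as 0")
  classes <- unique(callset$sites$class)
  rows <- lapply(c(classes, "all"), function(cl) {
    idx <- if (cl == "all") rep(TRUE, nrow(g)) else callset$sites$class == cl
    counts <- colSums(g[idx, , drop = FALSE] >= 1L, na.rm = TRUE)
    m <- mean(counts)
    s <- if (length(counts) > 1) sd(counts) else 0
    data.frame(class = cl, n_sites = sum(idx), mean = m, sd = s,
               gof_p = .poisson_gof_p(counts, min_expected),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Chi-squared goodness of fit of integer counts against Poisson(mean),
# pooling bins from both tails until expected counts reach min_expected.
# One df lost for the estimated mean.
.poisson_gof_p <- function(counts, min_expected = 5) {
  n <- length(counts)
  if (n < 2) return(NA_real_)
  lambda <- mean(counts)
  kmax <- max(counts, ceiling(lambda + 6 * sqrt(lambda + 1)))
  k <- 0:kmax
  p <- dpois(k, lambda)
  p[length(p)] <- p[length(p)] + ppois(kmax, lambda, lower.tail = FALSE)
  expected <- n * p
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  # pool adjacent bins until every pooled bin has expected >= min_expected
  groups <- integer(length(k))
  gid <- 1L
  acc <- 0
  for (i in seq_along(k)) {
    groups[i] <- gid
    acc <- acc + expected[i]
    if (acc >= min_expected && sum(expected[-seq_len(i)]) >= min_expected) {
      gid <- gid + 1L
      acc <- 0
    }
  }
  E <- tapply(expected, groups, sum)
  O <- tapply(obs, groups, sum)
  df <- length(E) - 1L - 1L
  if (df < 1) return(NA_real_)
  stat <- sum((O - E)^2 / E)
  pchisq(stat, df, lower.tail = FALSE)
}
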