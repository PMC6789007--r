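# Trio de novo candidate identification, parental mosaicism statistics, and
# long-read phasing summaries.

#' Find candidate de novo sites in trios
#'
#' A candidate is a site genotyped heterozygous in exactly one proband,
#' homozygous reference in both of that proband's parents, and carried by no
#' other individual in the cohort (cohort-uniqueness; can be disabled).
#' Sites with a missing parental genotype in the candidate trio are excluded
#' and tallied.
#'
#' @param callset A call set (`sites` + `geno`).
#' @param pedigree Data frame with `proband`, `father`, `mother` sample ids.
#' @param unique_in_cohort Require no other carrier cohort-wide
#'   (default `TRUE`).
#' @return Data frame of candidates: site columns plus `proband`; the number
#'   of sites excluded for missing parental genotypes is in
#'   `attr(, "excluded_missing")`.
#' @export
find_candidate_denovos <- function(callset, pedigree,
                                   unique_in_cohort = TRUE) {
  g <- callset$geno
  rows <- list()
  excluded <- 0L
  for (i in seq_len(nrow(g))) {
    het <- colnames(g)[!is.na(g[i, ]) & g[i, ] == 1L]
    carriers <- colnames(g)[!is.na(g[i, ]) & g[i, ] >= 1L]
    pro_het <- intersect(het, pedigree$proband)
    if (length(pro_het) != 1L) next
    t <- match(pro_het, pedigree$proband)
    fa <- g[i, pedigree$father[t]]
    mo <- g[i, pedigree$mother[t]]
    if (is.na(fa) || is.na(mo)) {
      excluded <- excluded + 1L
      next
    }
    if (fa != 0L || mo != 0L) next
    if (unique_in_cohort && length(setdiff(carriers, pro_het)) > 0) next
    rows[[length(rows) + 1L]] <-
      cbind(callset$sites[i, , drop = FALSE],
            data.frame(proband = pro_het, stringsAsFactors = FALSE))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(callset$sites[0, , drop = FALSE],
          data.frame(proband = character(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "excluded_missing") <- excluded
  out
}

#' Allelic proportion of insertion-supporting reads
#'
#' @param alt,ref Read counts supporting the insertion and the reference
#'   allele.
#' @return `alt / (alt + ref)`; zero total depth is an error.
#' @export
allelic_proportion <- function(alt, ref) {
  if (any(alt + ref <= 0))
    stop("zero depth: allelic proportion undefined")
  alt / (alt + ref)
}

#' One-sample z-test of a locus against the cohort distribution of
#' per-locus means
#'
#' Tests whether the mean homozygous-reference allelic proportion at one
#' locus is elevated relative to the distribution of per-locus means across
#' the cohort (an elevated mean indicates locus-specific sequencing or
#' genotyping error rather than parental mosaicism).
#'
#' @param locus_homref_props Allelic proportions of homozygous-reference
#'   genotypes at the locus under test.
#' @param cohort_loci_means Per-locus mean homozygous-reference allelic
#'   proportions forming the null distribution (>= 2 loci).
#' @return List with `z` and two-sided `p`.
#' @export
mosaic_locus_ztest <- function(locus_homref_props, cohort_loci_means) {
  if (length(cohort_loci_means) < 2)
    stop("need >= 2 cohort loci to form the null distribution")
  s <- sd(cohort_loci_means)
  if (s == 0) stop("zero variance in the null distribution")
  z <- (mean(locus_homref_props) - mean(cohort_loci_means)) / s
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Two-sample Kolmogorov-Smirnov test of read-start distributions
#'
#' Compares the read start positions around an insertion site in two samples
#' (e.g. parent vs proband); the asymptotic p-value is used.
#'
#' @param starts_a,starts_b Read start positions (non-empty).
#' @return List with `D` and asymptotic `p`.
#' @export
read_start_ks <- function(starts_a, starts_b) {
  if (length(starts_a) == 0 || length(starts_b) == 0)
    stop("both samples must be non-empty")
  res <- suppressWarnings(ks.test(starts_a, starts_b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Phase an MEI to a nearby heterozygous SNV from long reads
#'
#' Tallies the four read configurations (MEI+SNV+, MEI+SNV-, MEI-SNV+,
#' MEI-SNV-) and assigns a parental origin when at least `consistency` of
#' MEI-supporting reads carry one SNV allele and that allele is carried by
#' exactly one parent.
#'
#' @param reads Data frame with logical `mei` (read supports the insertion)
#'   and character `allele` (SNV allele observed on the read).
#' @param father_alleles,mother_alleles Character vectors of the two SNV
#'   alleles in each parent's genotype.
#' @param consistency Minimum agreeing fraction among MEI+ reads
#'   (default 0.9).
#' @return List of class `phase_count`: `counts` (named integer vector of
#'   the four configurations), `snv_allele` (the phased allele or `NA`),
#'   `origin` (`"father"`, `"mother"`, or `"unknown"`).
#' @export
phase_mei_to_snv <- function(reads, father_alleles, mother_alleles,
                             consistency = 0.9) {
  if (sum(reads$mei) == 0)
    stop("no MEI-supporting reads to phase")
  alleles <- sort(unique(reads$allele))
  if (length(alleles) != 2)
    stop("expected a biallelic heterozygous SNV; observed alleles: ",
         paste(alleles, collapse = ", "))
  ref <- alleles[1]
  alt <- alleles[2]
  counts <- c(
    "MEI+SNV+" = sum(reads$mei & reads$allele == alt),
    "MEI+SNV-" = sum(reads$mei & reads$allele == ref),
    "MEI-SNV+" = sum(!reads$mei & reads$allele == alt),
    "MEI-SNV-" = sum(!reads$mei & reads$allele == ref)
  )
  mei_alleles <- reads$allele[reads$mei]
  tab <- table(mei_alleles)
  top <- names(tab)[which.max(tab)]
  origin <- "unknown"
  phased <- NA_character_
  if (max(tab) / sum(tab) >= consistency) {
    phased <- top
    in_fa <- top %in% father_alleles
    in_mo <- top %in% mother_alleles
    if (in_fa && !in_mo) origin <- "father"
    else if (in_mo && !in_fa) origin <- "mother"
  }
  structure(list(counts = counts, snv_allele = phased, origin = origin),
            class = "phase_count")
}

#' @export
print.phase_count <- function(x, ...) {
  cat("phase_count: origin =", x$origin, "\n")
  print(x$counts)
  invisible(x)
}
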