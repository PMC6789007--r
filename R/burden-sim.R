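# Genome-wide de novo burden simulation and enrichment tests.
#
# The null model places the expected number of de novo events uniformly at
# random over the genome, annotates each placement with the single-
# consequence rule (enhancer priority), and averages counts per compartment
# over replicates to obtain a Poisson expectation lambda. Observed counts
# are compared with lambda by an upper-tail Poisson test.

#' Simulate genome-wide de novo placements under the neutral rate
#'
#' @param n_events Number of de novo events per replicate (>= 1).
#' @param reps Number of replicates (>= 1).
#' @param genome A [gen_toy_genome()] genome.
#' @param gene_sets Optional named list of transcript-id vectors; for each
#'   set, exonic and intronic counts restricted to genes in the set are also
#'   tallied (compartments named `"exonic:<label>"` etc.).
#' @param seed Integer seed.
#' @param ci One of `"normal"` (`lambda +/- 1.96 sqrt(lambda)`) or
#'   `"percentile"` (2.5/97.5 percentiles of the replicate counts).
#' @return Data frame of class `compartment_expectation`: `compartment`,
#'   `lambda`, `lower`, `upper`; per-replicate counts in
#'   `attr(, "rep_counts")`.
#' @export
simulate_denovo_placements <- function(n_events, reps, genome,
                                       gene_sets = NULL, seed = 1L,
                                       ci = c("normal", "percentile")) {
  stopifnot(n_events >= 1, reps >= 1)
  ci <- match.arg(ci)
  set.seed(seed)
  chrom_len <- genome$chrom_len
  base_comp <- c("enhancer", "exonic", "intronic", "intergenic")
  comp_names <- base_comp
  if (!is.null(gene_sets))
    comp_names <- c(comp_names,
                    unlist(lapply(names(gene_sets), function(l)
                      paste0(c("exonic:", "intronic:"), l))))
  counts <- matrix(0L, nrow = reps, ncol = length(comp_names),
                   dimnames = list(NULL, comp_names))
  total <- sum(chrom_len)
  for (r in seq_len(reps)) {
    flat <- sample.int(total, n_events, replace = TRUE) - 1L
    cum <- cumsum(as.numeric(chrom_len))
    ci_chrom <- findInterval(flat, c(0, cum), rightmost.closed = FALSE)
    chrom <- names(chrom_len)[ci_chrom]
    pos <- flat - c(0, cum)[ci_chrom]
    ann <- annotate_consequence(genome, chrom, pos)
    tab <- table(factor(ann$consequence, levels = base_comp))
    counts[r, base_comp] <- as.integer(tab)
    if (!is.null(gene_sets)) {
      for (l in names(gene_sets)) {
        in_set <- !is.na(ann$gene) & ann$gene %in% gene_sets[[l]]
        counts[r, paste0("exonic:", l)] <-
          sum(ann$consequence == "exonic" & in_set)
        counts[r, paste0("intronic:", l)] <-
          sum(ann$consequence == "intronic" & in_set)
      }
    }
  }
  lambda <- colMeans(counts)
  if (ci == "normal") {
    lower <- lambda - 1.96 * sqrt(lambda)
    upper <- lambda + 1.96 * sqrt(lambda)
  } else {
    qs <- apply(counts, 2, quantile, probs = c(0.025, 0.975))
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  out <- data.frame(compartment = comp_names, lambda = unname(lambda),
                    lower = unname(lower), upper = unname(upper),
                    stringsAsFactors = FALSE)
  attr(out, "rep_counts") <- counts
  class(out) <- c("compartment_expectation", "data.frame")
  out
}

#' Upper-tail Poisson enrichment p-value
#'
#' `P(X >= observed)` under `Poisson(lambda)`, i.e. `1 - F(observed - 1)`.
#'
#' @param observed Observed count (>= 0).
#' @param lambda Poisson mean (>= 0).
#' @return The upper-tail probability.
#' @export
poisson_upper_p <- function(observed, lambda) {
  if (any(observed < 0)) stop("observed must be >= 0")
  stopifnot(all(lambda >= 0))
  ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' Upper-tail binomial enrichment p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, by exact summation. Used e.g. for
#' the probability that at least `k` of `n` exonic de novo events fall
#' within a gene set occupying a fraction `p` of the exome.
#'
#' @param k Observed successes (`0 <= k <= n`).
#' @param n Number of trials.
#' @param p Success probability.
#' @return The upper-tail probability.
#' @export
binomial_upper_p <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, p >= 0, p <= 1)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Normal-approximation interval on a Poisson expectation
#'
#' @param lambda Poisson mean.
#' @param level Confidence level (default 0.95).
#' @return Named vector `lower`, `upper`: `lambda -/+ z sqrt(lambda)`.
#' @export
#' @examples
#' round(lambda_interval(12.3), 1)  # 5.4, 19.2
lambda_interval <- function(lambda, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = lambda - z * sqrt(lambda), upper = lambda + z * sqrt(lambda))
}
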