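# Shared fixtures and independent oracles used across the suite.

# A tiny deterministic genome with hand-placed coordinates, for unit tests
# that need known exon/enhancer boundaries (0-based half-open).
manual_genome <- function() {
  genes <- rbind(
    data.frame(transcript_id = "TXA", chrom = "chr1", strand = "+",
               start = c(1000L, 2000L, 3000L, 4000L, 5000L),
               end = c(1200L, 2200L, 3200L, 4200L, 5200L), exon = 1:5),
    data.frame(transcript_id = "TXB", chrom = "chr1", strand = "-",
               start = c(10000L, 12000L), end = c(10300L, 12300L),
               exon = 1:2)
  )
  g <- structure(list(
    chrom_len = c(chr1 = 50000L),
    genes = genes,
    pli = data.frame(transcript_id = c("TXA", "TXB"), pli = c(0.99, 0.1),
                     stringsAsFactors = FALSE),
    enhancers = data.frame(chrom = "chr1", start = 20000L, end = 20500L,
                           stringsAsFactors = FALSE),
    seq = NULL), class = "toy_genome")
  g$compartments <- compartment_bp(g)
  g
}

# A minimal call set built by hand (sites + genotype matrix).
manual_callset <- function(sites, geno) {
  rownames(geno) <- sites$site_id
  list(sites = sites, geno = geno)
}

make_site <- function(id, filter = "PASS", sr = 10L, assess = 5L,
                      chrom = "chr1", pos0 = 100L, class = "Alu") {
  data.frame(site_id = id, chrom = chrom, pos0 = pos0, class = class,
             ac_true = NA_integer_, assess = assess, sr = sr,
             filter = filter, insert_len = 300L, stringsAsFactors = FALSE)
}

# Brute-force oracles -------------------------------------------------------

# Nearest-rank percentile by explicit sort-and-index.
oracle_nearest_rank <- function(x, q) sort(x)[ceiling(q * length(x))]

# Low-complexity scan by enumerating every 15-mer.
oracle_low_complexity <- function(seq, min_run = 15L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < min_run) return(FALSE)
  for (i in seq_len(n - min_run + 1L)) {
    win <- chars[i:(i + min_run - 1L)]
    if (!"N" %in% win && length(unique(win)) <= 2L) return(TRUE)
  }
  FALSE
}

# Two-sided Fisher exact p by full hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed table's.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(as, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Poisson upper tail by direct pmf summation over the upper support
# (truncated far beyond any appreciable mass).
oracle_poisson_upper <- function(observed, lambda) {
  if (observed == 0) return(1)
  kmax <- max(observed, ceiling(lambda)) + 400L
  sum(dpois(observed:kmax, lambda))
}

# Binomial upper tail by exact enumeration.
oracle_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Two-sample KS statistic by brute-force ECDF maximisation over the pooled
# support.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
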