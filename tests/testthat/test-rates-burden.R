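# Watterson mutation-rate estimation, accessibility masks, burden
# simulation, and enrichment tails.

test_that("harmonic numbers by direct summation", {
  expect_equal(harmonic_number(1), 1)
  expect_equal(harmonic_number(3), 1 + 1 / 2 + 1 / 3)
  expect_equal(harmonic_number(5007), sum(1 / (1:5007)))
  expect_equal(harmonic_number(5007), 9.09592, tolerance = 1e-5)
  expect_error(harmonic_number(0), ">= 1")
})

test_that("coverage masks keep >= threshold runs and merge intervals", {
  uni <- build_mask(data.frame(chrom = "chr1", start = 0, end = 1e6,
                               coverage = 30))
  expect_equal(uni$L, 1e6)
  expect_equal(mask_n_intervals(uni), 1)
  none <- build_mask(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                coverage = 5))
  expect_equal(none$L, 0)
  alt <- data.frame(chrom = "chr1", start = seq(0, 9900, 100),
                    end = seq(100, 10000, 100),
                    coverage = rep(c(20, 5), 50))
  m <- build_mask(alt, 10)
  expect_equal(m$L, 5000)
  expect_equal(mask_n_intervals(m), 50)
  # boundary: coverage exactly at threshold is retained
  eq <- build_mask(data.frame(chrom = "chr1", start = 0, end = 100,
                              coverage = 10), 10)
  expect_equal(eq$L, 100)
})

test_that("mask combination follows interval algebra", {
  A <- mask_set(data.frame(chrom = "chr1", start = 0, end = 100))
  B <- mask_set(data.frame(chrom = "chr1", start = 50, end = 60))
  sub <- combine_masks(list(A, B), "subtract")
  expect_equal(sub$intervals$start, c(0, 60))
  expect_equal(sub$intervals$end, c(50, 100))
  expect_equal(sub$L, 90)
  empty <- mask_set(data.frame(chrom = character(), start = integer(),
                               end = integer()))
  expect_equal(combine_masks(list(A, empty), "intersect")$L, 0)
  adj <- combine_masks(list(A, mask_set(data.frame(chrom = "chr1",
                                                   start = 100, end = 200))),
                       "union")
  expect_equal(mask_n_intervals(adj), 1)
  expect_equal(adj$L, 200)
  expect_error(combine_masks(list(A, B), "frobnicate"), "unknown mode")
  # identities: (A \ B) union B contains A; L is subadditive
  back <- combine_masks(list(sub, B), "union")
  expect_equal(combine_masks(list(A, back), "intersect")$L, A$L)
  expect_lte(back$L, sub$L + B$L)
})

test_that("Watterson estimates reproduce the published rate arithmetic", {
  kgp <- watterson_mu(c(Alu = 8554, L1 = 2047, SVA = 329),
                      c(Alu = 1113.0e6, L1 = 959.9e6, SVA = 1113.0e6),
                      n_individuals = 2504, Ne = 1e4)
  expect_equal(kgp$a, harmonic_number(5007))
  expect_equal(kgp$mu_combined, 1.39e-11, tolerance = 5e-3)
  expect_equal(signif(kgp$mu_combined, 2), 1.4e-11)

  ddd <- watterson_mu(c(Alu = 653, L1 = 107, SVA = 30), 74.2e6,
                      n_individuals = 17032, Ne = 1e4)
  expect_equal(signif(ddd$mu_combined, 2), 1.2e-11)
  expect_equal(ddd$mu_combined, sum(ddd$per_class$mu))

  zero <- watterson_mu(c(Alu = 0, L1 = 0), 1e9, 100)
  expect_equal(zero$mu_combined, 0)
  expect_error(watterson_mu(c(Alu = 5), c(Alu = 0), 100), "L = 0")
  expect_error(watterson_mu(c(Alu = 5), c(Alu = 1e6), 1), ">= 2")
})

test_that("extrapolation arithmetic reproduces the genome-wide expectation", {
  e <- expected_denovo(1.2e-11, 9738)
  expect_equal(e$expected, 677)
  bp <- expected_denovo(1.39e-11, 1)$births_per_event
  expect_gt(bp, 12)
  expect_lt(bp, 14)
  expect_equal(expected_denovo(0, 100)$expected, 0)
})

test_that("Watterson recovery: estimates track a known simulated rate", {
  # Sites per class drawn at the Watterson expectation E[S] = theta a L;
  # the estimator must recover mu within 10% relative error on average.
  mu_true <- 1.0e-11
  Ne <- 1e4
  n <- 500
  L <- 1e9
  a <- harmonic_number(2 * n - 1)
  ES <- (8 * Ne * mu_true) * a * L
  set.seed(33)
  est <- vapply(1:100, function(i) {
    S <- rpois(1, ES)
    watterson_mu(c(Alu = S), c(Alu = L), n, Ne)$mu_combined
  }, numeric(1))
  expect_lt(abs(mean(est) - mu_true) / mu_true, 0.1)
  expect_true(mean(abs(est - mu_true) / mu_true < 0.1) > 0.95)
})

test_that("uniform placements converge to compartment fractions", {
  g <- gen_toy_genome(1, 1e6, 10, seed = 1)
  sim <- simulate_denovo_placements(677, 100, g, seed = 3)
  frac <- g$compartments / sum(g$chrom_len)
  for (comp in c("exonic", "intronic", "enhancer", "intergenic")) {
    lam <- sim$lambda[sim$compartment == comp]
    expected <- 677 * frac[[comp]]
    mc_se <- sqrt(677 * frac[[comp]] * (1 - frac[[comp]]) / 100)
    expect_lt(abs(lam - expected), max(3 * mc_se, 1e-9))
  }
  expect_equal(sum(sim$lambda[sim$compartment %in%
                                c("exonic", "intronic", "enhancer",
                                  "intergenic")]), 677)
  # determinism at reps = 1
  s1 <- simulate_denovo_placements(50, 1, g, seed = 9)
  s2 <- simulate_denovo_placements(50, 1, g, seed = 9)
  expect_identical(attr(s1, "rep_counts"), attr(s2, "rep_counts"))
  # gene-set restricted compartments are bounded by their parents
  gs <- list(dd = unique(g$genes$transcript_id)[1:3])
  sim2 <- simulate_denovo_placements(300, 20, g, gene_sets = gs, seed = 4)
  expect_lte(sim2$lambda[sim2$compartment == "exonic:dd"],
             sim2$lambda[sim2$compartment == "exonic"])
})

test_that("the normal interval on lambda reproduces the printed bounds", {
  ci <- lambda_interval(12.3)
  expect_equal(round(unname(ci["lower"]), 1), 5.4)
  expect_equal(round(unname(ci["upper"]), 1), 19.2)
  sim <- data.frame(lambda = 12.3)
  expect_true(ci["lower"] < 12.3 && ci["upper"] > 12.3)
})

test_that("Poisson and binomial tails equal brute-force summation", {
  expect_equal(poisson_upper_p(0, 5), 1)
  expect_equal(poisson_upper_p(3, 1), 1 - exp(-1) * (1 + 1 + 0.5),
               tolerance = 1e-12)
  expect_equal(poisson_upper_p(12, 12.3), oracle_poisson_upper(12, 12.3),
               tolerance = 1e-12)
  expect_equal(round(poisson_upper_p(12, 12.3), 4), 0.5722)
  set.seed(8)
  for (i in 1:25) {
    lam <- runif(1, 0.1, 50)
    obs <- sample(0:60, 1)
    expect_equal(poisson_upper_p(obs, lam), oracle_poisson_upper(obs, lam),
                 tolerance = 1e-12)
  }
  expect_error(poisson_upper_p(-1, 2), ">= 0")

  expect_equal(binomial_upper_p(4, 6, 0.5), 22 / 64)
  expect_equal(binomial_upper_p(0, 6, 0.37), 1)
  expect_equal(binomial_upper_p(6, 6, 0), 0)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(binomial_upper_p(k, n, p), oracle_binom_upper(k, n, p),
                 tolerance = 1e-12)
  }
})
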