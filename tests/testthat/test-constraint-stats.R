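# Constraint metrics, enrichment tests, SNV missingness QC, downsampling
# z-scores, and the expression filter.

test_that("singleton proportion carries the closed-form Wald interval", {
  res <- singleton_proportion(c(1, 1, 1, 1, 2, 3, 2, 5, 2, 4))
  expect_equal(unname(res["estimate"]), 0.4)
  expect_equal(unname(res["half_width"]), 1.96 * sqrt(0.4 * 0.6 / 10),
               tolerance = 1e-4)
  all_s <- singleton_proportion(rep(1, 8))
  expect_equal(unname(all_s["estimate"]), 1)
  expect_equal(unname(all_s["half_width"]), 0)
  expect_error(singleton_proportion(integer(0)), "empty")
})

test_that("neutral-spectrum cohorts show the Watterson singleton fraction", {
  g <- gen_toy_genome(1, 5e5, 4, seed = 2)
  co <- gen_mei_cohort(g, 400, class_means = c(Alu = 40), seed = 17)
  carrier <- rowSums(co$geno >= 1)
  res <- singleton_proportion(carrier)
  n_hap <- 2 * 400
  expected <- 1 / harmonic_number(n_hap - 1)
  # carrier singletons approximate allele-count singletons for rare sites
  expect_lt(abs(res["estimate"] - expected), 3 * res["half_width"])
})

test_that("pLI proportion flags the LoF-intolerant fraction", {
  expect_equal(unname(pli_proportion(runif(20, 0, 0.5))["estimate"]), 0)
  res <- pli_proportion(c(rep(0.99, 5), rep(0.2, 15)))
  expect_equal(unname(res["estimate"]), 0.25)
  expect_equal(unname(res["half_width"]), 1.96 * sqrt(0.25 * 0.75 / 20),
               tolerance = 1e-4)
  expect_warning(empty <- pli_proportion(numeric(0)), "undefined")
  expect_true(is.na(empty["estimate"]))
  # boundary: pLI exactly 0.9 is not high-pLI
  expect_equal(unname(pli_proportion(c(0.9, 0.91))["estimate"]), 0.5)
})

test_that("proportions pool as carrier-weighted averages across partitions", {
  set.seed(12)
  cc_a <- sample(1:5, 30, replace = TRUE)
  cc_b <- sample(1:5, 50, replace = TRUE)
  pooled <- singleton_proportion(c(cc_a, cc_b))["estimate"]
  parts <- (30 * singleton_proportion(cc_a)["estimate"] +
              50 * singleton_proportion(cc_b)["estimate"]) / 80
  expect_equal(unname(pooled), unname(parts))
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  expect_equal(fisher_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_2x2(1, 1, 1, 1), 1)
  expect_warning(p <- fisher_2x2(0, 0, 3, 4), "degenerate")
  expect_equal(p, 1)
  set.seed(14)
  for (i in 1:30) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    expect_equal(fisher_2x2(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_2x2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
})

test_that("orientation bias test matches the closed-form chi-square", {
  even <- orientation_bias_test(50, 50)
  expect_equal(even$chisq, 0)
  expect_equal(even$p, 1)
  skew <- orientation_bias_test(60, 40)
  expect_equal(skew$chisq, 4)
  expect_equal(round(skew$p, 4), 0.0455)
  extreme <- orientation_bias_test(0, 10)
  expect_equal(extreme$chisq, 10)
  expect_equal(extreme$p, pchisq(10, 1, lower.tail = FALSE))
  ref <- chisq.test(c(60, 40), p = c(0.5, 0.5))
  expect_equal(skew$p, unname(ref$p.value), tolerance = 1e-12)
  expect_error(orientation_bias_test(0, 0), "positive")
})

test_that("missingness filter applies genotype and variant thresholds", {
  gt <- data.frame(
    variant_id = rep(c("v1", "v2", "v3"), each = 4),
    sample = rep(paste0("s", 1:4), 3),
    gt = c(1L, 0L, 1L, 0L,
           1L, 1L, 1L, 0L,
           1L, 0L, 0L, 0L),
    gq = c(19, 50, 50, 50,   50, 50, 50, 50,  50, 19, 19, 19),
    dp = c(30, 30, 30, 7,    30, 30, 30, 30,  30, 30, 30, 30),
    ad_ref = c(15, 30, 15, 7, 30, 15, 15, 30, 15, 30, 30, 30),
    ad_alt = c(15, 0, 15, 0,  0, 15, 15, 0,   15, 0, 0, 0),
    stringsAsFactors = FALSE)
  gt$ad_ref[5] <- 30; gt$ad_alt[5] <- 0
  gt$gt[5] <- 1L  # het with 0/30 balance -> AD p << 0.001 -> missing
  res <- snv_missingness_filter(gt)
  m <- res$genotypes
  expect_true(m$missing[m$variant_id == "v1" & m$sample == "s1"])  # GQ 19
  expect_true(m$missing[m$variant_id == "v1" & m$sample == "s4"])  # DP 7
  expect_true(m$missing[m$variant_id == "v2" & m$sample == "s1"])  # AD
  expect_false(m$missing[m$variant_id == "v2" & m$sample == "s2"]) # 15/15
  # v3: 3 of 4 genotypes missing (> 50%) -> dropped
  expect_true("v3" %in% names(res$dropped))
  expect_false("v3" %in% res$keep)
  expect_true(all(c("v1", "v2") %in% res$keep))
  # VQSLOD site prefilter
  res2 <- snv_missingness_filter(gt, sites = data.frame(
    variant_id = c("v1", "v2", "v3"), vqslod = c(-3, 1, 1)))
  expect_equal(unname(res2$dropped["v1"]), "vqslod")
  # order independence across genotype rows
  res3 <- snv_missingness_filter(gt[sample(nrow(gt)), ])
  expect_setequal(res3$keep, res$keep)
})

test_that("downsampling z-scores are centred and scaled correctly", {
  g <- gen_toy_genome(1, 5e5, 4, seed = 2)
  co <- gen_mei_cohort(g, 200, class_means = c(Alu = 15), seed = 19)
  base <- downsample_zscore(co, c(Alu = 0), subset_size = 100, reps = 200,
                            seed = 3)
  # reference at the mean -> z ~ 0; at mean + sd -> z ~ 1
  at_mean <- downsample_zscore(co, c(Alu = round(base$mean)),
                               subset_size = 100, reps = 200, seed = 3)
  expect_lt(abs(at_mean$z), 0.2)
  shifted <- downsample_zscore(co, c(Alu = round(base$mean + base$sd)),
                               subset_size = 100, reps = 200, seed = 3)
  expect_lt(abs(shifted$z - 1), 0.3)
  expect_error(downsample_zscore(co, c(Alu = 5), subset_size = 200),
               "smaller than the cohort")
})

test_that("median expression filter keeps genes at the boundary", {
  m <- rbind(lowexp = c(0, 0, 5), atone = c(1, 1, 1), high = c(2, 3, 4))
  expect_setequal(median_expression_filter(m), c("atone", "high"))
  m2 <- rbind(m, empty = c(NA, NA, NA))
  expect_warning(keep <- median_expression_filter(m2), "excluded")
  expect_setequal(keep, c("atone", "high"))
})
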