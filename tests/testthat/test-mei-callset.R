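# MEI call-set filtering, low-complexity flagging, consequence annotation,
# allele frequency recomputation, and per-individual summaries.

test_that("low-complexity flag matches the 15-mer enumeration oracle", {
  expect_true(low_complexity_flag(paste0("GCGTA", strrep("A", 15), "CGTGC")))
  expect_true(low_complexity_flag("ATATATATATATATA"))
  expect_false(low_complexity_flag(strrep("ACG", 20)))
  # N breaks runs
  expect_false(low_complexity_flag(paste0(strrep("A", 10), "N",
                                          strrep("A", 10))))
  expect_error(low_complexity_flag("ACGTX"), "non-ACGTN")
  set.seed(3)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:80, 1),
                      replace = TRUE, prob = c(.3, .3, .2, .1, .1)),
               collapse = "")
    expect_equal(low_complexity_flag(s), oracle_low_complexity(s), info = s)
  }
  # adversarial: two-nucleotide runs just under / at the boundary
  expect_false(low_complexity_flag(paste0("ACGTG", strrep("AT", 7), "GC")))
  expect_true(low_complexity_flag(paste0("CCGTG", strrep("AT", 7), "A")))
})

test_that("call-set filters retain and attribute removals as specified", {
  sites <- rbind(
    make_site("ok"),
    make_site("low_cr"),
    make_site("sr2", sr = 2L),
    make_site("sr3", sr = 3L),
    make_site("assess2", assess = 2L),
    make_site("badfilter", filter = "hDP"),
    make_site("rsd_ok", filter = "rSD"),
    make_site("lc_flag", filter = "PASS;lc")
  )
  n <- nrow(sites)
  geno <- matrix(0L, n, 20, dimnames = list(sites$site_id, paste0("s", 1:20)))
  geno[, 1] <- 1L
  geno["low_cr", 5:20] <- NA_integer_  # call rate 4/20 = 0.20
  cs <- manual_callset(sites, geno)
  out <- apply_callset_filters(cs)
  expect_setequal(out$sites$site_id, c("ok", "sr3", "rsd_ok"))
  ledger <- attr(out, "ledger")
  expect_equal(unname(ledger["lc"]), 1)
  expect_equal(unname(ledger["call_rate"]), 1)
  expect_equal(unname(ledger["split_reads"]), 1)
  expect_equal(unname(ledger["assess"]), 1)
  expect_equal(unname(ledger["filter"]), 1)
  expect_equal(unname(ledger["retained"]), 3)
  # boundary: call rate exactly 0.25 passes
  geno2 <- geno
  geno2["low_cr", ] <- c(rep(0L, 5), rep(NA_integer_, 15))
  out2 <- apply_callset_filters(manual_callset(sites, geno2))
  expect_true("low_cr" %in% out2$sites$site_id)
  # idempotence
  out_twice <- apply_callset_filters(out)
  expect_identical(out$sites, out_twice$sites)
  expect_identical(out$geno, out_twice$geno)
  expect_error(apply_callset_filters(cs, cohort_size = 0), "positive")
})

test_that("ledger attributes each removal to the first failing criterion", {
  # a record failing everything is attributed to lc (first in fixed order)
  sites <- rbind(make_site("allbad", filter = "hDP;lc", sr = 0L, assess = 0L),
                 make_site("crsr"))
  sites$sr[2] <- 1L
  geno <- matrix(NA_integer_, 2, 10,
                 dimnames = list(sites$site_id, paste0("s", 1:10)))
  out <- apply_callset_filters(manual_callset(sites, geno))
  ledger <- attr(out, "ledger")
  expect_equal(unname(ledger["lc"]), 1)
  expect_equal(unname(ledger["call_rate"]), 1)  # crsr: call rate before SR
  expect_equal(unname(ledger["retained"]), 0)
})

test_that("reference-window scan adds the lc filter flag", {
  g <- list(chrom_len = c(chr1 = 300L))
  g$seq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("ACGTG", 20),   # 0..99 complex
    strrep("A", 20),        # 100..119 poly-A
    strrep("TCAGG", 36))))
  sites <- rbind(make_site("in_lc", pos0 = 110L),
                 make_site("clean", pos0 = 250L))
  cs <- manual_callset(sites, matrix(1L, 2, 2, dimnames = list(
    sites$site_id, c("a", "b"))))
  out <- flag_low_complexity_sites(cs, g$seq)
  expect_equal(out$sites$filter, c("PASS;lc", "PASS"))
  # flagging is idempotent
  out2 <- flag_low_complexity_sites(out, g$seq)
  expect_identical(out2$sites$filter, out$sites$filter)
})

test_that("consequence annotation is a single-label partition with priority", {
  g <- manual_genome()
  # enhancer beats everything; exon beats intron; default intergenic
  ann <- annotate_consequence(
    g, rep("chr1", 5), c(20100L, 1100L, 1500L, 30000L, 10050L))
  expect_equal(ann$consequence,
               c("enhancer", "exonic", "intronic", "intergenic", "exonic"))
  expect_equal(ann$gene[2], "TXA")
  expect_equal(ann$pli[2], 0.99)
  expect_equal(ann$gene[5], "TXB")
  expect_true(is.na(ann$gene[1]))
  expect_error(annotate_consequence(g, "chr1", 50001L), "off-chromosome")
  expect_error(annotate_consequence(g, "chr9", 10L), "off-chromosome")

  # enhancer priority when an enhancer overlaps a gene body
  g2 <- g
  g2$enhancers <- rbind(g2$enhancers,
                        data.frame(chrom = "chr1", start = 1400L,
                                   end = 1600L))
  expect_equal(annotate_consequence(g2, "chr1", 1500L)$consequence,
               "enhancer")

  # partition: counts over consequences sum to total records
  set.seed(5)
  pos <- sample.int(50000L, 400L) - 1L
  ann_all <- annotate_consequence(g, rep("chr1", 400), pos)
  expect_equal(sum(table(ann_all$consequence)), 400)
})

test_that("allele frequencies account for missing genotypes", {
  sites <- rbind(make_site("s1"), make_site("s2"), make_site("s3"))
  geno <- matrix(0L, 3, 100, dimnames = list(sites$site_id, paste0("i", 1:100)))
  geno["s1", 1] <- 1L
  geno["s2", 1] <- 1L
  geno["s2", 51:100] <- NA_integer_
  cs <- manual_callset(sites, geno)
  af <- recompute_af(cs)
  expect_equal(af, c(1 / 200, 1 / 100, 0))
  sub <- recompute_af(cs, subset = paste0("i", 1:10))
  expect_equal(sub[1], 1 / 20)
  expect_error(recompute_af(cs, subset = character(0)), "non-empty")
  geno["s3", ] <- NA_integer_
  expect_warning(af2 <- recompute_af(manual_callset(sites, geno)),
                 "missing")
  expect_true(is.na(af2[3]))
})

test_that("per-individual summaries recover the mean and accept Poisson data", {
  g <- gen_toy_genome(1, 5e5, 4, seed = 2)
  co <- gen_mei_cohort(g, 400, class_means = c(Alu = 23.6), seed = 6)
  s <- per_individual_count_summary(co)
  alu <- s[s$class == "Alu", ]
  expect_lt(abs(alu$mean - 23.6), 3 * alu$sd / sqrt(400))

  # genuinely Poisson counts are not rejected by the GOF test
  set.seed(10)
  rejections <- vapply(1:40, function(i) {
    counts <- rpois(500, 33.0)
    retrotools:::.poisson_gof_p(counts) < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
  # and a gross misfit is rejected
  set.seed(11)
  expect_lt(retrotools:::.poisson_gof_p(rbinom(500, 40, 0.5)), 0.01)

  one <- manual_callset(make_site("s1"),
                        matrix(1L, 1, 1, dimnames = list("s1", "only")))
  expect_warning(res <- per_individual_count_summary(one), "single individual")
  expect_equal(res$sd, c(0, 0))
})
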