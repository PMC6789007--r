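# Cohort simulator for mobile element insertion (MEI) call sets.
#
# Sites are drawn from a site-frequency spectrum (neutral 1/i by default, so
# Watterson-based rate estimation on the fixture has an analytic truth);
# allele counts are placed on founder haplotypes by sampling without
# replacement, trio probands inherit Mendelian genotypes from their parents,
# and de novo events / mosaic parents can be planted with known truth.

.sfs_draw <- function(n_sites, n_hap, sfs = c("neutral", "uniform")) {
  sfs <- match.arg(sfs)
  i <- seq_len(n_hap - 1L)
  w <- switch(sfs, neutral = 1 / i, uniform = rep(1, length(i)))
  sample(i, n_sites, replace = TRUE, prob = w / sum(w))
}

# Expected probability that a diploid founder carries a site, under the SFS.
.expected_carrier_prob <- function(n_hap, sfs) {
  i <- seq_len(n_hap - 1L)
  w <- switch(sfs, neutral = 1 / i, uniform = rep(1, length(i)))
  w <- w / sum(w)
  q <- 1 - (1 - i / n_hap)^2
  sum(w * q)
}

#' Simulate an MEI cohort with trios, planted de novos, and mosaic parents
#'
#' Generates a population sample of MEI sites whose per-founder site counts
#' match the requested per-class means (per-individual counts are then
#' approximately Poisson, as observed in real exome cohorts) and whose
#' allele counts follow the requested site-frequency spectrum. Trio probands
#' inherit genotypes from their parents; planted de novo sites are
#' heterozygous in a single proband and absent from all other genomes;
#' planted mosaic parents are genotyped homozygous reference but carry the
#' insertion at a known read-level allele fraction.
#'
#' Site counts are tuned so that the summed carrier probability equals the
#' requested mean: sites are drawn sequentially from the spectrum and the
#' final site's allele count is chosen to close the residual, keeping the
#' realised per-founder expectation on target.
#'
#' @param genome A [gen_toy_genome()] genome (positions are placed uniformly).
#' @param n_individuals Total cohort size, including trio members.
#' @param class_means Named vector of mean sites per founder (unrelated
#'   individual) per ME class; defaults to the per-parent means observed in
#'   large exome cohorts (`Alu` 23.6, `L1` 2.8, `SVA` 0.2).
#' @param n_trios Number of trios; the first `3 * n_trios` individuals are
#'   organised as (proband, father, mother) and probands' genotypes are
#'   inherited, not drawn.
#' @param n_denovo Number of planted de novo sites (each in a distinct,
#'   randomly chosen proband; requires `n_trios >= 1` when positive).
#' @param sfs `"neutral"` (1/i) or `"uniform"` allele-count spectrum.
#' @param n_mosaic Number of planted mosaic-parent sites.
#' @param mosaic_fraction True read-level allele fraction of mosaic parents.
#' @param seed Integer seed.
#' @return An object of class `mei_cohort`: `sites` (data frame: `site_id`,
#'   `chrom`, `pos0`, `class`, `ac_true`, `assess`, `sr`, `filter`,
#'   `insert_len`), `geno` (integer matrix sites x individuals with values
#'   0/1/2), `pedigree` (`proband`, `father`, `mother`), `samples`, and
#'   `truth` (`denovo`, `mosaic` data frames).
#' @export
gen_mei_cohort <- function(genome, n_individuals,
                           class_means = c(Alu = 23.6, L1 = 2.8, SVA = 0.2),
                           n_trios = 0L, n_denovo = 0L,
                           sfs = c("neutral", "uniform"),
                           n_mosaic = 0L, mosaic_fraction = 0.1,
                           seed = 1L) {
  sfs <- match.arg(sfs)
  stopifnot(all(class_means > 0), n_trios * 3 <= n_individuals)
  if (n_denovo > 0 && n_trios == 0)
    stop("planting de novo sites requires at least one trio")
  if (n_mosaic > 0 && n_trios == 0)
    stop("planting mosaic parents requires at least one trio")
  set.seed(seed)

  ids <- character(0)
  pedigree <- data.frame(proband = character(), father = character(),
                         mother = character(), stringsAsFactors = FALSE)
  if (n_trios > 0) {
    pedigree <- data.frame(proband = sprintf("T%03d_pro", seq_len(n_trios)),
                           father = sprintf("T%03d_fa", seq_len(n_trios)),
                           mother = sprintf("T%03d_mo", seq_len(n_trios)),
                           stringsAsFactors = FALSE)
    ids <- as.vector(t(as.matrix(pedigree)))
  }
  n_single <- n_individuals - 3L * n_trios
  if (n_single > 0) ids <- c(ids, sprintf("P%04d", seq_len(n_single)))
  founders <- setdiff(ids, pedigree$proband)
  n_f <- length(founders)

  empty <- structure(list(
    sites = data.frame(site_id = character(), chrom = character(),
                       pos0 = integer(), class = character(),
                       ac_true = integer(), assess = integer(), sr = integer(),
                       filter = character(), insert_len = integer(),
                       stringsAsFactors = FALSE),
    geno = matrix(integer(0), 0, length(ids),
                  dimnames = list(NULL, if (length(ids)) ids else NULL)),
    pedigree = pedigree, samples = ids,
    truth = list(denovo = data.frame(site_id = character(),
                                     proband = character(),
                                     stringsAsFactors = FALSE),
                 mosaic = data.frame(site_id = character(),
                                     parent = character(), proband = character(),
                                     fraction = numeric(),
                                     stringsAsFactors = FALSE))),
    class = "mei_cohort")
  if (n_individuals == 0) return(empty)

  n_hap <- 2L * n_f
  # Draw allele counts per class until the summed carrier probability reaches
  # the requested mean; the closing site's count minimises the residual.
  class_ac <- lapply(names(class_means), function(cl) {
    target <- class_means[[cl]]
    i <- seq_len(n_hap - 1L)
    qi <- 1 - (1 - i / n_hap)^2
    acs <- integer(0)
    acc <- 0
    repeat {
      ac <- .sfs_draw(1L, n_hap, sfs)
      if (acc + qi[ac] >= target) {
        close_ac <- i[which.min(abs(qi - (target - acc)))]
        acs <- c(acs, close_ac)
        break
      }
      acs <- c(acs, ac)
      acc <- acc + qi[ac]
    }
    acs
  })
  names(class_ac) <- names(class_means)

  site_class <- rep(names(class_ac), lengths(class_ac))
  ac <- unlist(class_ac, use.names = FALSE)
  n_sites <- length(ac)
  chrom <- sample(names(genome$chrom_len), n_sites, replace = TRUE)
  pos0 <- vapply(chrom, function(ch)
    sample.int(genome$chrom_len[ch], 1L) - 1L, integer(1))

  # Place alt alleles on founder haplotypes without replacement.
  geno <- matrix(0L, n_sites, length(ids), dimnames = list(NULL, ids))
  for (s in seq_len(n_sites)) {
    hap <- sample.int(n_hap, ac[s])
    carrier <- tabulate((hap - 1L) %/% 2L + 1L, nbins = n_f)
    geno[s, founders] <- as.integer(carrier)
  }
  # Probands inherit one allele from each parent.
  if (n_trios > 0) {
    for (t in seq_len(n_trios)) {
      fa <- geno[, pedigree$father[t]]
      mo <- geno[, pedigree$mother[t]]
      transmit <- function(g) ifelse(g == 2L, 1L,
                                     ifelse(g == 1L, rbinom(length(g), 1L, 0.5), 0L))
      geno[, pedigree$proband[t]] <- transmit(fa) + transmit(mo)
    }
  }

  truth_dn <- empty$truth$denovo
  if (n_denovo > 0) {
    pro <- sample(pedigree$proband, n_denovo,
                  replace = n_denovo > nrow(pedigree))
    dn_class <- sample(names(class_means), n_denovo, replace = TRUE,
                       prob = class_means / sum(class_means))
    dn_chrom <- sample(names(genome$chrom_len), n_denovo, replace = TRUE)
    dn_pos <- vapply(dn_chrom, function(ch)
      sample.int(genome$chrom_len[ch], 1L) - 1L, integer(1))
    dn_geno <- matrix(0L, n_denovo, length(ids), dimnames = list(NULL, ids))
    dn_geno[cbind(seq_len(n_denovo), match(pro, ids))] <- 1L
    geno <- rbind(geno, dn_geno)
    site_class <- c(site_class, dn_class)
    ac <- c(ac, rep(1L, n_denovo))
    chrom <- c(chrom, dn_chrom)
    pos0 <- c(pos0, dn_pos)
    truth_dn <- data.frame(site_id = sprintf("DN%03d", seq_len(n_denovo)),
                           proband = pro, stringsAsFactors = FALSE)
  }

  truth_mo <- empty$truth$mosaic
  if (n_mosaic > 0) {
    trio_idx <- sample.int(nrow(pedigree), n_mosaic,
                           replace = n_mosaic > nrow(pedigree))
    parent <- ifelse(runif(n_mosaic) < 0.5, "father", "mother")
    par_id <- ifelse(parent == "father", pedigree$father[trio_idx],
                     pedigree$mother[trio_idx])
    mo_chrom <- sample(names(genome$chrom_len), n_mosaic, replace = TRUE)
    mo_pos <- vapply(mo_chrom, function(ch)
      sample.int(genome$chrom_len[ch], 1L) - 1L, integer(1))
    mo_geno <- matrix(0L, n_mosaic, length(ids), dimnames = list(NULL, ids))
    mo_geno[cbind(seq_len(n_mosaic),
                  match(pedigree$proband[trio_idx], ids))] <- 1L
    geno <- rbind(geno, mo_geno)
    site_class <- c(site_class, rep("Alu", n_mosaic))
    ac <- c(ac, rep(1L, n_mosaic))
    chrom <- c(chrom, mo_chrom)
    pos0 <- c(pos0, mo_pos)
    truth_mo <- data.frame(site_id = sprintf("MO%03d", seq_len(n_mosaic)),
                           parent = par_id,
                           proband = pedigree$proband[trio_idx],
                           fraction = mosaic_fraction, stringsAsFactors = FALSE)
  }

  n_tot <- length(ac)
  site_id <- sprintf("MEI%05d", seq_len(n_tot))
  if (nrow(truth_dn))
    site_id[(n_sites + 1L):(n_sites + n_denovo)] <- truth_dn$site_id
  if (nrow(truth_mo))
    site_id[(n_tot - n_mosaic + 1L):n_tot] <- truth_mo$site_id
  ins_len <- ifelse(site_class == "Alu", sample(250:320, n_tot, TRUE),
                    ifelse(site_class == "L1", sample(500:6000, n_tot, TRUE),
                           sample(700:1600, n_tot, TRUE)))
  sites <- data.frame(site_id = site_id, chrom = chrom, pos0 = pos0,
                      class = site_class, ac_true = as.integer(ac),
                      assess = 5L, sr = 10L, filter = "PASS",
                      insert_len = as.integer(ins_len),
                      stringsAsFactors = FALSE)
  rownames(geno) <- site_id
  structure(list(sites = sites, geno = geno, pedigree = pedigree,
                 samples = ids,
                 truth = list(denovo = truth_dn, mosaic = truth_mo)),
            class = "mei_cohort")
}

#' Simulate per-site read support for trio members
#'
#' Draws sequencing depth and insertion-supporting read counts for every
#' (site, sample) pair: heterozygous genotypes at allele fraction 0.5,
#' homozygous alternates at 0.995, homozygous reference at an error rate, and
#' planted mosaic parents at their true fraction.
#'
#' @param cohort A [gen_mei_cohort()] cohort.
#' @param depth Mean sequencing depth (Poisson).
#' @param error_rate Alt-read rate for true homozygous-reference genotypes.
#' @param seed Integer seed.
#' @return Data frame: `site_id`, `sample`, `alt`, `ref` read counts.
#' @export
gen_site_reads <- function(cohort, depth = 30, error_rate = 0.005, seed = 1L) {
  set.seed(seed)
  geno <- cohort$geno
  long <- expand.grid(site_id = rownames(geno), sample = colnames(geno),
                      stringsAsFactors = FALSE)
  g <- geno[cbind(long$site_id, long$sample)]
  frac <- ifelse(g == 2L, 0.995, ifelse(g == 1L, 0.5, error_rate))
  mo <- cohort$truth$mosaic
  if (nrow(mo)) {
    key <- paste(long$site_id, long$sample)
    hit <- match(paste(mo$site_id, mo$parent), key)
    frac[hit[!is.na(hit)]] <- mo$fraction[!is.na(hit)]
  }
  dp <- rpois(nrow(long), depth)
  alt <- rbinom(nrow(long), dp, frac)
  data.frame(site_id = long$site_id, sample = long$sample,
             alt = alt, ref = dp - alt, stringsAsFactors = FALSE)
}

#' @export
print.mei_cohort <- function(x, ...) {
  cat("mei_cohort:", nrow(x$sites), "site(s) x", length(x$samples),
      "individual(s);", nrow(x$pedigree), "trio(s)\n")
  if (nrow(x$sites))
    print(table(x$sites$class))
  invisible(x)
}
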