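# MEI call-set VCF input/output. On disk positions are 1-based (VCF); in
# memory they are 0-based (`pos0`). Reading goes through vcfR; writing uses
# a small formatter that emits a MELT-style VCF 4.2 with CLASS/ASSESS/SR
# INFO keys and GT genotypes.

#' Write an MEI call set as VCF
#'
#' @param callset A call set (`sites` + `geno`), e.g. from
#'   [gen_mei_cohort()].
#' @param path Output path.
#' @param chrom_len Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @param assess_key,sr_key,class_key INFO key names (defaults `ASSESS`,
#'   `SR`, `CLASS`).
#' @return `path`, invisibly.
#' @export
write_mei_vcf <- function(callset, path, chrom_len = NULL,
                          assess_key = "ASSESS", sr_key = "SR",
                          class_key = "CLASS") {
  s <- callset$sites
  g <- callset$geno
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(chrom_len))
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_len),
              as.integer(chrom_len)),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"ME class\">",
            class_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Caller assessment score\">",
            assess_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Split reads supporting the insertion\">",
            sr_key),
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insert length estimate\">",
    "##FILTER=<ID=rSD,Description=\"Ratio of split reads to discordant pairs outside expectation\">",
    "##FILTER=<ID=lc,Description=\"Within 50 bp of a low-complexity run\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[callset$geno + 1L],
                   nrow = nrow(g), ncol = ncol(g))
  gt_str[is.na(callset$geno)] <- "./."
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos0[i] + 1L, s$site_id[i], "N",
            sprintf("<INS:ME:%s>", s$class[i]), ".", s$filter[i],
            sprintf("%s=%s;%s=%d;%s=%d;SVLEN=%d", class_key, s$class[i],
                    assess_key, s$assess[i], sr_key, s$sr[i],
                    s$insert_len[i]),
            "GT", gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an MEI call set from VCF
#'
#' Converts 1-based VCF positions to 0-based internal coordinates, preserves
#' missing genotypes, and rejects records lacking the required INFO keys
#' with an error naming the key and the record.
#'
#' @param path VCF path.
#' @param assess_key,sr_key,class_key Required INFO key names.
#' @return A call set: list with `sites` (`site_id`, `chrom`, `pos0`,
#'   `class`, `ac_true = NA`, `assess`, `sr`, `filter`, `insert_len`),
#'   `geno` (integer matrix), `samples`.
#' @export
read_mei_vcf <- function(path, assess_key = "ASSESS", sr_key = "SR",
                         class_key = "CLASS") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  grab_info <- function(key, as_int = FALSE) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v) || all(is.na(v)))
      stop("INFO key '", key, "' absent from ", path)
    miss <- which(is.na(v))
    if (length(miss))
      stop("record ", miss[1], " (", fix[miss[1], "CHROM"], ":",
           fix[miss[1], "POS"], ") is missing INFO key '", key, "'")
    if (as_int) as.integer(v) else v
  }
  cls <- grab_info(class_key)
  assess <- grab_info(assess_key, as_int = TRUE)
  sr <- grab_info(sr_key, as_int = TRUE)
  svlen <- suppressWarnings(
    as.integer(vcfR::extract.info(vcf, element = "SVLEN")))
  sites <- data.frame(
    site_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos0 = as.integer(fix[, "POS"]) - 1L, class = cls,
    ac_true = NA_integer_, assess = assess, sr = sr,
    filter = fix[, "FILTER"], insert_len = svlen,
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- matrix(NA_integer_, nrow = n, ncol = ncol(gt),
                 dimnames = list(sites$site_id, colnames(gt)))
  alt_counts <- function(x) {
    alleles <- strsplit(x, "[/|]")
    vapply(alleles, function(a) {
      if (any(a == "." | is.na(a))) NA_integer_ else sum(a != "0")
    }, integer(1))
  }
  for (j in seq_len(ncol(gt))) geno[, j] <- alt_counts(gt[, j])
  list(sites = sites, geno = geno, samples = colnames(geno))
}

#' Parse a VCF FILTER string into its component set
#'
#' @param filter Character vector of FILTER strings (`;`-separated).
#' @return List of character vectors.
#' @export
parse_filter_set <- function(filter) strsplit(filter, ";", fixed = TRUE)
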