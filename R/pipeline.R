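# Pipeline configuration and the end-to-end driver tying the stages
# together: PPG calling -> MEI call-set filters -> trio de novo -> rate
# estimation -> burden simulation -> constraint summaries.

#' Build a pipeline configuration
#'
#' All thresholds default to the values the analysis was designed around;
#' every one of them is recorded in the run log so a filter ledger can be
#' audited. The configuration round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used by every stochastic stage.
#' @param vcf,pedigree,reads,genes_bed,enhancers_bed,chrom_sizes Input paths
#'   (any may be `NULL`; stages without inputs are skipped).
#' @param thresholds Named list overriding individual defaults:
#'   `step1_min_drp` (4), `min_support` (5), `min_call_rate` (0.25),
#'   `min_sr` (3), `min_assess` (3), `lc_flank` (50), `lc_min_run` (15),
#'   `Ne` (10000), `mask_bp` (total accessible bp used as the Watterson
#'   denominator; defaults to the full toy genome), `sim_reps` (100),
#'   `high_pli` (0.9).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, vcf = NULL, pedigree = NULL,
                            reads = NULL, genes_bed = NULL,
                            enhancers_bed = NULL, chrom_sizes = NULL,
                            thresholds = list()) {
  defaults <- list(step1_min_drp = 4L, min_support = 5L,
                   min_call_rate = 0.25, min_sr = 3L, min_assess = 3L,
                   lc_flank = 50L, lc_min_run = 15L, Ne = 1e4,
                   mask_bp = NULL, sim_reps = 100L, high_pli = 0.9)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  structure(list(out_dir = out_dir, seed = as.integer(seed), vcf = vcf,
                 pedigree = pedigree, reads = reads, genes_bed = genes_bed,
                 enhancers_bed = enhancers_bed, chrom_sizes = chrom_sizes,
                 thresholds = defaults),
            class = "pipeline_config")
}

#' Write a configuration as a flat key-value document
#' @param config A [pipeline_config()].
#' @param path Output path (YAML-formatted flat mapping).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(config[setdiff(names(config), "thresholds")],
            config$thresholds)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path Config path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  thr_names <- c("step1_min_drp", "min_support", "min_call_rate", "min_sr",
                 "min_assess", "lc_flank", "lc_min_run", "Ne", "mask_bp",
                 "sim_reps", "high_pli")
  pipeline_config(
    out_dir = flat$out_dir, seed = flat$seed, vcf = flat$vcf,
    pedigree = flat$pedigree, reads = flat$reads,
    genes_bed = flat$genes_bed, enhancers_bed = flat$enhancers_bed,
    chrom_sizes = flat$chrom_sizes,
    thresholds = flat[intersect(thr_names, names(flat))]
  )
}

#' Read a two-column chromosome-sizes file
#' @param path TSV: chromosome name, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  t <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  setNames(as.integer(t[[2]]), t[[1]])
}

.load_annotation <- function(config) {
  if (is.null(config$genes_bed) || is.null(config$chrom_sizes))
    stop("config stage error [annotation]: genes_bed and chrom_sizes are required")
  genes <- read_genes_bed(config$genes_bed)
  chrom_len <- read_chrom_sizes(config$chrom_sizes)
  enhancers <- if (!is.null(config$enhancers_bed))
    read_intervals_bed(config$enhancers_bed)
  else data.frame(chrom = character(), start = integer(), end = integer())
  tids <- unique(genes$transcript_id)
  genome <- structure(
    list(chrom_len = chrom_len, genes = genes,
         pli = data.frame(transcript_id = tids,
                          pli = rep(1, length(tids)),
                          stringsAsFactors = FALSE),
         enhancers = enhancers, seq = NULL),
    class = "toy_genome")
  genome$compartments <- compartment_bp(genome)
  genome
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in fixed order, the stages for which inputs are configured:
#' PPG calling from the SAM read set, MEI call-set filtering with the removal
#' ledger, per-individual count summaries, trio de novo candidate discovery,
#' Watterson rate estimation, burden simulation on the annotation, and
#' constraint proportions on founders. Per-stage logs, the seed, and every
#' threshold in effect are written to `<out_dir>/pipeline.log`; the
#' Table-style cohort summary goes to `<out_dir>/report.tsv`. A stage
#' failure halts the run with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `summary` (the
#'   per-class cohort table), `filter_ledger`, `denovo`, `rates`, `burden`,
#'   `ppg`, `constraint`, `thresholds`, `seed`.
#' @export
run_pipeline <- function(config) {
  thr <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("# pipeline run", paste0("seed: ", config$seed),
                 paste0("threshold ", names(thr), ": ",
                        vapply(thr, function(x)
                          if (is.null(x)) "default" else format(x),
                          character(1))))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage error [", name, "]: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, paste0("stage ", name, ": ok"))
    res
  }
  genome <- stage("annotation", .load_annotation(config))

  ppg <- NULL
  if (!is.null(config$reads))
    ppg <- stage("ppg", {
      reads <- read_sam(config$reads)
      call_ppgs(reads, genome, min_drp = thr$step1_min_drp,
                min_support = thr$min_support)
    })

  if (is.null(config$vcf))
    stop("config stage error [mei]: vcf input is required")
  callset <- stage("mei_filter", {
    cs <- read_mei_vcf(config$vcf)
    apply_callset_filters(cs, min_call_rate = thr$min_call_rate,
                          min_sr = thr$min_sr, min_assess = thr$min_assess)
  })
  ledger <- attr(callset, "ledger")
  log_lines <- c(log_lines,
                 paste0("filter ", names(ledger), ": ", ledger))

  pedigree <- if (!is.null(config$pedigree))
    stage("pedigree", read_pedigree(config$pedigree)) else NULL
  founders <- if (!is.null(pedigree))
    setdiff(colnames(callset$geno), pedigree$proband)
  else colnames(callset$geno)

  denovo <- if (!is.null(pedigree))
    stage("denovo", find_candidate_denovos(callset, pedigree)) else NULL

  counts <- stage("summary",
                  per_individual_count_summary(callset, samples = founders))

  rates <- stage("rates", {
    S <- table(factor(callset$sites$class,
                      levels = unique(callset$sites$class)))
    L <- thr$mask_bp %||% sum(genome$chrom_len)
    watterson_mu(setNames(as.numeric(S), names(S)), L,
                 n_individuals = length(founders), Ne = thr$Ne)
  })

  burden <- stage("burden", {
    births <- if (!is.null(pedigree)) nrow(pedigree) else length(founders)
    exp_dn <- expected_denovo(rates$mu_combined, births,
                              haploid_genome_len = sum(genome$chrom_len))
    sim <- simulate_denovo_placements(max(1L, exp_dn$expected),
                                      reps = thr$sim_reps, genome = genome,
                                      seed = config$seed)
    list(expected = exp_dn, compartments = sim)
  })

  constraint <- stage("constraint", {
    carrier <- rowSums(callset$geno[, founders, drop = FALSE] >= 1L,
                       na.rm = TRUE)
    keep <- carrier >= 1L
    ann <- annotate_consequence(genome, callset$sites$chrom[keep],
                                callset$sites$pos0[keep])
    list(singleton = singleton_proportion(carrier[keep]),
         pli = pli_proportion(ann$pli[!is.na(ann$pli)],
                              cutoff = thr$high_pli))
  })

  classes <- unique(callset$sites$class)
  dn_by_class <- if (!is.null(denovo))
    table(factor(denovo$class, levels = classes))
  else setNames(rep(NA_integer_, length(classes)), classes)
  summary_tab <- data.frame(
    class = c(classes, "Total-MEI"),
    total_sites = c(as.integer(table(factor(callset$sites$class,
                                            levels = classes))),
                    nrow(callset$sites)),
    mean_per_founder = round(c(counts$mean[match(classes, counts$class)],
                               counts$mean[counts$class == "all"]), 2),
    sd_per_founder = round(c(counts$sd[match(classes, counts$class)],
                             counts$sd[counts$class == "all"]), 2),
    denovo = c(as.integer(dn_by_class),
               if (!is.null(denovo)) nrow(denovo) else NA_integer_),
    stringsAsFactors = FALSE
  )
  write.table(summary_tab, file.path(config$out_dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))

  structure(list(summary = summary_tab, filter_ledger = ledger,
                 denovo = denovo, rates = rates, burden = burden, ppg = ppg,
                 constraint = constraint, thresholds = thr,
                 seed = config$seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
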