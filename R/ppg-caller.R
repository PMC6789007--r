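# Two-step processed pseudogene (retrogene) caller.
#
# Step 1 (discovery, per individual): iterate genes carrying a pLI score and
# count discordant read pairs (DRPs) whose mates overlap two different exons
# of the same transcript and whose apparent insert size exceeds the sample's
# 99.5th-percentile insert threshold. A gene with more than `min_drp`
# (default 4) such pairs is considered retroduplicated in that individual.
#
# Step 2 (genotyping, cohort-wide): evidence from all step-1-positive
# individuals is pooled into a junction model per gene; every individual is
# then typed positive when it shows at least five supporting fragments with
# at least one split read pair (SRP) and at least one DRP.

#' Per-sample insert-size discordance threshold
#'
#' Nearest-rank 99.5th percentile of the insert-size distribution; fragments
#' with insert size strictly above the threshold qualify as size-discordant.
#'
#' @param insert_sizes Numeric vector of fragment insert sizes (bp).
#' @param quantile Percentile defining discordance (default 0.995).
#' @return The threshold in bp.
#' @export
#' @examples
#' insert_size_threshold(1:1000)  # 995
insert_size_threshold <- function(insert_sizes, quantile = 0.995) {
  if (length(insert_sizes) == 0)
    stop("insert_sizes must be non-empty")
  sorted <- sort(insert_sizes)
  sorted[ceiling(quantile * length(sorted))]
}

# Overlap-based exon assignment of aligned segments: any overlap >= 1 bp.
# Returns, per fragment, the transcript(s) whose two *different* exons the
# two segments hit. `reads` rows must share one sample.
.link_exons <- function(reads, genome) {
  if (!nrow(reads))
    return(data.frame(idx = integer(), transcript_id = character(),
                      exon_a = integer(), exon_b = integer(),
                      stringsAsFactors = FALSE))
  ex_gr <- .df_to_gr(genome$genes)
  g1 <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start1 + 1L, reads$end1))
  g2 <- GenomicRanges::GRanges(reads$chrom2,
                               IRanges::IRanges(reads$start2 + 1L, reads$end2))
  h1 <- GenomicRanges::findOverlaps(g1, ex_gr)
  h2 <- GenomicRanges::findOverlaps(g2, ex_gr)
  a <- data.frame(idx = S4Vectors::queryHits(h1),
                  tid = genome$genes$transcript_id[S4Vectors::subjectHits(h1)],
                  exon = genome$genes$exon[S4Vectors::subjectHits(h1)])
  b <- data.frame(idx = S4Vectors::queryHits(h2),
                  tid = genome$genes$transcript_id[S4Vectors::subjectHits(h2)],
                  exon = genome$genes$exon[S4Vectors::subjectHits(h2)])
  m <- merge(a, b, by = c("idx", "tid"), suffixes = c("_a", "_b"))
  m <- m[m$exon_a != m$exon_b, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(idx = integer(), transcript_id = character(),
                      exon_a = integer(), exon_b = integer(),
                      stringsAsFactors = FALSE))
  data.frame(idx = m$idx, transcript_id = m$tid,
             exon_a = pmin(m$exon_a, m$exon_b),
             exon_b = pmax(m$exon_a, m$exon_b), stringsAsFactors = FALSE)
}

.dedup_fragments <- function(reads) {
  key <- paste(reads$chrom, reads$start1, reads$chrom2, reads$start2,
               reads$is_split)
  reads[!duplicated(key), , drop = FALSE]
}

#' Collect per-gene discordant read-pair evidence for one sample
#'
#' Counts, for every transcript with a defined pLI, fragments whose two mates
#' overlap (>= 1 bp) two different exons of that transcript and whose insert
#' size exceeds the sample's [insert_size_threshold()]. The threshold is
#' estimated from the sample's properly paired, non-split primary fragments
#' (the aligner's proper-pair insert distribution). Duplicate fragments
#' (identical mate coordinates) are counted once; unmapped and secondary
#' records are skipped and tallied.
#'
#' @param reads A `read_pairs` data frame for one sample.
#' @param genome A [gen_toy_genome()] genome.
#' @param sample Optional sample id to subset `reads`.
#' @return A data frame (class `ppg_evidence`) with one row per transcript:
#'   `transcript_id`, `drp` count, and a `junctions` list-column tallying
#'   unordered exon-index pairs. Attributes: `skipped` (unmapped/secondary
#'   tally), `threshold`.
#' @export
collect_drp_evidence <- function(reads, genome, sample = NULL) {
  if (!is.null(sample)) reads <- reads[reads$sample == sample, , drop = FALSE]
  skipped <- sum(reads$is_unmapped | reads$is_secondary)
  reads <- reads[!reads$is_unmapped & !reads$is_secondary, , drop = FALSE]
  thr <- insert_size_threshold(
    reads$insert_size[reads$is_proper & !reads$is_split])
  cand <- .dedup_fragments(reads[!reads$is_split &
                                   reads$insert_size > thr, , drop = FALSE])
  links <- .link_exons(cand, genome)
  tids <- genome$pli$transcript_id[!is.na(genome$pli$pli)]
  links <- links[links$transcript_id %in% tids, , drop = FALSE]
  counts <- table(factor(links$transcript_id, levels = tids))
  junctions <- lapply(tids, function(t) {
    l <- links[links$transcript_id == t, , drop = FALSE]
    table(paste0(l$exon_a, "-", l$exon_b))
  })
  out <- data.frame(transcript_id = tids, drp = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$junctions <- junctions
  attr(out, "skipped") <- skipped
  attr(out, "threshold") <- thr
  class(out) <- c("ppg_evidence", "data.frame")
  out
}

#' Flag retroduplicated genes from one sample's DRP evidence
#'
#' A gene is flagged when more than `min_drp` reads link two of its exons
#' (strictly greater, i.e. >= `min_drp + 1` pairs).
#'
#' @param evidence Output of [collect_drp_evidence()].
#' @param min_drp Step-1 threshold; genes need `drp > min_drp` (default 4).
#' @return Character vector of flagged transcript ids.
#' @export
flag_retroduplicated_genes <- function(evidence, min_drp = 4L) {
  evidence$transcript_id[evidence$drp > min_drp]
}

#' Genotype one processed pseudogene across samples
#'
#' Applies the pooled junction model for one gene to every sample: a sample
#' is positive when its total supporting evidence (DRP + SRP) is at least
#' `min_support` with at least one SRP and at least one DRP.
#'
#' @param model List with `transcript_id` and `junctions` (character vector
#'   of pooled `"i-j"` exon junction keys), as built by [call_ppgs()].
#' @param reads Cohort `read_pairs` data frame (all samples).
#' @param genome A [gen_toy_genome()] genome.
#' @param samples Character vector of samples to type (default: all in
#'   `reads`).
#' @param min_support Minimum total fragments (default 5).
#' @return Data frame, one row per sample: `sample`, `transcript_id`, `drp`,
#'   `srp`, `positive`.
#' @export
genotype_ppg <- function(model, reads, genome, samples = unique(reads$sample),
                         min_support = 5L) {
  res <- lapply(samples, function(s) {
    rs <- reads[reads$sample == s & !reads$is_unmapped & !reads$is_secondary,
                , drop = FALSE]
    drp <- srp <- 0L
    if (nrow(rs)) {
      proper <- rs$insert_size[rs$is_proper & !rs$is_split]
      thr <- if (length(proper)) insert_size_threshold(proper) else Inf
      dr <- .dedup_fragments(rs[!rs$is_split & rs$insert_size > thr, ,
                                drop = FALSE])
      dl <- .link_exons(dr, genome)
      dl <- dl[dl$transcript_id == model$transcript_id, , drop = FALSE]
      drp <- nrow(dl)
      sp <- .dedup_fragments(rs[rs$is_split, , drop = FALSE])
      sl <- .link_exons(sp, genome)
      sl <- sl[sl$transcript_id == model$transcript_id, , drop = FALSE]
      srp <- nrow(sl)
    }
    data.frame(sample = s, transcript_id = model$transcript_id,
               drp = drp, srp = srp,
               positive = (drp + srp) >= min_support & srp >= 1L & drp >= 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full two-step processed pseudogene pipeline on a cohort
#'
#' Step 1 flags candidate retroduplicated genes per sample; all evidence from
#' step-1-positive samples is pooled into a per-gene junction model; step 2
#' genotypes every sample against every model.
#'
#' @inheritParams genotype_ppg
#' @param min_drp Step-1 threshold (strictly greater than; default 4).
#' @return A list of class `ppg_call_table`: `calls` (logical matrix
#'   transcript x sample), `evidence` (long data frame from
#'   [genotype_ppg()]), `step1` (per-sample flags).
#' @export
call_ppgs <- function(reads, genome, min_drp = 4L, min_support = 5L) {
  samples <- unique(reads$sample)
  step1 <- lapply(samples, function(s)
    flag_retroduplicated_genes(collect_drp_evidence(reads, genome, s),
                               min_drp))
  names(step1) <- samples
  genes <- unique(unlist(step1))
  evidence <- list()
  for (g in genes) {
    pos_samples <- samples[vapply(step1, function(x) g %in% x, logical(1))]
    pooled <- unlist(lapply(pos_samples, function(s) {
      ev <- collect_drp_evidence(reads, genome, s)
      names(ev$junctions[[match(g, ev$transcript_id)]])
    }))
    model <- list(transcript_id = g, junctions = unique(pooled))
    evidence[[g]] <- genotype_ppg(model, reads, genome, samples, min_support)
  }
  evid <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(sample = character(), transcript_id = character(),
               drp = integer(), srp = integer(), positive = logical(),
               stringsAsFactors = FALSE)
  rownames(evid) <- NULL
  calls <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
                  dimnames = list(genes, samples))
  if (nrow(evid))
    calls[cbind(evid$transcript_id, evid$sample)] <- evid$positive
  structure(list(calls = calls, evidence = evid, step1 = step1),
            class = "ppg_call_table")
}

#' @export
print.ppg_call_table <- function(x, ...) {
  cat("ppg_call_table:", nrow(x$calls), "gene(s) x", ncol(x$calls),
      "sample(s);", sum(x$calls), "positive call(s)\n")
  invisible(x)
}
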