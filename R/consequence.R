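# Single-consequence annotation of insertion points against a toy genome.
# Priority: enhancer > exonic > intronic > intergenic; exactly one
# consequence per position, with containing gene and pLI attached for genic
# hits.

#' Annotate insertion positions with a single consequence
#'
#' Assigns each position exactly one consequence with enhancer annotation
#' taking priority over gene-based annotation, then exonic over intronic.
#' Genic hits carry the containing transcript and its pLI.
#'
#' @param genome A [gen_toy_genome()] genome (or any list with `chrom_len`,
#'   `genes`, `enhancers`, `pli` in the same layout).
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based insertion positions.
#' @return Data frame with `chrom`, `pos`, `consequence` (one of
#'   `"enhancer"`, `"exonic"`, `"intronic"`, `"intergenic"`), `gene`
#'   (transcript id or `NA`) and `pli` (`NA` outside genes).
#' @export
annotate_consequence <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  bad <- !(chrom %in% names(genome$chrom_len)) |
    pos < 0 | pos >= genome$chrom_len[chrom]
  if (any(bad))
    stop("position off-chromosome: ", chrom[which(bad)[1]], ":",
         pos[which(bad)[1]])
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = pos,
                    consequence = rep("intergenic", n),
                    gene = rep(NA_character_, n), pli = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  qry <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))

  if (nrow(genome$genes)) {
    spans <- gene_spans(genome)
    hit_gene <- GenomicRanges::findOverlaps(qry, .df_to_gr(spans),
                                            select = "first")
    in_gene <- !is.na(hit_gene)
    out$consequence[in_gene] <- "intronic"
    out$gene[in_gene] <- spans$transcript_id[hit_gene[in_gene]]
    hit_ex <- GenomicRanges::findOverlaps(qry, .df_to_gr(genome$genes),
                                          select = "first")
    in_ex <- !is.na(hit_ex)
    out$consequence[in_ex] <- "exonic"
    out$gene[in_ex] <- genome$genes$transcript_id[hit_ex[in_ex]]
    out$pli <- genome$pli$pli[match(out$gene, genome$pli$transcript_id)]
  }
  if (nrow(genome$enhancers)) {
    hit_enh <- GenomicRanges::findOverlaps(qry, .df_to_gr(genome$enhancers),
                                           select = "first")
    in_enh <- !is.na(hit_enh)
    # enhancer priority: overrides any gene-based consequence
    out$consequence[in_enh] <- "enhancer"
    out$gene[in_enh] <- NA_character_
    out$pli[in_enh] <- NA_real_
  }
  out
}
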