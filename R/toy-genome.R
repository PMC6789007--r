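# Toy genome generator: a small annotated genome (genes with ordered exons,
# enhancers, intergenic space) on which every downstream stage can run.
# All coordinates are 0-based half-open internally.

#' Generate a toy annotated genome
#'
#' Builds a small genome with non-overlapping multi-exon gene models,
#' enhancer intervals placed in intergenic space, and (optionally) a random
#' reference sequence. Every gene carries a pLI score so that the processed
#' pseudogene caller and constraint statistics have the annotation they
#' expect. The partition exon/intron/enhancer/intergenic covers the genome
#' exactly once.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_genes Total number of genes to place (spread across chromosomes).
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @param n_enhancers Number of enhancer intervals (default: half the gene
#'   count); enhancers never overlap genes.
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges the
#'   per-gene structure is drawn from.
#' @param with_sequence If `TRUE`, attach a random reference sequence
#'   (a [Biostrings::DNAStringSet]) for low-complexity window scans.
#' @param max_tries Bounded number of placement retries per feature before an
#'   explicit error is raised.
#'
#' @return An object of class `toy_genome`: a list with `chrom_len` (named
#'   vector), `genes` (one row per exon: `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon`), `pli` (per-transcript pLI), `enhancers`,
#'   optional `seq`, and the compartment bp tally in `compartments`.
#' @export
#' @examples
#' g <- gen_toy_genome(1, 1e6, 10, seed = 1)
#' sum(g$compartments)  # == 1e6
gen_toy_genome <- function(n_chrom, chrom_len, n_genes, seed,
                           n_enhancers = max(0L, round(n_genes / 2)),
                           exon_count_range = c(3L, 8L),
                           exon_len_range = c(150L, 400L),
                           intron_len_range = c(500L, 3000L),
                           with_sequence = FALSE,
                           max_tries = 200L) {
  stopifnot(n_chrom >= 1, chrom_len > 0, n_genes >= 0)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_len <- setNames(rep(as.integer(chrom_len), n_chrom), chroms)

  exon_rows <- list()
  occupied <- vector("list", n_chrom)
  names(occupied) <- chroms
  for (g in seq_len(n_genes)) {
    tid <- sprintf("GENE%03d", g)
    n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1L)
    ex_len <- sample(exon_len_range[1]:exon_len_range[2], n_ex, replace = TRUE)
    in_len <- if (n_ex > 1)
      sample(intron_len_range[1]:intron_len_range[2], n_ex - 1L, replace = TRUE)
    else integer(0)
    span <- sum(ex_len) + sum(in_len)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1L)
      if (span >= chrom_len[chrom]) next
      start <- sample.int(chrom_len[chrom] - span, 1L) - 1L
      cand <- c(start, start + span)
      clash <- any(vapply(occupied[[chrom]], function(iv)
        cand[1] < iv[2] && iv[1] < cand[2], logical(1)))
      if (!clash) {
        occupied[[chrom]] <- c(occupied[[chrom]], list(cand))
        starts <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
        exon_rows[[g]] <- data.frame(
          transcript_id = tid, chrom = chrom,
          strand = sample(c("+", "-"), 1L),
          start = starts, end = starts + ex_len,
          exon = seq_len(n_ex), stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("failed to place gene ", tid, " after ", max_tries, " tries; ",
           "increase chrom_len or reduce n_genes")
  }
  genes <- if (length(exon_rows)) do.call(rbind, exon_rows) else
    data.frame(transcript_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               exon = integer(), stringsAsFactors = FALSE)

  # pLI mixture: a LoF-intolerant tail plus a tolerant bulk
  tids <- unique(genes$transcript_id)
  pli <- data.frame(
    transcript_id = tids,
    pli = ifelse(runif(length(tids)) < 0.3,
                 runif(length(tids), 0.9, 1), runif(length(tids), 0, 0.9)),
    stringsAsFactors = FALSE
  )

  enh_rows <- list()
  for (e in seq_len(n_enhancers)) {
    len <- sample(200:800, 1L)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1L)
      start <- sample.int(chrom_len[chrom] - len, 1L) - 1L
      cand <- c(start, start + len)
      clash <- any(vapply(occupied[[chrom]], function(iv)
        cand[1] < iv[2] && iv[1] < cand[2], logical(1)))
      if (!clash) {
        occupied[[chrom]] <- c(occupied[[chrom]], list(cand))
        enh_rows[[e]] <- data.frame(chrom = chrom, start = start,
                                    end = start + len,
                                    stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("failed to place enhancer after ", max_tries, " tries")
  }
  enhancers <- if (length(enh_rows)) do.call(rbind, enh_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  genome <- structure(
    list(chrom_len = chrom_len, genes = genes, pli = pli,
         enhancers = enhancers, seq = NULL),
    class = "toy_genome"
  )
  if (with_sequence) {
    seqs <- lapply(chrom_len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
    genome$seq <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome$seq) <- chroms
  }
  genome$compartments <- compartment_bp(genome)
  genome
}

#' Compartment sizes of a toy genome
#'
#' Tallies exonic, intronic, enhancer, and intergenic territory in bp.
#' The four compartments partition the genome (enhancers are placed outside
#' genes by the generator).
#'
#' @param genome A `toy_genome`.
#' @return Named numeric vector (`exonic`, `intronic`, `enhancer`,
#'   `intergenic`) summing to the total genome length.
#' @export
compartment_bp <- function(genome) {
  total <- sum(genome$chrom_len)
  exon_bp <- if (nrow(genome$genes))
    sum(GenomicRanges::width(GenomicRanges::reduce(.df_to_gr(genome$genes))))
  else 0
  gene_bp <- if (nrow(genome$genes)) {
    spans <- gene_spans(genome)
    sum(GenomicRanges::width(GenomicRanges::reduce(.df_to_gr(spans))))
  } else 0
  enh_bp <- if (nrow(genome$enhancers))
    sum(GenomicRanges::width(GenomicRanges::reduce(.df_to_gr(genome$enhancers))))
  else 0
  c(exonic = exon_bp, intronic = gene_bp - exon_bp, enhancer = enh_bp,
    intergenic = total - gene_bp - enh_bp)
}

#' Per-transcript gene spans (first exon start to last exon end)
#' @param genome A `toy_genome`.
#' @return Data frame with `transcript_id`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_spans <- function(genome) {
  g <- genome$genes
  if (!nrow(g))
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  sp <- do.call(rbind, lapply(split(g, g$transcript_id), function(d)
    data.frame(transcript_id = d$transcript_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chrom_len), "chromosome(s),",
      sum(x$chrom_len), "bp total\n")
  cat("  genes:", length(unique(x$genes$transcript_id)),
      " exons:", nrow(x$genes),
      " enhancers:", nrow(x$enhancers), "\n")
  fr <- x$compartments / sum(x$chrom_len)
  cat(sprintf("  compartments: exonic %.3f intronic %.3f enhancer %.3f intergenic %.3f\n",
              fr["exonic"], fr["intronic"], fr["enhancer"], fr["intergenic"]))
  invisible(x)
}
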