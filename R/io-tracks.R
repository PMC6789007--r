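# BED / FASTA / SAM / TSV interchange. BED is 0-based half-open on disk
# (matching the internal convention); SAM and VCF are 1-based on disk.

#' Write gene models as exon-per-row BED
#'
#' Columns: chrom, start, end, name (transcript id), score (exon index),
#' strand.
#'
#' @param genome A [gen_toy_genome()] genome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  gr$name <- g$transcript_id
  gr$score <- g$exon
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read exon-per-row BED gene models
#'
#' @param path BED path written by [write_genes_bed()].
#' @return Data frame in the `toy_genome$genes` layout.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    transcript_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    exon = as.integer(gr$score),
    stringsAsFactors = FALSE
  )
  out[order(out$transcript_id, out$exon), ]
}

#' Write plain intervals (enhancers, masks) as BED3
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  rtracklayer::export(.df_to_gr(intervals), path, format = "BED")
  invisible(path)
}

#' Read BED3 intervals
#' @param path BED path.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_intervals_bed <- function(path) {
  .gr_to_df(rtracklayer::import(path, format = "BED"))
}

#' Write the toy reference as FASTA
#' @param genome A genome with a `seq` [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(genome, path) {
  if (is.null(genome$seq))
    stop("genome has no sequence; use gen_toy_genome(with_sequence = TRUE)")
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) Biostrings::readDNAStringSet(path)

# SAM FLAG bits used below
.FLAG_PAIRED <- 1L
.FLAG_PROPER <- 2L
.FLAG_UNMAPPED <- 4L
.FLAG_MREVERSE <- 32L
.FLAG_FIRST <- 64L
.FLAG_LAST <- 128L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

#' Write a read-pair table as SAM
#'
#' Each fragment becomes two alignment lines (mates, or primary plus
#' supplementary segment for split reads). The sample id is carried in the
#' `RG:Z:` tag, coordinates become 1-based, and SEQ/QUAL are omitted (`*`)
#' since downstream evidence rules use coordinates and flags only.
#'
#' @param reads A `read_pairs` data frame.
#' @param genome A genome supplying `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chrom_len),
                   as.integer(genome$chrom_len)),
           paste0("@RG\tID:", unique(reads$sample), "\tSM:",
                  unique(reads$sample)))
  lines <- character(0)
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    len1 <- r$end1 - r$start1
    len2 <- r$end2 - r$start2
    if (r$is_split) {
      f1 <- .FLAG_PAIRED + .FLAG_FIRST
      f2 <- .FLAG_PAIRED + .FLAG_FIRST + .FLAG_SUPPLEMENTARY
    } else {
      f1 <- .FLAG_PAIRED + .FLAG_FIRST + (if (r$is_proper) .FLAG_PROPER else 0L) +
        .FLAG_MREVERSE
      f2 <- .FLAG_PAIRED + .FLAG_LAST + (if (r$is_proper) .FLAG_PROPER else 0L)
    }
    if (r$is_secondary) {
      f1 <- f1 + .FLAG_SECONDARY
      f2 <- f2 + .FLAG_SECONDARY
    }
    if (r$is_unmapped) {
      f1 <- f1 + .FLAG_UNMAPPED
      f2 <- f2 + .FLAG_UNMAPPED
    }
    rg <- paste0("RG:Z:", r$sample)
    lines <- c(lines,
      paste(r$read_id, f1, r$chrom, r$start1 + 1L, 60,
            paste0(len1, "M"), "=", r$start2 + 1L, r$insert_size, "*", "*",
            rg, sep = "\t"),
      paste(r$read_id, f2, r$chrom2, r$start2 + 1L, 60,
            paste0(len2, "M"), "=", r$start1 + 1L, -r$insert_size, "*", "*",
            rg, sep = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file back into a read-pair table
#'
#' Minimal text-SAM reader for the mandatory columns this package writes
#' (coordinates, FLAG bits, TLEN, RG tag); pairs are reconstructed by read
#' name.
#'
#' @param path SAM path.
#' @return A `read_pairs` data frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    out <- data.frame(sample = character(), read_id = character(),
                      chrom = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      insert_size = integer(), is_split = logical(),
                      is_proper = logical(), is_secondary = logical(),
                      is_unmapped = logical(), stringsAsFactors = FALSE)
    class(out) <- c("read_pairs", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11)
  if (length(bad))
    stop("malformed SAM record at line ", bad[1] + sum(startsWith(readLines(path), "@")))
  qname <- vapply(fields, `[[`, "", 1)
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  rname <- vapply(fields, `[[`, "", 3)
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  cigar <- vapply(fields, `[[`, "", 6)
  tlen <- as.integer(vapply(fields, `[[`, "", 9))
  rg <- vapply(fields, function(f) {
    tag <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
    if (length(tag)) sub("^RG:Z:", "", tag[1]) else NA_character_
  }, character(1))
  mlen <- as.integer(sub("M$", "", cigar))
  first <- bitwAnd(flag, .FLAG_LAST) == 0 &
    bitwAnd(flag, .FLAG_SUPPLEMENTARY) == 0
  rows <- lapply(unique(qname), function(q) {
    idx <- which(qname == q)
    i1 <- idx[first[idx]][1]
    i2 <- setdiff(idx, i1)[1]
    data.frame(sample = rg[i1], read_id = q,
               chrom = rname[i1], start1 = pos[i1] - 1L,
               end1 = pos[i1] - 1L + mlen[i1],
               chrom2 = rname[i2], start2 = pos[i2] - 1L,
               end2 = pos[i2] - 1L + mlen[i2],
               insert_size = abs(tlen[i1]),
               is_split = bitwAnd(flag[i2], .FLAG_SUPPLEMENTARY) > 0,
               is_proper = bitwAnd(flag[i1], .FLAG_PROPER) > 0,
               is_secondary = bitwAnd(flag[i1], .FLAG_SECONDARY) > 0,
               is_unmapped = bitwAnd(flag[i1], .FLAG_UNMAPPED) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Write a pedigree table (proband, father, mother) as TSV
#' @param pedigree Data frame with `proband`, `father`, `mother`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV
#' @param path TSV with `proband`, `father`, `mother` columns.
#' @return Data frame.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("proband", "father", "mother")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  ped
}
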