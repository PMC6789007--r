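# Paired-end read-set generator for the processed pseudogene caller.
# Reads are abstract alignment records (one row per fragment) convertible to
# SAM; evidence rules use coordinates and flags only, so no bases or
# qualities are simulated.

#' Simulate a read set containing a retroduplication signal
#'
#' Emits `n_background` concordant (properly paired) fragments scattered over
#' the genome, `n_drp` discordant read pairs whose mates map in two different
#' exons of the donor transcript with apparent insert size far beyond the
#' background insert distribution, and `n_srp` split reads spanning an
#' exon-exon junction of the donor (the two aligned segments abut the
#' junction). This is the evidence structure a processed pseudogene leaves in
#' exome data: the daughter copy cross-hybridises with the baits of its donor
#' gene, so junction-spanning fragments pile up on the donor's exons.
#'
#' @param genome A [gen_toy_genome()] genome.
#' @param donor_gene Transcript id of the retroduplicated gene (needs >= 2
#'   exons).
#' @param n_drp,n_srp,n_background Fragment counts per evidence class.
#' @param insert_mean,insert_sd Background insert-size distribution (bp).
#' @param read_len Aligned length per mate (bp).
#' @param sample_id Sample name stamped on every record.
#' @param seed Integer seed.
#' @return A `read_pairs` data frame, one row per fragment: `sample`,
#'   `read_id`, `chrom`, `start1`, `end1`, `chrom2`, `start2`, `end2`
#'   (0-based half-open per mate), `insert_size`, `is_split`, `is_proper`,
#'   `is_secondary`, `is_unmapped`.
#' @export
gen_ppg_readset <- function(genome, donor_gene, n_drp, n_srp, n_background,
                            insert_mean = 300, insert_sd = 30,
                            read_len = 100L, sample_id = "S1", seed = 1L) {
  set.seed(seed)
  ex <- genome$genes[genome$genes$transcript_id == donor_gene, , drop = FALSE]
  if (nrow(ex) < 2)
    stop("donor gene ", donor_gene, " has fewer than 2 exons")
  ex <- ex[order(ex$exon), ]
  chroms <- names(genome$chrom_len)

  rows <- list()
  mk <- function(id, chrom, s1, chrom2, s2, isize, split, proper) {
    data.frame(sample = sample_id, read_id = id,
               chrom = chrom, start1 = s1, end1 = s1 + read_len,
               chrom2 = chrom2, start2 = s2, end2 = s2 + read_len,
               insert_size = isize, is_split = split, is_proper = proper,
               is_secondary = FALSE, is_unmapped = FALSE,
               stringsAsFactors = FALSE)
  }

  if (n_background > 0) {
    bchrom <- sample(chroms, n_background, replace = TRUE)
    isize <- pmax(2L * read_len,
                  as.integer(round(rnorm(n_background, insert_mean, insert_sd))))
    s1 <- vapply(seq_len(n_background), function(i)
      sample.int(genome$chrom_len[bchrom[i]] - isize[i], 1L) - 1L, integer(1))
    for (i in seq_len(n_background))
      rows[[length(rows) + 1L]] <- mk(
        sprintf("%s_bg%05d", sample_id, i), bchrom[i], s1[i], bchrom[i],
        s1[i] + isize[i] - read_len, isize[i], FALSE, TRUE)
  }

  pick_in_exon <- function(row) {
    lo <- ex$start[row]
    hi <- ex$end[row] - read_len
    if (hi <= lo) lo else lo + sample.int(hi - lo, 1L)
  }
  if (n_drp > 0) {
    for (i in seq_len(n_drp)) {
      pair <- sort(sample.int(nrow(ex), 2L))
      s1 <- pick_in_exon(pair[1])
      s2 <- pick_in_exon(pair[2])
      isize <- abs(s2 + read_len - s1)
      rows[[length(rows) + 1L]] <- mk(
        sprintf("%s_drp%03d", sample_id, i), ex$chrom[1], s1, ex$chrom[1],
        s2, isize, FALSE, FALSE)
    }
  }
  if (n_srp > 0) {
    for (i in seq_len(n_srp)) {
      j <- sample.int(nrow(ex) - 1L, 1L)  # junction between exon j and j+1
      half <- max(20L, read_len %/% 2L)
      s1 <- ex$end[j] - half
      s2 <- ex$start[j + 1L]
      rows[[length(rows) + 1L]] <- mk(
        sprintf("%s_srp%03d", sample_id, i), ex$chrom[1], s1, ex$chrom[1],
        s2, ex$start[j + 1L] + half - s1, TRUE, FALSE)
      # split-read segments are `half` bp each
      rows[[length(rows)]]$end1 <- s1 + half
      rows[[length(rows)]]$end2 <- s2 + half
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else mk(character(0),
    character(0), integer(0), character(0), integer(0), integer(0),
    logical(0), logical(0))[0, ]
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Merge several read sets into one cohort-level table
#' @param ... `read_pairs` data frames (e.g. one per sample).
#' @return A single `read_pairs` data frame.
#' @export
bind_readsets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}
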