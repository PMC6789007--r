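# Accessibility masks: interval sets defining the genomic territory in
# which variant discovery is considered reliable. Interval algebra is done
# with GenomicRanges; intervals are stored merged and 0-based half-open.

#' Construct a mask set from intervals
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open); overlapping or adjacent intervals are merged.
#' @param classes ME classes this mask applies to (informational).
#' @return Object of class `mask_set`: `intervals`, total accessible length
#'   `L` (bp), `classes`.
#' @export
mask_set <- function(intervals, classes = c("Alu", "L1", "SVA")) {
  gr <- GenomicRanges::reduce(.df_to_gr(intervals))
  iv <- .gr_to_df(gr)
  structure(list(intervals = iv, L = sum(iv$end - iv$start),
                 classes = classes), class = "mask_set")
}

#' Build an accessibility mask from a coverage track
#'
#' Retains intervals whose mean coverage is at least `threshold` and merges
#' adjacent runs. The coverage track is a set of intervals with a mean
#' coverage value, e.g. fixed-width bins of cohort-mean depth.
#'
#' @param coverage_track Data frame: `chrom`, `start`, `end`, `coverage`.
#' @param threshold Minimum mean coverage (default 10).
#' @param classes ME classes the mask applies to.
#' @return A [mask_set()].
#' @export
build_mask <- function(coverage_track, threshold = 10,
                       classes = c("Alu", "L1", "SVA")) {
  keep <- coverage_track[coverage_track$coverage >= threshold, , drop = FALSE]
  if (!nrow(keep))
    return(structure(list(intervals = data.frame(chrom = character(),
                                                 start = integer(),
                                                 end = integer()),
                          L = 0, classes = classes), class = "mask_set"))
  mask_set(keep[, c("chrom", "start", "end")], classes)
}

#' Combine masks by interval algebra
#'
#' @param masks List of [mask_set()] objects (the first is the base; for
#'   `"subtract"`, the remaining masks are removed from it).
#' @param mode `"intersect"`, `"subtract"`, or `"union"`.
#' @return A [mask_set()] with `L` recomputed.
#' @export
combine_masks <- function(masks, mode = c("intersect", "subtract", "union")) {
  if (is.character(mode) && !mode[1] %in% c("intersect", "subtract", "union"))
    stop("unknown mode: ", mode[1])
  mode <- match.arg(mode)
  grs <- lapply(masks, function(m) GenomicRanges::reduce(.df_to_gr(m$intervals)))
  acc <- grs[[1]]
  for (g in grs[-1]) {
    acc <- switch(mode,
                  intersect = GenomicRanges::intersect(acc, g),
                  subtract = GenomicRanges::setdiff(acc, g),
                  union = GenomicRanges::reduce(GenomicRanges::union(acc, g)))
  }
  mask_set(.gr_to_df(acc),
           classes = unique(unlist(lapply(masks, `[[`, "classes"))))
}

#' Number of intervals in a mask
#' @param mask A `mask_set`.
#' @return Integer interval count.
#' @export
mask_n_intervals <- function(mask) nrow(mask$intervals)

#' @export
print.mask_set <- function(x, ...) {
  cat("mask_set:", nrow(x$intervals), "interval(s), L =", x$L, "bp;",
      "classes:", paste(x$classes, collapse = ","), "\n")
  invisible(x)
}
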