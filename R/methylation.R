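# Case/control CpG methylation signature: differential CpG discovery on a
# training subset and correlation-based classification of held-out samples.

# Vectorised Welch two-sample t-test over matrix rows (case vs control
# columns); returns two-sided p-values. Cross-checked against stats::t.test
# in the test suite.
.row_welch_p <- function(mat, case_cols, control_cols) {
  n1 <- length(case_cols)
  n2 <- length(control_cols)
  m1 <- rowMeans(mat[, case_cols, drop = FALSE])
  m2 <- rowMeans(mat[, control_cols, drop = FALSE])
  v1 <- apply(mat[, case_cols, drop = FALSE], 1, var)
  v2 <- apply(mat[, control_cols, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows (zero variance in both groups): no evidence either way
  p[!is.finite(tstat)] <- 1
  list(p = p, delta = m1 - m2, mean_case = m1, mean_control = m2)
}

#' Build a differential methylation signature from a training subset
#'
#' Randomly samples `n_case` cases and `n_control` controls, tests each CpG
#' for a group difference in mean beta (Welch t-test), adjusts p-values by
#' Benjamini-Hochberg, and retains CpGs with `|delta beta| >= effect_cutoff`
#' and adjusted `p <= fdr`.
#'
#' @param beta Beta-value matrix (CpG x sample).
#' @param labels Named character vector over samples (`"case"`/`"control"`).
#' @param n_case,n_control Training subset sizes (defaults 15 and 15).
#' @param effect_cutoff Minimum absolute group difference in beta
#'   (default 0.20).
#' @param fdr FDR-adjusted p-value cutoff (default 0.01).
#' @param seed Integer seed for the training-subset draw.
#' @return An object of class `methyl_signature`: data frame (`cpg`,
#'   `mean_case`, `mean_control`, `delta`, `p`, `padj`) of signature CpGs,
#'   with the training sample ids in `attr(, "training")`.
#' @export
build_signature <- function(beta, labels, n_case = 15L, n_control = 15L,
                            effect_cutoff = 0.20, fdr = 0.01, seed = 1L) {
  cases <- names(labels)[labels == "case"]
  controls <- names(labels)[labels == "control"]
  if (length(cases) < n_case || length(controls) < n_control)
    stop("fewer samples than requested: need ", n_case, " cases and ",
         n_control, " controls")
  set.seed(seed)
  tr_case <- sample(cases, n_case)
  tr_ctrl <- sample(controls, n_control)
  w <- .row_welch_p(beta, tr_case, tr_ctrl)
  padj <- p.adjust(w$p, method = "BH")
  keep <- abs(w$delta) >= effect_cutoff & padj <= fdr
  keep[is.na(keep)] <- FALSE
  sig <- data.frame(cpg = rownames(beta)[keep], mean_case = w$mean_case[keep],
                    mean_control = w$mean_control[keep],
                    delta = w$delta[keep], p = w$p[keep], padj = padj[keep],
                    stringsAsFactors = FALSE)
  rownames(sig) <- NULL
  structure(sig, class = c("methyl_signature", "data.frame"),
            training = c(tr_case, tr_ctrl),
            effect_cutoff = effect_cutoff, fdr = fdr)
}

#' Classify a sample against a methylation signature by correlation
#'
#' Computes the Pearson correlation of the query's beta values at signature
#' CpGs against the mean case and mean control profiles; the label is the
#' profile with the larger correlation (`"uncertain"` on an exact tie).
#'
#' @param query Named beta vector (or matrix CpG x sample for several
#'   queries); must cover at least `min_coverage` of the signature CpGs.
#' @param signature A [build_signature()] result (must be non-empty).
#' @param min_coverage Required fraction of signature CpGs present in the
#'   query (default 0.9).
#' @return Data frame with one row per query sample: `sample`, `r_case`,
#'   `r_control`, `label`.
#' @export
classify_by_correlation <- function(query, signature, min_coverage = 0.9) {
  if (nrow(signature) == 0)
    stop("signature is empty")
  if (is.null(dim(query)))
    query <- matrix(query, ncol = 1,
                    dimnames = list(names(query), "query"))
  covered <- intersect(signature$cpg, rownames(query))
  if (length(covered) < min_coverage * nrow(signature))
    stop("query covers only ", length(covered), "/", nrow(signature),
         " signature CpGs (minimum ", min_coverage, ")")
  idx <- match(covered, signature$cpg)
  case_prof <- signature$mean_case[idx]
  ctrl_prof <- signature$mean_control[idx]
  res <- lapply(colnames(query), function(s) {
    q <- query[covered, s]
    r_case <- cor(q, case_prof)
    r_ctrl <- cor(q, ctrl_prof)
    label <- if (isTRUE(all.equal(r_case, r_ctrl))) "uncertain"
    else if (r_case > r_ctrl) "case" else "control"
    data.frame(sample = s, r_case = r_case, r_control = r_ctrl,
               label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
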