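# Methylation beta-value matrix generator with planted differential CpGs.

#' Simulate a case/control beta-value matrix with a planted episignature
#'
#' Baseline per-CpG methylation is drawn uniformly, cases are shifted by
#' `effect` (random direction, clipped into `[0, 1]`) at `n_signature`
#' planted CpGs, and i.i.d. Gaussian noise is added to every entry before
#' clipping. Non-signature CpGs are exchangeable between groups.
#'
#' @param n_cpg Total number of CpGs.
#' @param n_case,n_control Sample counts per group.
#' @param n_signature Number of planted differential CpGs
#'   (`<= n_cpg`).
#' @param effect Group difference in beta at signature CpGs (`0 <= effect
#'   <= 1`).
#' @param noise_sd Per-entry Gaussian noise SD (beta units).
#' @param seed Integer seed.
#' @return List: `beta` (matrix CpG x sample), `labels` (named character,
#'   `"case"`/`"control"`), `signature` (planted CpG ids), `delta` (signed
#'   planted effect per signature CpG).
#' @export
gen_beta_matrix <- function(n_cpg, n_case, n_control, n_signature,
                            effect = 0.3, noise_sd = 0.05, seed = 1L) {
  stopifnot(effect >= 0, effect <= 1)
  if (n_signature > n_cpg)
    stop("n_signature must not exceed n_cpg")
  set.seed(seed)
  cpgs <- sprintf("cg%07d", seq_len(n_cpg))
  samples <- c(sprintf("case%03d", seq_len(n_case)),
               sprintf("ctrl%03d", seq_len(n_control)))
  labels <- setNames(rep(c("case", "control"), c(n_case, n_control)),
                     samples)
  base <- runif(n_cpg, 0.2, 0.8)
  sig_idx <- sort(sample.int(n_cpg, n_signature))
  # shift direction chosen so the shifted mean stays in [0, 1] and the
  # planted group difference is exactly `effect`
  dir <- sample(c(-1, 1), n_signature, replace = TRUE)
  up_ok <- base[sig_idx] + effect <= 1
  dn_ok <- base[sig_idx] - effect >= 0
  dir[dir > 0 & !up_ok] <- -1
  dir[dir < 0 & !dn_ok] <- 1
  delta <- dir * effect
  mean_mat <- matrix(base, n_cpg, n_case + n_control)
  if (n_signature)
    mean_mat[sig_idx, seq_len(n_case)] <- base[sig_idx] + delta
  beta <- mean_mat + matrix(rnorm(length(mean_mat), 0, noise_sd),
                            nrow = n_cpg)
  beta <- pmax(pmin(beta, 1), 0)
  dimnames(beta) <- list(cpgs, samples)
  list(beta = beta, labels = labels, signature = cpgs[sig_idx],
       delta = setNames(delta, cpgs[sig_idx]))
}
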