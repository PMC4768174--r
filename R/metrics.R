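#' Relative Frobenius inference error
#'
#' `rho = ||S_hat - S0||_F / ||S0||_F`: 0 for exact recovery, 1 when the
#' estimate is identically zero (or twice the truth).
#'
#' @param S_hat estimated matrix.
#' @param S0 ground-truth matrix (must be nonzero).
#' @return nonnegative scalar.
#' @export
inference_error <- function(S_hat, S0) {
  stopifnot(identical(dim(S_hat), dim(S0)))
  denom <- frobenius(S0)
  if (denom == 0) stop("S0 is all-zero: inference error undefined",
                       call. = FALSE)
  frobenius(S_hat - S0) / denom
}

#' Absence-detection error
#'
#' Fraction of truly absent arcs (off-diagonal zero entries of `S0`) whose
#' estimated magnitude exceeds `tau` — a Heaviside count of false presences,
#' the specificity-oriented error the sparse formulation targets. Diagonal
#' entries are excluded: self-influence is not part of the structure being
#' scored.
#'
#' @param S_hat estimated matrix.
#' @param S0 ground-truth matrix (needs at least one off-diagonal zero).
#' @param tau detection threshold.
#' @return error in `[0, 1]`.
#' @export
absence_error <- function(S_hat, S0, tau) {
  stopifnot(identical(dim(S_hat), dim(S0)), tau >= 0)
  off <- row(S0) != col(S0)
  zeros <- off & S0 == 0
  if (!any(zeros)) stop("S0 has no off-diagonal zero entries", call. = FALSE)
  mean(abs(S_hat[zeros]) > tau)
}

#' Rank-based AUROC and interpolation-free AUPR
#'
#' Standard threshold-free scores of an edge ranking against a gold standard:
#' AUROC from the Mann-Whitney rank statistic (ties averaged) and AUPR as the
#' step-wise average precision (no interpolation; tied scores processed as one
#' block).
#'
#' @param scores numeric edge scores (higher = more confident presence).
#' @param labels binary gold-standard labels, same length.
#' @return list with `auroc` and `aupr`.
#' @export
auroc_aupr <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1); Ng <- sum(labels == 0)
  if (P == 0 || Ng == 0)
    stop("gold standard must contain both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * Ng)
  # average precision over tie blocks in decreasing score order
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blocks <- cumsum(!duplicated(s))
  tp_in_block <- tapply(y, blocks, sum)
  n_in_block <- tapply(y, blocks, length)
  tp <- cumsum(tp_in_block)
  seen <- cumsum(n_in_block)
  prec <- tp / seen
  aupr <- sum(tp_in_block / P * prec)
  list(auroc = auroc, aupr = as.numeric(aupr))
}

#' Prediction score from AUROC/AUPR permutation p-values
#'
#' `xi = -(log10 p_AUROC + log10 p_AUPR) / 2`, with p-values estimated from a
#' seeded permutation null over the edge scores (labels fixed, scores
#' shuffled) and an add-one pseudocount so p never vanishes: with `n_perm`
#' permutations the score saturates at `-log10(1 / (n_perm + 1))`. This null
#' is internal to the package and not numerically comparable to challenge
#' scores computed against precomputed nulls.
#'
#' @param scores numeric edge scores.
#' @param labels binary gold-standard labels.
#' @param n_perm permutation-null size (>= 100).
#' @param seed integer seed.
#' @return scalar score, with attributes `auroc`, `aupr`, `p_auroc`, `p_aupr`.
#' @export
xi_score <- function(scores, labels, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  obs <- auroc_aupr(scores, labels)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- auroc_aupr(sample(scores), labels)
      c(perm$auroc, perm$aupr)
    }, numeric(2))
  })
  p_roc <- (1 + sum(null_stats[1, ] >= obs$auroc)) / (n_perm + 1)
  p_pr <- (1 + sum(null_stats[2, ] >= obs$aupr)) / (n_perm + 1)
  structure(-(log10(p_roc) + log10(p_pr)) / 2,
            auroc = obs$auroc, aupr = obs$aupr,
            p_auroc = p_roc, p_aupr = p_pr)
}

#' Full evaluation report of an estimate against a gold standard
#'
#' Convenience wrapper collecting the package's metrics for one estimated
#' direct-influence matrix: inference error, Hoyer sparsity, absence error
#' and the off-diagonal ranking scores.
#'
#' @param S_hat estimated matrix.
#' @param S0 ground-truth matrix.
#' @param tau absence-detection threshold.
#' @param xi compute the permutation-null prediction score (slower).
#' @param seed seed for the permutation null.
#' @return named list (`rho`, `hoyer`, `e`, `auroc`, `aupr`, optionally `xi`).
#' @export
eval_report <- function(S_hat, S0, tau = 1e-3 * max(abs(S_hat)), xi = FALSE,
                        seed = 1) {
  off <- row(S0) != col(S0)
  scores <- abs(S_hat[off])
  labels <- (S0[off] != 0) * 1
  ra <- auroc_aupr(scores, labels)
  out <- list(rho = inference_error(S_hat, S0), hoyer = hoyer(S_hat),
              e = absence_error(S_hat, S0, tau),
              auroc = ra$auroc, aupr = ra$aupr)
  if (xi) out$xi <- as.numeric(xi_score(scores, labels, seed = seed))
  out
}
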