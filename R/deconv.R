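#' Estimate a total-influence matrix from expression-like samples
#'
#' Pairwise Pearson or Spearman correlation across columns of a samples-by-
#' nodes matrix, used as a cheap surrogate measurement of the total influence
#' between nodes. The diagonal is forced to zero (self-influence is not part
#' of the measurement) and the matrix is used as-is: the l1 constraint is
#' expected to absorb the estimation error.
#'
#' @param samples numeric matrix, one row per sample, one column per node.
#' @param method `"pearson"` or `"spearman"`.
#' @return square symmetric matrix with zero diagonal; attribute
#'   `provenance` records the estimator.
#' @export
estimate_total_influence <- function(samples, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(samples, 2, sd)
  G <- suppressWarnings(cor(samples, method = method))
  if (any(sds == 0)) {
    warning("constant column(s) ", paste(which(sds == 0), collapse = ", "),
            ": correlations set to 0")
  }
  G[!is.finite(G)] <- 0
  diag(G) <- 0
  attr(G, "provenance") <- paste0("correlation-", method)
  G
}

#' Build the unified linear system relating direct and total influence
#'
#' The direct and total influence matrices satisfy `S %*% B = C`. For the
#' deconvolution mapping used here (the Feizi et al. instantiation),
#' `B = I + G` and `C = G`: if `G0` is the closure of `S0`
#' (`G0 = S0 + S0 %*% G0`) then `S0 %*% (I + G0) = G0` identically. The MRA
#' branch produces the same shape with `B = R` and `C` the derivative
#' responses (see [build_response_system()]).
#'
#' @param G square total-influence matrix.
#' @return list of class `linear_system_form` with fields `B`, `C`, `mapping`.
#' @export
build_linear_system <- function(G) {
  check_square(G, "G")
  structure(list(B = diag(nrow(G)) + G, C = G, mapping = "feizi"),
            class = "linear_system_form")
}

#' Closed-form network deconvolution
#'
#' The noise-free inverse of the total-influence closure:
#' `S = G %*% solve(I + G)`. This is the non-sparse baseline the constrained
#' l1 recovery is compared against; with noisy `G` it spreads the error over
#' all entries instead of concentrating support.
#'
#' @param G square total-influence matrix.
#' @param max_cond condition-number guard on `I + G`.
#' @return the deconvolved direct-influence matrix.
#' @export
nd_closed_form <- function(G, max_cond = 1e12) {
  check_square(G, "G")
  IG <- diag(nrow(G)) + G
  kc <- suppressWarnings(kappa(IG, exact = FALSE))
  if (!is.finite(kc) || kc > max_cond)
    stop("I + G is numerically singular (condition number > ",
         format(max_cond), ")", call. = FALSE)
  G %*% solve(IG)
}
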