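#' Average direct-influence estimates across realizations or time points
#'
#' Elementwise mean of a stack of estimates `S^(k)` computed from independent
#' noise realizations of the total-influence matrix, or from different time
#' points of a transient experiment. Under additive zero-mean estimation
#' error, entries of truly absent arcs shrink toward zero at the usual
#' `1/sqrt(N)` rate, so the averaged estimate is at least as good as a single
#' one for absence detection.
#'
#' @param estimates list of same-shaped direct-influence matrices.
#' @return the averaged matrix.
#' @export
average_estimates <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 1)
  dims <- dim(estimates[[1]])
  for (E in estimates)
    if (!identical(dim(E), dims))
      stop("all estimates must have the same shape", call. = FALSE)
  Reduce(`+`, estimates) / length(estimates)
}

#' Classify absent links from an averaged estimate
#'
#' Flags entry `(i, j)` as an absent arc when `|S_avg[i, j]| <= tau`
#' (so `tau = 0` flags exactly the exact zeros). With no
#' known noise level a threshold of `1e-3 * max(abs(S_avg))` is a serviceable
#' default: the l1 solutions contain many exact zeros, so the call set is
#' insensitive to `tau` over several decades.
#'
#' @param S_avg averaged direct-influence matrix.
#' @param tau nonnegative absolute threshold; `NULL` for the default above.
#' @return binary matrix, 1 = predicted absent.
#' @export
zero_set <- function(S_avg, tau = NULL) {
  check_square(S_avg, "S_avg")
  if (is.null(tau)) tau <- 1e-3 * max(abs(S_avg))
  stopifnot(tau >= 0)
  (abs(S_avg) <= tau) * 1
}
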