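#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the Mersenne-Twister generator seeded at `seed` and then
#' restores whatever random state existed before the call, so seeded helpers
#' never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed for sub-draws; double arithmetic (exact below
# 2^53) keeps the result below 2^31 without integer overflow.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 12289) %% 2147483587)
}

check_square <- function(M, name = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be a square matrix", call. = FALSE)
  if (!all(is.finite(M)))
    stop(name, " must have finite entries", call. = FALSE)
  invisible(M)
}

spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

row_l2 <- function(M) sqrt(rowSums(M^2))

frobenius <- function(M) sqrt(sum(M^2))
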