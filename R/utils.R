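# Internal validators and numeric helpers shared across modules.

.prob_tol <- 1e-12

#' Validate a probability vector
#'
#' Checks nonnegativity and unit sum (tolerance 1e-12) of a distribution over
#' k >= 2 discrete states.
#'
#' @param p numeric vector of probabilities.
#' @param what label used in error messages.
#' @return `p`, invisibly, after validation.
#' @export
check_prob_vector <- function(p, what = "probability vector") {
  if (!is.numeric(p) || length(p) < 2L)
    stop(what, " must be a numeric vector with k >= 2 entries", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0))
    stop(what, " has negative or non-finite entries", call. = FALSE)
  if (abs(sum(p) - 1) > .prob_tol * max(1, length(p)))
    stop(what, " does not sum to 1 (sum = ", format(sum(p), digits = 15), ")",
         call. = FALSE)
  invisible(p)
}

#' Validate a row-stochastic transition matrix
#'
#' @param kernel square numeric matrix; entry (i, j) is the probability of a
#'   one-step move from state i to state j.
#' @param what label used in error messages.
#' @return `kernel`, invisibly, after validation.
#' @export
check_transition_matrix <- function(kernel, what = "transition matrix") {
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) || nrow(kernel) < 2L)
    stop(what, " must be a square k x k matrix with k >= 2", call. = FALSE)
  if (any(!is.finite(kernel)) || any(kernel < 0))
    stop(what, " has negative or non-finite entries", call. = FALSE)
  rs <- rowSums(kernel)
  if (any(abs(rs - 1) > .prob_tol * ncol(kernel)))
    stop(what, " rows must each sum to 1 (worst residual ",
         format(max(abs(rs - 1)), digits = 3), ")", call. = FALSE)
  invisible(kernel)
}

#' Validate a joint endpoint distribution
#'
#' @param joint square numeric matrix of probabilities over (X_0, X_T).
#' @param what label used in error messages.
#' @return `joint`, invisibly, after validation.
#' @export
check_joint <- function(joint, what = "joint distribution") {
  if (!is.matrix(joint) || nrow(joint) != ncol(joint) || nrow(joint) < 2L)
    stop(what, " must be a square k x k matrix with k >= 2", call. = FALSE)
  if (any(!is.finite(joint)) || any(joint < 0))
    stop(what, " has negative or non-finite entries", call. = FALSE)
  if (abs(sum(joint) - 1) > .prob_tol * length(joint))
    stop(what, " must sum to 1 (sum = ", format(sum(joint), digits = 15), ")",
         call. = FALSE)
  invisible(joint)
}

# log(sum(exp(x))) guarding the all -Inf case.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible child seed from a master seed and a stream label.
# Small deterministic string hash; keeps results below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the kernel for eigenvalue 1, normalized to a
#' probability vector. Errors when the unit eigenvalue is not simple
#' (non-ergodic chain), since the stationary start is then ambiguous.
#'
#' @param kernel row-stochastic k x k matrix.
#' @param tol eigenvalue tolerance for detecting multiplicity.
#' @return length-k stationary probability vector.
#' @export
stationary_distribution <- function(kernel, tol = 1e-9) {
  check_transition_matrix(kernel)
  e <- eigen(t(kernel))
  unit <- which(abs(e$values - 1) < tol)
  if (length(unit) != 1L)
    stop("non_ergodic_kernel: unit eigenvalue has multiplicity ",
         length(unit), "; stationary distribution is not unique", call. = FALSE)
  v <- Re(e$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -1e-12))
    stop("non_ergodic_kernel: stationary eigenvector is not nonnegative",
         call. = FALSE)
  v[v < 0] <- 0
  v / sum(v)
}
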