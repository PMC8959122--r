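# Discrete Schrodinger Bridge endpoint problem: minimum-KL coupling between a
# prescribed initial and target state distribution, relative to the joint law
# of the baseline (uncontrolled) Markov chain at times 0 and T.

#' Joint endpoint distribution of the uncontrolled chain
#'
#' Builds Q with `Q[i, j] = pi[i] * (kernel^T)[i, j]`, the probability that the
#' baseline chain started from `pi` occupies state i at time 0 and state j at
#' time T. For horizons T > 1 the T-step kernel is the T-fold composition of
#' the one-step kernel; only the endpoints enter the bridge optimization, the
#' interior of the path being handled by [reconstruct_full_path()].
#'
#' @param pi initial distribution over the k states.
#' @param kernel k x k row-stochastic baseline transition matrix.
#' @param T integer horizon, T >= 1 (number of steps to the target time).
#' @return k x k joint matrix with `attr(, "horizon") = T`; grand sum 1.
#' @examples
#' K <- rbind(c(0.9, 0.1), c(0.2, 0.8))
#' uncontrolled_joint(c(0.5, 0.5), K, T = 1)
#' @export
uncontrolled_joint <- function(pi, kernel, T = 1L) {
  check_prob_vector(pi, "initial distribution")
  check_transition_matrix(kernel)
  if (length(pi) != nrow(kernel))
    stop("initial distribution and kernel dimensions disagree", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T != round(T))
    stop("horizon T must be a single integer >= 1", call. = FALSE)
  Q <- pi * matrix_power(kernel, as.integer(T))
  dimnames(Q) <- dimnames(kernel)
  attr(Q, "horizon") <- as.integer(T)
  Q
}

# T-fold composition of a square matrix by repeated squaring.
matrix_power <- function(A, n) {
  out <- diag(nrow(A))
  base <- A
  while (n > 0L) {
    if (n %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    n <- n %/% 2L
  }
  out
}

#' Kullback-Leibler divergence between two joint endpoint distributions
#'
#' Computes `sum(P * log(P / Q))` in nats with the convention
#' `0 * log(0 / q) = 0`. Mass of P on the zero set of Q is a hard support
#' violation and raises an error rather than returning infinity, so
#' infeasible comparisons fail loudly.
#'
#' @param P,Q same-shape nonnegative matrices (or vectors) each summing to 1.
#' @return nonnegative scalar divergence in nats.
#' @export
kl_divergence <- function(P, Q) {
  if (!identical(dim(P), dim(Q)) || length(P) != length(Q))
    stop("P and Q must have identical shape", call. = FALSE)
  bad <- which(P > 0 & Q == 0)
  if (length(bad))
    stop(errorCondition(
      paste0("support_violation: P has mass where Q is zero (first flat index ",
             bad[1L], ")"),
      class = c("sbridge_support_violation", "error", "condition")))
  pos <- P > 0
  sum(P[pos] * (log(P[pos]) - log(Q[pos])))
}

#' Entropy-regularized optimal transport identity
#'
#' The bridge objective D_KL(P || Q) equals the transport cost
#' `sum(C * P)` with `C = -log(Q)` minus the joint entropy `H(P)`, which casts
#' the problem as entropy-regularized optimal transport. Returns the three
#' quantities so the identity can be inspected numerically.
#'
#' @inheritParams kl_divergence
#' @return named numeric vector `c(kl, transport_term, entropy)` (nats);
#'   `kl == transport_term - entropy` up to roundoff.
#' @export
ot_identity_check <- function(P, Q) {
  kl <- kl_divergence(P, Q)
  pos <- P > 0
  transport <- sum(P[pos] * (-log(Q[pos])))
  entropy <- -sum(P[pos] * log(P[pos]))
  c(kl = kl, transport_term = transport, entropy = entropy)
}

#' Solve the Schrodinger Bridge endpoint problem
#'
#' Finds the coupling `P*` minimizing D_KL(P || Q) subject to row marginals
#' `pi` and column marginals `pi_target`. The optimum has the Gibbs form
#' `P*[i, j] = exp(alpha[i] + beta[j]) * Q[i, j]` and is computed by
#' alternating updates of the Lagrange multipliers alpha and beta (the
#' Sinkhorn algorithm), run in the log domain for numerical stability. The
#' normalization constant is a gauge freedom and is folded into alpha on
#' termination, so the reported multipliers reproduce `P*` exactly.
#'
#' Zeros of Q are preserved exactly in `P*`; no smoothing is applied unless
#' `smoothing > 0` is requested explicitly, in which case Q is first mixed
#' with the uniform joint as `(1 - smoothing) * Q + smoothing / k^2`.
#'
#' @param pi initial (row) marginal.
#' @param pi_target target (column) marginal.
#' @param Q baseline joint endpoint distribution, e.g. from
#'   [uncontrolled_joint()].
#' @param tol convergence tolerance: maximum absolute marginal residual.
#' @param max_iter iteration budget for the alternating updates.
#' @param smoothing optional uniform-mixing weight in `[0, 1)`; default 0.
#' @return object of class `bridge_solution`: list with `optimal_joint`,
#'   `alpha`, `beta`, `cost` (nats), `iterations`, `residual`, `converged`,
#'   plus the inputs `pi`, `pi_target`, `tol` and the horizon of Q.
#' @examples
#' K <- rbind(c(0.9, 0.1), c(0.2, 0.8))
#' Q <- uncontrolled_joint(c(0.5, 0.5), K, 1)
#' sol <- solve_bridge(c(0.5, 0.5), c(0.9, 0.1), Q)
#' sol$cost
#' @export
solve_bridge <- function(pi, pi_target, Q, tol = 1e-10, max_iter = 1e5,
                         smoothing = 0) {
  check_prob_vector(pi, "initial distribution")
  check_prob_vector(pi_target, "target distribution")
  horizon <- attr(Q, "horizon")
  Q <- structure(as.matrix(Q), horizon = NULL)
  check_joint(Q)
  k <- nrow(Q)
  if (length(pi) != k || length(pi_target) != k)
    stop("marginals and joint dimensions disagree", call. = FALSE)
  if (smoothing < 0 || smoothing >= 1)
    stop("smoothing must be in [0, 1)", call. = FALSE)
  if (smoothing > 0)
    Q <- (1 - smoothing) * Q + smoothing / (k * k)

  bad_row <- which(pi > 0 & rowSums(Q) == 0)
  if (length(bad_row))
    stop(errorCondition(
      paste0("infeasible_marginals: initial mass on state ", bad_row[1L],
             " but row ", bad_row[1L], " of Q has no support"),
      class = c("sbridge_infeasible", "error", "condition")))
  bad_col <- which(pi_target > 0 & colSums(Q) == 0)
  if (length(bad_col))
    stop(errorCondition(
      paste0("infeasible_marginals: target mass on state ", bad_col[1L],
             " but column ", bad_col[1L], " of Q has no support"),
      class = c("sbridge_infeasible", "error", "condition")))

  logQ <- suppressWarnings(log(Q))        # -Inf at structural zeros
  log_pi <- suppressWarnings(log(pi))
  log_pit <- suppressWarnings(log(pi_target))
  alpha <- numeric(k)
  beta <- numeric(k)
  alpha[pi == 0] <- -Inf

  residual <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # beta update (Lagrange multiplier for the column constraint)
    for (j in seq_len(k)) {
      beta[j] <- if (pi_target[j] == 0) -Inf else
        log_pit[j] - logsumexp(alpha + logQ[, j])
    }
    # alpha update (row constraint)
    for (i in seq_len(k)) {
      alpha[i] <- if (pi[i] == 0) -Inf else
        log_pi[i] - logsumexp(beta + logQ[i, ])
    }
    P <- exp(outer(alpha, beta, "+") + logQ)
    P[Q == 0] <- 0                         # exact zero preservation
    residual <- max(abs(rowSums(P) - pi), abs(colSums(P) - pi_target))
    if (is.nan(residual)) residual <- Inf
    if (residual <= tol || iter >= max_iter) break
  }

  if (residual > tol)
    stop(errorCondition(
      paste0("sinkhorn_not_converged: residual ", format(residual, digits = 6),
             " after ", iter, " iterations (tol ", format(tol), ");",
             " the marginals may be infeasible for the support of Q"),
      class = c("sbridge_not_converged", "error", "condition"),
      residual = residual, iterations = iter))

  # gauge fix: fold the global normalization into alpha so that
  # P* = exp(alpha_i + beta_j) * Q_ij holds with grand sum exactly 1
  s <- sum(P)
  alpha <- alpha - log(s)
  P <- P / s

  structure(list(
    optimal_joint = P,
    alpha = alpha,
    beta = beta,
    cost = kl_divergence(P, Q),
    iterations = iter,
    residual = residual,
    converged = TRUE,
    pi = pi,
    pi_target = pi_target,
    tol = tol,
    horizon = if (is.null(horizon)) NA_integer_ else horizon
  ), class = "bridge_solution")
}

#' @export
print.bridge_solution <- function(x, ...) {
  k <- length(x$pi)
  cat("Schrodinger Bridge solution (k = ", k, " states)\n", sep = "")
  cat("  transition cost: ", format(x$cost, digits = 6), " nats (",
      format(x$cost / log(2), digits = 6), " bits)\n", sep = "")
  cat("  iterations: ", x$iterations, ", marginal residual: ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Minimum KL transition cost between state distributions
#'
#' Convenience composition: build the uncontrolled endpoint joint from the
#' baseline kernel, solve the bridge, and return its cost. By the
#' decomposition of the path divergence into an endpoint term plus a
#' conditional-bridge term, this endpoint minimum equals the minimum over
#' full controlled paths.
#'
#' @inheritParams uncontrolled_joint
#' @param pi_target target distribution at time T.
#' @param units report the cost in `"nats"` (natural log, default) or
#'   `"bits"`.
#' @param ... passed to [solve_bridge()] (`tol`, `max_iter`, `smoothing`).
#' @return nonnegative scalar cost.
#' @examples
#' K <- rbind(c(0.9, 0.1), c(0.2, 0.8))
#' transition_cost(c(0.5, 0.5), c(0.9, 0.1), K, T = 1)
#' @export
transition_cost <- function(pi, pi_target, kernel, T = 1L,
                            units = c("nats", "bits"), ...) {
  units <- match.arg(units)
  sol <- solve_bridge(pi, pi_target, uncontrolled_joint(pi, kernel, T), ...)
  if (units == "bits") sol$cost / log(2) else sol$cost
}
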