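# Full controlled-path reconstruction. The bridge optimum fixes the endpoint
# coupling; the interior of the optimal path is the baseline chain conditioned
# on its endpoints, which makes the controlled path a time-inhomogeneous
# Markov chain (a Doob h-transform of the baseline kernel).

#' Reconstruct the optimally controlled path
#'
#' Expands a [solve_bridge()] endpoint solution into the full controlled path
#' p*(X_0, ..., X_T): the unique path law whose endpoint joint is `P*` and
#' whose interior, conditional on the endpoints, coincides with the baseline
#' chain's bridge. Realized as a time-inhomogeneous Markov chain via the
#' backward recursion `h_t(s) = sum_j kernel[s, j] * h_{t+1}(j)` with
#' `h_T = exp(beta)`; the step kernel from time t to t+1 is
#' `kernel[s, s'] * h_{t+1}(s') / h_t(s)`.
#'
#' @param solution a `bridge_solution` whose baseline joint was built from
#'   `kernel` with horizon `T`.
#' @param kernel the baseline one-step transition matrix.
#' @param T integer horizon; must match the solution's horizon when recorded.
#' @return object of class `path_distribution`: list with `horizon`,
#'   `initial` (marginal at t = 0) and `kernels` (list of T row-stochastic
#'   step matrices).
#' @export
reconstruct_full_path <- function(solution, kernel, T = solution$horizon) {
  stopifnot(inherits(solution, "bridge_solution"))
  check_transition_matrix(kernel)
  if (is.na(T) || T < 1)
    stop("horizon T must be a positive integer", call. = FALSE)
  T <- as.integer(T)
  if (!is.na(solution$horizon) && solution$horizon != T)
    stop("T disagrees with the horizon recorded in the solution", call. = FALSE)
  k <- nrow(kernel)
  if (length(solution$pi) != k)
    stop("kernel dimension disagrees with the solution", call. = FALSE)

  KT <- matrix_power(kernel, T)
  if (any(solution$optimal_joint > 0 & KT == 0))
    stop(errorCondition(
      "infeasible_endpoint: optimal coupling puts mass on an endpoint pair unreachable under the kernel",
      class = c("sbridge_infeasible", "error", "condition")))

  # backward recursion of the terminal reweighting
  h <- vector("list", T + 1L)
  h[[T + 1L]] <- exp(solution$beta)
  for (t in T:1) h[[t]] <- as.vector(kernel %*% h[[t + 1L]])

  kernels <- vector("list", T)
  for (t in seq_len(T)) {
    Kt <- kernel * rep(h[[t + 1L]], each = k)   # kernel[s,s'] * h_{t+1}(s')
    hs <- h[[t]]
    live <- hs > 0
    Kt[live, ] <- Kt[live, , drop = FALSE] / hs[live]
    # states with h_t = 0 carry zero probability under the controlled path;
    # give them an arbitrary valid row to keep the kernel stochastic
    if (any(!live)) Kt[!live, ] <- 1 / k
    Kt <- Kt / rowSums(Kt)
    kernels[[t]] <- Kt
  }

  structure(list(horizon = T, initial = solution$pi, kernels = kernels),
            class = "path_distribution")
}

#' Path law of the uncontrolled baseline chain
#'
#' The homogeneous counterpart of [reconstruct_full_path()]: the baseline
#' kernel applied for T steps from `pi`, packaged in the same
#' `path_distribution` form for side-by-side comparison.
#'
#' @inheritParams uncontrolled_joint
#' @return a `path_distribution` with T copies of `kernel`.
#' @export
uncontrolled_path <- function(pi, kernel, T = 1L) {
  check_prob_vector(pi)
  check_transition_matrix(kernel)
  T <- as.integer(T)
  if (T < 1) stop("horizon T must be a positive integer", call. = FALSE)
  structure(list(horizon = T, initial = pi,
                 kernels = rep(list(kernel), T)),
            class = "path_distribution")
}

#' Marginal state distribution of a path law at one time point
#'
#' @param path a `path_distribution`.
#' @param t time index in `0:T`.
#' @return length-k probability vector at time t.
#' @export
path_marginal <- function(path, t) {
  stopifnot(inherits(path, "path_distribution"), t >= 0, t <= path$horizon)
  m <- path$initial
  if (t > 0) for (s in seq_len(t)) m <- as.vector(m %*% path$kernels[[s]])
  m
}

#' Enumerate all trajectories of a path law
#'
#' Exhaustively lists the k^(T+1) state trajectories with their probabilities.
#' Intended for small k and T, where it serves as an exact oracle for
#' path-level divergences.
#'
#' @param path a `path_distribution`.
#' @return data.frame with one column per time point (`t0`, ..., `tT`) and a
#'   `prob` column; probabilities sum to 1.
#' @export
enumerate_paths <- function(path) {
  stopifnot(inherits(path, "path_distribution"))
  k <- length(path$initial)
  T <- path$horizon
  grid <- expand.grid(rep(list(seq_len(k)), T + 1L))
  names(grid) <- paste0("t", 0:T)
  prob <- path$initial[grid[[1L]]]
  for (t in seq_len(T)) {
    prob <- prob * path$kernels[[t]][cbind(grid[[t]], grid[[t + 1L]])]
  }
  grid$prob <- prob
  grid
}

#' KL divergence between two path laws by exhaustive enumeration
#'
#' Computes D_KL(p || q) over whole trajectories by enumerating all k^(T+1)
#' paths. Exact but exponential in T; meant as an oracle on small systems.
#'
#' @param p,q `path_distribution` objects with the same k and horizon.
#' @return divergence in nats.
#' @export
path_kl <- function(p, q) {
  stopifnot(inherits(p, "path_distribution"), inherits(q, "path_distribution"),
            p$horizon == q$horizon,
            length(p$initial) == length(q$initial))
  pp <- enumerate_paths(p)$prob
  qq <- enumerate_paths(q)$prob
  if (any(pp > 0 & qq == 0))
    stop(errorCondition(
      "support_violation: controlled path has mass on a trajectory impossible under the baseline",
      class = c("sbridge_support_violation", "error", "condition")))
  pos <- pp > 0
  sum(pp[pos] * (log(pp[pos]) - log(qq[pos])))
}
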