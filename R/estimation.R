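# Estimation of state distributions and the baseline transition kernel from
# multi-subject coarse-grained state sequences, with trajectory bootstrapping
# for uncertainty propagation.

#' Assemble a multi-subject set of state sequences
#'
#' Container used by all estimation functions: one row per time frame, in
#' temporal order within each subject x condition block, with integer states
#' in 1..k.
#'
#' @param subject character/factor vector of subject identifiers.
#' @param condition character/factor vector of condition labels (e.g. "rest",
#'   task names).
#' @param state integer vector of coarse-grained states in 1..k.
#' @param k number of states.
#' @return data.frame of class `state_seqs` with attribute `k`.
#' @export
state_sequences <- function(subject, condition, state, k) {
  if (length(subject) != length(state) || length(condition) != length(state))
    stop("subject, condition and state must have equal length", call. = FALSE)
  if (length(state) == 0L) stop("empty state sequence set", call. = FALSE)
  subject <- as.character(subject)
  condition <- as.character(condition)
  if (any(!nzchar(subject)) || any(!nzchar(condition)))
    stop("subject and condition labels must be nonempty", call. = FALSE)
  state <- as.integer(state)
  if (!is.numeric(k) || k < 2) stop("k must be >= 2", call. = FALSE)
  k <- as.integer(k)
  if (any(is.na(state)) || any(state < 1L) || any(state > k))
    stop("states must be integers in 1..k", call. = FALSE)
  structure(data.frame(subject = subject, condition = condition,
                       state = state, stringsAsFactors = FALSE),
            k = k, class = c("state_seqs", "data.frame"))
}

seqs_k <- function(seqs) {
  k <- attr(seqs, "k")
  if (is.null(k)) stop("not a state_seqs object (missing k)", call. = FALSE)
  k
}

pick_condition <- function(seqs, condition) {
  if (!condition %in% seqs$condition)
    stop("unknown condition: ", condition, call. = FALSE)
  seqs[seqs$condition == condition, , drop = FALSE]
}

#' Empirical state distribution of one condition
#'
#' Occupancy frequencies of the k states over all frames of all subjects in
#' the given condition.
#'
#' @param seqs a [state_sequences()] object.
#' @param condition condition label to tabulate.
#' @return length-k probability vector.
#' @export
empirical_distribution <- function(seqs, condition) {
  k <- seqs_k(seqs)
  sub <- pick_condition(seqs, condition)
  as.vector(tabulate(sub$state, nbins = k)) / nrow(sub)
}

#' List of consecutive-frame transitions within subjects
#'
#' Builds the pooled list of (from, to) state pairs over consecutive frames,
#' never pairing the last frame of one subject with the first frame of the
#' next: transitions across subject boundaries are excluded. Subjects whose
#' sequence has fewer than two frames contribute no pairs.
#'
#' @inheritParams empirical_distribution
#' @return data.frame of class `transition_list` with columns `subject`,
#'   `from`, `to`, in temporal order within subject; attribute `k`.
#' @export
build_transition_list <- function(seqs, condition) {
  k <- seqs_k(seqs)
  sub <- pick_condition(seqs, condition)
  parts <- lapply(split(seq_len(nrow(sub)), sub$subject), function(idx) {
    s <- sub$state[idx]
    if (length(s) < 2L) return(NULL)
    data.frame(subject = sub$subject[idx[1L]],
               from = s[-length(s)], to = s[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(subject = character(), from = integer(),
                      to = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, k = k, class = c("transition_list", "data.frame"))
}

#' Bootstrap resample of the baseline joint transition distribution
#'
#' Draws `n_draws` transition pairs uniformly with replacement from the
#' pooled within-subject transition list, counts them into a k x k matrix and
#' normalizes to a joint probability matrix over (X_t, X_t+1). One such
#' resample underlies each trajectory-bootstrap replicate.
#'
#' @param tlist a [build_transition_list()] result.
#' @param n_draws number of sampled pairs; defaults to the list length.
#' @param seed integer seed for the draw (local RNG; the caller's RNG state
#'   is untouched).
#' @return k x k joint matrix, grand sum 1, `attr(, "horizon") = 1`.
#' @export
bootstrap_joint <- function(tlist, n_draws = nrow(tlist), seed = 1L) {
  k <- attr(tlist, "k")
  if (is.null(k)) stop("not a transition_list (missing k)", call. = FALSE)
  if (nrow(tlist) == 0L) stop("empty transition list", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  idx <- with_seed(seed, sample.int(nrow(tlist), n_draws, replace = TRUE))
  M <- matrix(0, k, k)
  counts <- table(factor(tlist$from[idx], levels = seq_len(k)),
                  factor(tlist$to[idx], levels = seq_len(k)))
  M[] <- as.numeric(counts)
  M <- M / n_draws
  attr(M, "horizon") <- 1L
  M
}

#' Row-normalize a joint distribution into a transition matrix
#'
#' `kernel[i, j] = joint[i, j] / rowSums(joint)[i]`. A state never observed
#' as a transition source (all-zero row) makes the kernel undefined for that
#' row and raises a named error; choosing fewer states or smoothing the
#' estimate avoids this.
#'
#' @param joint k x k joint matrix over consecutive states.
#' @return k x k row-stochastic matrix.
#' @export
to_transition_matrix <- function(joint) {
  joint <- structure(as.matrix(joint), horizon = NULL)
  check_joint(joint)
  rs <- rowSums(joint)
  zero <- which(rs == 0)
  if (length(zero))
    stop(errorCondition(
      paste0("unobserved_source_state: state ", zero[1L],
             " never occurs as a transition source; consider a smaller k or smoothing"),
      class = c("sbridge_unobserved_state", "error", "condition")))
  joint / rs
}

#' Bootstrap resample of a condition's state distribution
#'
#' Draws `n_draws` frames uniformly with replacement from the condition's
#' pooled frames and normalizes the state counts, mirroring the
#' trajectory-bootstrap treatment of marginal distributions.
#'
#' @inheritParams empirical_distribution
#' @param n_draws number of sampled frames; defaults to the number available.
#' @param seed integer seed for the draw.
#' @return length-k probability vector.
#' @export
bootstrap_distribution <- function(seqs, condition, n_draws = NULL, seed = 1L) {
  k <- seqs_k(seqs)
  sub <- pick_condition(seqs, condition)
  if (is.null(n_draws)) n_draws <- nrow(sub)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  s <- with_seed(seed, sample(sub$state, n_draws, replace = TRUE))
  as.vector(tabulate(s, nbins = k)) / n_draws
}

#' Bootstrap ensemble of transition costs between two conditions
#'
#' For each replicate, independently resamples (i) the baseline joint (and
#' hence kernel) from the baseline condition's transition list and (ii) the
#' two condition distributions from their frames, then computes the bridge
#' transition cost from `cond_a`'s distribution to `cond_b`'s under the
#' resampled baseline kernel. Replicates whose resampled kernel leaves the
#' problem infeasible (e.g. an unobserved source state) are recorded with a
#' named status, never silently dropped.
#'
#' @inheritParams empirical_distribution
#' @param baseline condition label supplying the uncontrolled dynamics.
#' @param cond_a,cond_b condition labels for the initial and target
#'   distributions.
#' @param T bridge horizon (steps of the baseline kernel).
#' @param n_replicates number of bootstrap replicates (>= 2).
#' @param seed master seed; each replicate derives its own named streams, so
#'   the whole ensemble is reproducible bit for bit.
#' @param tol,max_iter forwarded to [solve_bridge()].
#' @return object of class `bootstrap_costs`: list with `costs` (length
#'   `n_replicates`, NA where infeasible), `status`, `mean`, `sd` (over the
#'   feasible replicates), `n_replicates`, `n_infeasible`, `seed`.
#' @export
bootstrap_costs <- function(seqs, baseline, cond_a, cond_b, T = 1L,
                            n_replicates = 100L, seed = 1L,
                            tol = 1e-10, max_iter = 1e5) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  tlist <- build_transition_list(seqs, baseline)
  costs <- rep(NA_real_, n_replicates)
  status <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    kernel_seed <- derive_seed(seed, paste0("rep", r, ":kernel"))
    a_seed <- derive_seed(seed, paste0("rep", r, ":", cond_a, ":a"))
    b_seed <- derive_seed(seed, paste0("rep", r, ":", cond_b, ":b"))
    res <- tryCatch({
      kern <- to_transition_matrix(bootstrap_joint(tlist, seed = kernel_seed))
      pa <- bootstrap_distribution(seqs, cond_a, seed = a_seed)
      pb <- bootstrap_distribution(seqs, cond_b, seed = b_seed)
      list(cost = transition_cost(pa, pb, kern, T = T, tol = tol,
                                  max_iter = max_iter),
           status = "ok")
    },
    sbridge_infeasible = function(e) list(cost = NA_real_, status = "infeasible"),
    sbridge_unobserved_state = function(e) list(cost = NA_real_, status = "infeasible"),
    sbridge_not_converged = function(e) list(cost = NA_real_, status = "not_converged"))
    costs[r] <- res$cost
    status[r] <- res$status
  }
  ok <- status == "ok"
  structure(list(costs = costs, status = status,
                 mean = mean(costs[ok]), sd = stats::sd(costs[ok]),
                 n_replicates = n_replicates,
                 n_infeasible = sum(!ok), seed = seed,
                 from = cond_a, to = cond_b, baseline = baseline, T = T),
            class = "bootstrap_costs")
}

#' @export
print.bootstrap_costs <- function(x, ...) {
  cat("Bootstrap transition costs ", x$from, " -> ", x$to,
      " (baseline: ", x$baseline, ", T = ", x$T, ")\n", sep = "")
  cat("  mean ", format(x$mean, digits = 6), " nats, sd ",
      format(x$sd, digits = 6), " over ", sum(x$status == "ok"), "/",
      x$n_replicates, " feasible replicates\n", sep = "")
  invisible(x)
}
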