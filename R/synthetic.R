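# Ground-truth-known synthetic data: Markov state sequences from a specified
# baseline kernel, task conditions as i.i.d. draws from tilted target
# distributions (only marginals of task data ever enter the downstream
# computation; the baseline alone supplies dynamics), and directional
# Gaussian activity clusters that cosine k-means can recover.

#' Specification of a synthetic study
#'
#' Bundles everything needed to generate a multi-subject synthetic dataset:
#' the true baseline kernel, per-condition target ("tilt") distributions,
#' cohort and recording sizes, and the activity-geometry parameters.
#'
#' @param k number of discrete states.
#' @param n_subjects subjects per condition.
#' @param frames_per_condition frames recorded per subject and condition.
#' @param baseline_kernel true k x k row-stochastic resting kernel.
#' @param condition_tilts named list of length-k probability vectors, one per
#'   non-baseline condition; frames of those conditions are drawn i.i.d.
#'   from these distributions.
#' @param baseline label of the baseline condition (default "rest").
#' @param channel_dim M, the activity-space dimension (M >= k for separated
#'   planted directions).
#' @param cluster_concentration inverse noise scale of the activity clusters;
#'   frame noise is isotropic Gaussian with sd `1 / cluster_concentration`.
#' @param seed master seed for all generation streams.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(k, n_subjects, frames_per_condition,
                           baseline_kernel, condition_tilts,
                           baseline = "rest", channel_dim = 20L,
                           cluster_concentration = 8, seed = 1L) {
  check_transition_matrix(baseline_kernel)
  stopifnot(nrow(baseline_kernel) == k, n_subjects >= 1,
            frames_per_condition >= 2, cluster_concentration > 0)
  if (length(condition_tilts) > 0 &&
      (is.null(names(condition_tilts)) || any(!nzchar(names(condition_tilts)))))
    stop("condition_tilts must be a named list", call. = FALSE)
  for (nm in names(condition_tilts))
    check_prob_vector(condition_tilts[[nm]], paste0("tilt '", nm, "'"))
  if (channel_dim < k)
    stop("channel_dim must be >= k to place separated directions",
         call. = FALSE)
  structure(list(k = as.integer(k), n_subjects = as.integer(n_subjects),
                 frames_per_condition = as.integer(frames_per_condition),
                 baseline_kernel = baseline_kernel,
                 condition_tilts = condition_tilts,
                 baseline = baseline,
                 channel_dim = as.integer(channel_dim),
                 cluster_concentration = cluster_concentration,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

simulate_chain <- function(kernel, n, init) {
  k <- nrow(kernel)
  s <- integer(n)
  s[1L] <- sample.int(k, 1L, prob = init)
  for (t in seq_len(n - 1L))
    s[t + 1L] <- sample.int(k, 1L, prob = kernel[s[t], ])
  s
}

#' Simulate multi-subject state sequences
#'
#' The baseline condition evolves as a first-order Markov chain under the
#' spec's kernel, started from its stationary distribution (or uniformly with
#' `uniform_start = TRUE`, e.g. for non-ergodic kernels). Every other
#' condition draws frames i.i.d. from its tilt distribution. Fully
#' reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param uniform_start start baseline chains from the uniform distribution
#'   instead of the stationary one.
#' @return a [state_sequences()] object covering all subjects and conditions.
#' @export
simulate_state_sequences <- function(spec, uniform_start = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$k
  init <- if (uniform_start) rep(1 / k, k) else
    stationary_distribution(spec$baseline_kernel)
  conds <- c(spec$baseline, names(spec$condition_tilts))
  subj <- cond <- character(0)
  state <- integer(0)
  nf <- spec$frames_per_condition
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%03d", s)
    for (cn in conds) {
      states <- with_seed(derive_seed(spec$seed, paste0(sid, ":", cn)), {
        if (cn == spec$baseline)
          simulate_chain(spec$baseline_kernel, nf, init)
        else
          sample.int(k, nf, replace = TRUE, prob = spec$condition_tilts[[cn]])
      })
      subj <- c(subj, rep(sid, nf))
      cond <- c(cond, rep(cn, nf))
      state <- c(state, states)
    }
  }
  state_sequences(subj, cond, state, k)
}

#' Simulate activity matrices from planted directional clusters
#'
#' Assigns each state a unit direction in M-dimensional activity space (the
#' columns of a random orthogonal frame, so planted directions are mutually
#' orthogonal) and renders each frame as its state's direction plus isotropic
#' Gaussian noise with sd `1 / concentration`. This gives cosine k-means a
#' recoverable planted structure while carrying the subject/condition labels
#' through.
#'
#' @param seqs a [state_sequences()] object (the ground-truth states).
#' @param M activity-space dimension, `M >= k`.
#' @param concentration inverse noise sd (larger = tighter clusters).
#' @param seed integer seed.
#' @return list of class `activity_data`: `x` (M x N matrix), `subject`,
#'   `condition`, `state` (true generating states), `centroids` (k x M).
#' @export
simulate_activity <- function(seqs, M = 20L, concentration = 8, seed = 1L) {
  k <- seqs_k(seqs)
  if (M < k)
    stop("cannot place ", k, " separated directions in dimension ", M,
         call. = FALSE)
  n <- nrow(seqs)
  out <- with_seed(derive_seed(seed, "activity"), {
    G <- matrix(rnorm(M * k), M, k)
    centroids <- qr.Q(qr(G))[, seq_len(k), drop = FALSE]  # orthonormal columns
    noise <- matrix(rnorm(M * n, sd = 1 / concentration), M, n)
    list(x = centroids[, seqs$state, drop = FALSE] + noise,
         centroids = t(centroids))
  })
  structure(list(x = out$x, subject = seqs$subject,
                 condition = seqs$condition, state = seqs$state,
                 centroids = out$centroids),
            class = "activity_data")
}

#' Build a planted rest / easy / hard hierarchy
#'
#' Constructs a synthetic study in which two task conditions sit at strictly
#' increasing true bridge cost from the baseline: both tilt the stationary
#' distribution toward the states the resting dynamics visit rarely, the
#' "hard" condition further than the "easy" one. Because the transition cost
#' is convex in the target distribution and zero at the stationary target,
#' costs along this common ray are strictly ordered by construction. The true
#' (infinite-data) pairwise cost matrix under the true kernel ships with the
#' spec as oracle values, and the planted easy/hard asymmetry
#' (cost(easy -> hard) > cost(hard -> easy)) is verified at construction.
#'
#' @param k number of states.
#' @param seed master seed.
#' @param n_subjects,frames_per_condition cohort sizes for downstream
#'   simulation.
#' @param tilt_easy,tilt_hard mixing weights toward the rare-state
#'   distribution for the two task conditions (0 < easy < hard < 1).
#' @return a [synthetic_spec()] with extra fields `true_costs` (3 x 3 matrix
#'   over rest/easy/hard, entry (a, b) = true cost a -> b) and
#'   `true_stationary`.
#' @export
make_planted_hierarchy <- function(k = 6L, seed = 1L, n_subjects = 96L,
                                   frames_per_condition = 176L,
                                   tilt_easy = 0.25, tilt_hard = 0.55) {
  stopifnot(tilt_easy > 0, tilt_hard > tilt_easy, tilt_hard < 1)
  kernel <- with_seed(derive_seed(seed, "planted-kernel"), {
    W <- matrix(runif(k * k, 0.2, 1), k, k)
    # sticky diagonal with heterogeneous self-persistence so the stationary
    # distribution is far from uniform
    diag(W) <- diag(W) + seq(1, 4, length.out = k)
    W / rowSums(W)
  })
  pi0 <- stationary_distribution(kernel)
  rare <- (1 / pi0) / sum(1 / pi0)        # mass toward rarely visited states
  easy <- (1 - tilt_easy) * pi0 + tilt_easy * rare
  hard <- (1 - tilt_hard) * pi0 + tilt_hard * rare

  dists <- list(rest = pi0, easy = easy, hard = hard)
  tc <- matrix(0, 3, 3, dimnames = list(names(dists), names(dists)))
  for (a in names(dists)) for (b in names(dists))
    tc[a, b] <- transition_cost(dists[[a]], dists[[b]], kernel, T = 1L)

  if (!(tc["rest", "easy"] < tc["rest", "hard"]))
    stop("planted ordering failed; choose different tilts", call. = FALSE)
  if (!(tc["easy", "hard"] > tc["hard", "easy"]))
    stop("planted asymmetry failed; choose different tilts", call. = FALSE)

  spec <- synthetic_spec(k = k, n_subjects = n_subjects,
                         frames_per_condition = frames_per_condition,
                         baseline_kernel = kernel,
                         condition_tilts = list(easy = easy, hard = hard),
                         baseline = "rest", channel_dim = max(20L, k),
                         cluster_concentration = 8, seed = seed)
  spec$true_costs <- tc
  spec$true_stationary <- pi0
  spec
}
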