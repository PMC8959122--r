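# Coarse-graining of multivariate activity into k discrete states with
# cosine-similarity k-means (spherical k-means): frames and centroids live on
# the unit sphere and assignment maximizes the dot product. Base kmeans() is
# Euclidean-only (the Lloyd update would leave centroids off the sphere), so
# the spherical variant is implemented here directly.

normalize_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) stop("zero-norm frame: cosine geometry undefined",
                          call. = FALSE)
  sweep(x, 2L, nrm, "/")
}

# k-means++ style seeding on the sphere: squared chordal distance weights.
seed_centroids <- function(xn, k) {
  n <- ncol(xn)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- 2 - 2 * crossprod(xn[, idx[1L]], xn)[1L, ]
  if (k > 1L) for (j in 2:k) {
    w <- pmax(d2, 0)
    idx[j] <- if (sum(w) == 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = w)
    d2 <- pmin(d2, 2 - 2 * crossprod(xn[, idx[j]], xn)[1L, ])
  }
  xn[, idx, drop = FALSE]
}

spherical_lloyd <- function(xn, centroids, max_iter = 100L) {
  k <- ncol(centroids)
  n <- ncol(xn)
  assign_old <- rep(0L, n)
  obj_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sims <- crossprod(centroids, xn)            # k x n cosine similarities
    assign <- max.col(t(sims), ties.method = "first")
    obj <- sum(2 - 2 * sims[cbind(assign, seq_len(n))])  # squared chordal
    obj_trace <- c(obj_trace, obj)
    if (identical(assign, assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # empty-cluster repair: reseed at the worst-fit frame
        fit <- sims[cbind(assign, seq_len(n))]
        centroids[, j] <- xn[, which.min(fit)]
        next
      }
      m <- rowSums(xn[, members, drop = FALSE])
      nm <- sqrt(sum(m^2))
      centroids[, j] <- if (nm > 0) m / nm else xn[, which(members)[1L]]
    }
  }
  list(centroids = centroids, assignments = assign, objective = obj,
       obj_trace = obj_trace, iterations = it)
}

# total dispersion about the single best direction (the k = 1 solution)
total_dispersion <- function(xn) {
  m <- rowSums(xn)
  nm <- sqrt(sum(m^2))
  if (nm == 0) return(2 * ncol(xn))             # antipodally balanced data
  sum(2 - 2 * crossprod(m / nm, xn)[1L, ])
}

#' Fit cosine k-means to an activity matrix
#'
#' Spherical k-means: each frame (column) is normalized to unit length and
#' clustered by maximizing cosine similarity to k unit-norm centroid
#' directions, equivalently minimizing squared chordal distance on the
#' sphere. The best of `n_restarts` k-means++-seeded Lloyd runs (by total
#' within-cluster dispersion) is returned. Deterministic given `seed`.
#'
#' @param x M x N numeric matrix, channels/parcels in rows, time frames in
#'   columns; no zero columns.
#' @param k number of clusters (coarse-grained states), `2 <= k <= N`.
#' @param n_restarts independent seeded restarts; the best objective wins.
#' @param seed integer seed (local RNG).
#' @param max_iter Lloyd iteration cap per restart.
#' @return object of class `cluster_model`: list with `centroids` (k x M,
#'   unit rows), `assignments` (length N, states 1..k), `explained_variance`,
#'   `objective`, `k`, `seed`.
#' @export
fit_cosine_kmeans <- function(x, k, n_restarts = 10L, seed = 1L,
                              max_iter = 100L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (k < 1L || k > ncol(x)) stop("k must satisfy 1 <= k <= N frames",
                                  call. = FALSE)
  xn <- normalize_cols(x)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, paste0("kmeans-restart", r)), {
      spherical_lloyd(xn, seed_centroids(xn, k), max_iter = max_iter)
    })
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  tot <- total_dispersion(xn)
  ev <- if (tot > 0) 1 - best$objective / tot else 1
  structure(list(centroids = t(best$centroids),
                 assignments = best$assignments,
                 explained_variance = max(0, min(1, ev)),
                 objective = best$objective,
                 obj_trace = best$obj_trace,
                 k = k, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cosine k-means model: k = ", x$k, ", ", length(x$assignments),
      " frames, explained variance ",
      format(x$explained_variance, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Assign frames to the nearest centroid direction
#'
#' Maps each frame of `x` to the centroid with maximum cosine similarity;
#' ties break to the lowest state index.
#'
#' @param model a [fit_cosine_kmeans()] model.
#' @param x M x N activity matrix with the model's channel dimension.
#' @return integer state sequence of length N (values 1..k).
#' @export
assign_states <- function(model, x) {
  stopifnot(inherits(model, "cluster_model"))
  x <- as.matrix(x)
  if (nrow(x) != ncol(model$centroids))
    stop("channel dimension mismatch with the fitted model", call. = FALSE)
  sims <- model$centroids %*% normalize_cols(x)
  max.col(t(sims), ties.method = "first")
}

#' Explained-variance curve over a range of cluster counts
#'
#' Fits cosine k-means for each k in `k_min:k_max` and reports the fraction
#' of total spherical dispersion explained, the diagnostic used to choose the
#' number of coarse-grained states (the curve plateaus once k exceeds the
#' number of genuinely distinct activity patterns).
#'
#' @inheritParams fit_cosine_kmeans
#' @param k_min,k_max inclusive range of cluster counts.
#' @return data.frame with columns `k` and `explained_variance`.
#' @export
explained_variance_curve <- function(x, k_min = 2L, k_max = 12L,
                                     n_restarts = 10L, seed = 1L) {
  if (k_max > ncol(as.matrix(x)))
    stop("k_max exceeds the number of frames", call. = FALSE)
  ks <- k_min:k_max
  ev <- vapply(ks, function(k) {
    fit_cosine_kmeans(x, k, n_restarts = n_restarts,
                      seed = derive_seed(seed, paste0("evcurve-k", k)))$explained_variance
  }, numeric(1))
  data.frame(k = ks, explained_variance = ev)
}

#' State-occupancy check per subject and condition
#'
#' Verifies that every coarse-grained state occurs at least once in every
#' subject x condition block — the criterion used alongside the
#' explained-variance curve to bound the usable number of states.
#'
#' @param assignments integer state sequence (1..k).
#' @param subject,condition per-frame labels aligned with `assignments`.
#' @param k number of states.
#' @return list with `table` (rows: subject, condition, comma-separated
#'   missing states; only blocks with missing states) and `pass` (TRUE when
#'   nothing is missing anywhere).
#' @export
occupancy_check <- function(assignments, subject, condition, k) {
  stopifnot(length(subject) == length(assignments),
            length(condition) == length(assignments))
  df <- data.frame(subject = as.character(subject),
                   condition = as.character(condition),
                   state = assignments, stringsAsFactors = FALSE)
  keys <- unique(df[, c("subject", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    s <- df$state[df$subject == keys$subject[r] &
                  df$condition == keys$condition[r]]
    missing <- which(tabulate(s, nbins = k) == 0L)
    if (!length(missing)) return(NULL)
    data.frame(subject = keys$subject[r], condition = keys$condition[r],
               missing_states = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(subject = character(), condition = character(),
                      missing_states = character(), stringsAsFactors = FALSE)
  list(table = tab, pass = nrow(tab) == 0L)
}

#' Frame-count balancing plan across conditions
#'
#' To keep each condition from contributing unequal data to clustering and
#' estimation, all conditions are truncated to the smallest per-condition
#' frame count, keeping each condition's first frames.
#'
#' @param counts named integer vector of available frames per condition.
#' @return data.frame with columns `condition`, `available`, `keep` (the
#'   common truncation length, first `keep` frames retained).
#' @export
balance_frames <- function(counts) {
  if (length(counts) == 0L || is.null(names(counts)))
    stop("counts must be a named vector of per-condition frame counts",
         call. = FALSE)
  if (any(counts < 1)) stop("every condition needs at least one frame",
                            call. = FALSE)
  keep <- min(counts)
  data.frame(condition = names(counts), available = as.integer(counts),
             keep = as.integer(keep), stringsAsFactors = FALSE)
}
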