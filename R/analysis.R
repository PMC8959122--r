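# Condition-pair cost matrices, transition-cost asymmetry, the ordering
# consistency relation, and bootstrap significance tests.

#' Bootstrap cost matrix over all ordered condition pairs
#'
#' Runs [bootstrap_costs()] for every ordered pair of the requested
#' conditions under the baseline condition's resampled kernel, and collects
#' replicate costs, means and standard deviations. Note the diagonal is not
#' forced to zero: the cost of "transitioning" a condition to itself is zero
#' only when its distribution already equals its own uncontrolled image.
#'
#' @inheritParams bootstrap_costs
#' @param conditions ordered character vector of condition labels to compare
#'   (defaults to all conditions present, baseline first).
#' @return object of class `cost_table`: list with `conditions`, `mean` and
#'   `sd` (n x n matrices, entry (a, b) = cost a -> b), `replicates`
#'   (n_replicates x n x n array), `n_replicates`, `baseline`, `T`, `seed`,
#'   `n_infeasible`, and `notes` recording the independence caveat for the
#'   downstream t tests.
#' @export
pairwise_costs <- function(seqs, baseline, conditions = NULL, T = 1L,
                           n_replicates = 100L, seed = 1L,
                           tol = 1e-10, max_iter = 1e5) {
  if (is.null(conditions)) {
    conditions <- unique(seqs$condition)
    conditions <- c(baseline, setdiff(conditions, baseline))
  }
  if (!baseline %in% seqs$condition)
    stop("unknown baseline condition: ", baseline, call. = FALSE)
  n <- length(conditions)
  reps <- array(NA_real_, dim = c(n_replicates, n, n),
                dimnames = list(NULL, conditions, conditions))
  mean_m <- sd_m <- matrix(NA_real_, n, n,
                           dimnames = list(conditions, conditions))
  infeasible <- 0L
  for (a in seq_len(n)) for (b in seq_len(n)) {
    bc <- bootstrap_costs(seqs, baseline, conditions[a], conditions[b],
                          T = T, n_replicates = n_replicates, seed = seed,
                          tol = tol, max_iter = max_iter)
    reps[, a, b] <- bc$costs
    mean_m[a, b] <- bc$mean
    sd_m[a, b] <- bc$sd
    infeasible <- infeasible + bc$n_infeasible
  }
  structure(list(conditions = conditions, mean = mean_m, sd = sd_m,
                 replicates = reps, n_replicates = n_replicates,
                 baseline = baseline, T = T, seed = seed,
                 n_infeasible = infeasible,
                 notes = "bootstrap replicates treated as independent samples in downstream t tests (anti-conservative); no multiple-testing correction applied"),
            class = "cost_table")
}

#' @export
print.cost_table <- function(x, digits = 4, ...) {
  cat("Bootstrap transition-cost table (nats), baseline '", x$baseline,
      "', T = ", x$T, ", ", x$n_replicates, " replicates\n", sep = "")
  print(round(x$mean, digits))
  invisible(x)
}

#' Transition-cost asymmetry matrix
#'
#' For each ordered condition pair, `diff[a, b] = cost(a -> b) -
#' cost(b -> a)`, using the mean bootstrap costs. Rows and columns are
#' arranged in ascending order of cost from the baseline condition, so a
#' hierarchy of conditions shows as an all-positive upper triangle.
#'
#' @param table a [pairwise_costs()] result.
#' @param baseline condition used for the ascending arrangement; defaults to
#'   the table's baseline.
#' @return list of class `asymmetry_matrix`: `diff` (antisymmetric n x n
#'   matrix), `order` (condition arrangement used).
#' @export
asymmetry_matrix <- function(table, baseline = table$baseline) {
  stopifnot(inherits(table, "cost_table"))
  if (!baseline %in% table$conditions)
    stop("baseline not in the cost table", call. = FALSE)
  from_base <- table$mean[baseline, ]
  ord <- order(from_base)
  m <- table$mean[ord, ord, drop = FALSE]
  structure(list(diff = m - t(m), order = table$conditions[ord]),
            class = "asymmetry_matrix")
}

#' @export
print.asymmetry_matrix <- function(x, digits = 4, ...) {
  cat("Transition-cost asymmetry Diff(a, b) = cost(a->b) - cost(b->a) (nats)\n")
  print(round(x$diff, digits))
  invisible(x)
}

#' Ordering-consistency of costs from the baseline
#'
#' Checks, for every unordered condition pair {A, B} with
#' cost(baseline -> A) > cost(baseline -> B), whether the direct costs obey
#' cost(B -> A) > cost(A -> B): conditions that are more expensive to reach
#' from the baseline should also be more expensive to reach from other
#' conditions than to leave toward them.
#'
#' @inheritParams asymmetry_matrix
#' @return list with `fraction` (of pairs satisfying the relation),
#'   `n_pairs`, and `violations` (data.frame of offending pairs).
#' @export
ordering_consistency <- function(table, baseline = table$baseline) {
  stopifnot(inherits(table, "cost_table"))
  conds <- setdiff(table$conditions, baseline)
  from_base <- table$mean[baseline, ]
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  n_ok <- 0L
  viol <- list()
  for (p in pairs) {
    a <- p[1L]; b <- p[2L]
    # orient so that a is the condition farther from baseline
    if (from_base[a] < from_base[b]) { tmp <- a; a <- b; b <- tmp }
    ok <- table$mean[b, a] > table$mean[a, b]
    if (ok) n_ok <- n_ok + 1L else
      viol[[length(viol) + 1L]] <- data.frame(farther = a, nearer = b,
                                              stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(farther = character(), nearer = character(),
               stringsAsFactors = FALSE)
  list(fraction = if (length(pairs)) n_ok / length(pairs) else NA_real_,
       n_pairs = length(pairs), violations = violations)
}

#' Pooled-variance two-sample t test on bootstrap cost ensembles
#'
#' Student t statistic with pooled variance and df = n_a + n_b - 2; the sign
#' is positive when `costs_a` has the larger mean. One-sided p-values test
#' mean(a) > mean(b) (`"greater"`, default) or the reverse. Bootstrap
#' replicates are treated as independent samples, which is anti-conservative;
#' the returned object records this caveat and the group sizes so users can
#' correct across multiple comparisons.
#'
#' @param costs_a,costs_b numeric replicate vectors, or [bootstrap_costs()]
#'   objects (feasible replicates are used).
#' @param alternative `"greater"` (mean a > mean b), `"less"`, or
#'   `"two.sided"`.
#' @return list with `t`, `df`, `p`, `alternative`, `n_a`, `n_b`, `note`.
#' @export
bootstrap_ttest <- function(costs_a, costs_b,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(costs_a, "bootstrap_costs"))
    costs_a <- costs_a$costs[costs_a$status == "ok"]
  if (inherits(costs_b, "bootstrap_costs"))
    costs_b <- costs_b$costs[costs_b$status == "ok"]
  na <- length(costs_a); nb <- length(costs_b)
  if (na < 2 || nb < 2) stop("each ensemble needs >= 2 values", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(costs_a) + (nb - 1) * stats::var(costs_b)) /
    (na + nb - 2)
  if (sp2 <= 0)
    stop(errorCondition(
      "degenerate_variance: pooled variance is zero; ensembles are constant",
      class = c("sbridge_degenerate_variance", "error", "condition")))
  tstat <- (mean(costs_a) - mean(costs_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- switch(alternative,
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df, lower.tail = TRUE),
              two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  list(t = tstat, df = df, p = p, alternative = alternative,
       n_a = na, n_b = nb,
       note = "replicates treated as independent; p-values are anti-conservative and uncorrected")
}
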