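# Independent oracles and instance generators used across the suite. All are
# deliberately naive (grid/convex-solver/enumeration) and share no code with
# the package's Sinkhorn path.

# Exhaustive 1-D oracle for k = 2: a 2x2 coupling with both marginals fixed
# has a single free parameter p = P[1,1]; minimize KL over its interval.
bruteforce_cost_k2 <- function(pi, pit, Q) {
  lo <- max(0, pi[1] + pit[1] - 1)
  hi <- min(pi[1], pit[1])
  klp <- function(p) {
    P <- matrix(c(p, pit[1] - p, pi[1] - p, 1 - pi[1] - pit[1] + p), 2, 2)
    pos <- P > 1e-300
    sum(P[pos] * (log(P[pos]) - log(Q[pos])))
  }
  # coarse grid then golden-section refinement (convex objective)
  grid <- seq(lo, hi, length.out = 2001)
  inner <- grid[-c(1, length(grid))]
  v <- vapply(inner, klp, numeric(1))
  p0 <- inner[which.min(v)]
  opt <- stats::optimize(klp, lower = max(lo, p0 - (hi - lo) / 1000),
                         upper = min(hi, p0 + (hi - lo) / 1000),
                         tol = 1e-12)
  min(opt$objective, min(v), klp(lo), klp(hi))
}

# General constrained convex oracle for k = 3: parametrize the coupling by
# its upper-left 2x2 block (the marginals determine the rest) and run a
# log-barrier interior-point solve (constrOptim) from the independent
# coupling. Valid for instances with strictly positive Q and marginals,
# where the optimum is interior.
constr_cost_k3 <- function(pi, pit, Q) {
  expand <- function(x) {
    P <- matrix(0, 3, 3)
    P[1, 1:2] <- x[1:2]; P[2, 1:2] <- x[3:4]
    P[1, 3] <- pi[1] - sum(x[1:2])
    P[2, 3] <- pi[2] - sum(x[3:4])
    P[3, 1] <- pit[1] - x[1] - x[3]
    P[3, 2] <- pit[2] - x[2] - x[4]
    P[3, 3] <- 1 - sum(P[-9])
    P
  }
  f <- function(x) {
    P <- expand(x)
    if (any(P <= 0)) return(Inf)
    sum(P * (log(P) - log(Q)))
  }
  gr <- function(x) {
    P <- expand(x)
    L <- log(P) - log(Q) + 1
    c(L[1, 1] - L[1, 3] - L[3, 1] + L[3, 3],
      L[1, 2] - L[1, 3] - L[3, 2] + L[3, 3],
      L[2, 1] - L[2, 3] - L[3, 1] + L[3, 3],
      L[2, 2] - L[2, 3] - L[3, 2] + L[3, 3])
  }
  # constraints: all nine entries of expand(x) > 0, linear in x
  ui <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
              c(-1, -1, 0, 0), c(0, 0, -1, -1),
              c(-1, 0, -1, 0), c(0, -1, 0, -1),
              c(1, 1, 1, 1))
  ci <- c(0, 0, 0, 0, -pi[1], -pi[2], -pit[1], -pit[2],
          pi[1] + pi[2] + pit[1] + pit[2] - 1)
  P0 <- outer(pi, pit)
  x0 <- c(P0[1, 1:2], P0[2, 1:2])
  res <- stats::constrOptim(x0, f, gr, ui = ui, ci = ci,
                            mu = 1e-8, method = "BFGS",
                            outer.iterations = 200,
                            control = list(maxit = 500, reltol = 1e-14))
  res$value
}

# random strictly positive probability vector
rand_simplex <- function(k, min_mass = 0.02) {
  v <- runif(k, min_mass, 1)
  v / sum(v)
}

# random strictly positive joint with unit sum
rand_joint <- function(k, min_mass = 0.01) {
  m <- matrix(runif(k * k, min_mass, 1), k, k)
  m / sum(m)
}

# random row-stochastic kernel with strictly positive entries
rand_kernel <- function(k, sticky = 0) {
  m <- matrix(runif(k * k, 0.05, 1), k, k)
  if (sticky > 0) diag(m) <- diag(m) + sticky
  m / rowSums(m)
}

# total-variation distance between two kernels (max over rows)
kernel_tv <- function(A, B) max(rowSums(abs(A - B)) / 2)

# best assignment accuracy over all label permutations (k small)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

align_accuracy <- function(truth, est, k) {
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[est] == truth))
  best
}
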