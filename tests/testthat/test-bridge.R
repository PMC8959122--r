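# Core endpoint bridge solver: uncontrolled joint, KL divergence, Sinkhorn
# solution structure, and the closed-form/oracle checks.

test_that("uncontrolled joint composes the kernel over the horizon", {
  # absorbing identity kernel: mass never leaves the starting state
  expect_equal(unclass(uncontrolled_joint(c(1, 0), diag(2), T = 5))[1:4],
               c(1, 0, 0, 0))

  K <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  Q1 <- uncontrolled_joint(c(0.5, 0.5), K, T = 1)
  expect_equal(Q1[1, ], c(0.45, 0.05))
  expect_equal(Q1[2, ], c(0.10, 0.40))
  expect_equal(attr(Q1, "horizon"), 1L)

  # T = 2 against explicit enumeration of all 2-step paths
  Q2 <- uncontrolled_joint(c(0.5, 0.5), K, T = 2)
  enum <- matrix(0, 2, 2)
  for (i in 1:2) for (m in 1:2) for (j in 1:2)
    enum[i, j] <- enum[i, j] + 0.5 * K[i, m] * K[m, j]
  expect_equal(unclass(Q2), enum, ignore_attr = TRUE)
  expect_equal(sum(Q2), 1)

  expect_error(uncontrolled_joint(c(0.5, 0.5), K, T = 0), "horizon")
  expect_error(uncontrolled_joint(c(0.5, 0.3, 0.2), K), "disagree")
})

test_that("KL divergence follows the 0 log 0 convention and flags support violations", {
  Q <- matrix(0.25, 2, 2)
  expect_equal(kl_divergence(Q, Q), 0)
  P <- rbind(c(0.5, 0), c(0, 0.5))
  expect_equal(kl_divergence(P, Q), log(2))
  Qz <- rbind(c(0.25, 0.25), c(0.5, 0))   # Q vanishes where P[2, 2] > 0
  expect_error(kl_divergence(P, Qz), class = "sbridge_support_violation")
  expect_error(kl_divergence(matrix(0.25, 2, 2), matrix(1 / 9, 3, 3)), "shape")
})

test_that("the OT identity kl = transport - entropy holds", {
  U <- matrix(0.25, 2, 2)
  tri <- ot_identity_check(U, U)
  expect_equal(tri[["kl"]], 0)
  expect_equal(tri[["transport_term"]], log(4))
  expect_equal(tri[["entropy"]], log(4))

  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    P <- rand_joint(k); Q <- rand_joint(k)
    tri <- ot_identity_check(P, Q)
    expect_equal(tri[["kl"]], tri[["transport_term"]] - tri[["entropy"]],
                 tolerance = 1e-12)
  }
})

test_that("bridge with already-consistent marginals returns Q at zero cost", {
  set.seed(7)
  Q <- rand_joint(3)
  sol <- solve_bridge(rowSums(Q), colSums(Q), Q)
  expect_s3_class(sol, "bridge_solution")
  expect_lt(sol$cost, 1e-10)
  expect_equal(sol$optimal_joint, Q, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("memoryless kernels give the closed-form cost D_KL(target || row)", {
  # worked 2-state instance: identical rows r, separable optimum
  pi <- c(0.6, 0.4); r <- c(0.5, 0.5); pit <- c(0.9, 0.1)
  sol <- solve_bridge(pi, pit, outer(pi, r))
  expect_equal(sol$cost, 0.9 * log(1.8) + 0.1 * log(0.2), tolerance = 1e-10)
  expect_equal(sol$optimal_joint, outer(pi, pit),
               tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    pi <- rand_simplex(k); r <- rand_simplex(k); pit <- rand_simplex(k)
    kern <- matrix(r, k, k, byrow = TRUE)
    expect_equal(transition_cost(pi, pit, kern),
                 sum(pit * log(pit / r)), tolerance = 1e-10)
  }
})

test_that("Sinkhorn matches the exhaustive 1-D oracle on k = 2 instances", {
  set.seed(3)
  for (rep in 1:25) {
    pi <- rand_simplex(2); pit <- rand_simplex(2); Q <- rand_joint(2)
    expect_equal(solve_bridge(pi, pit, Q)$cost,
                 bruteforce_cost_k2(pi, pit, Q), tolerance = 1e-6)
  }
  # spec worked instance
  Q <- rbind(c(0.4, 0.1), c(0.2, 0.3))
  expect_equal(solve_bridge(c(0.5, 0.5), c(0.7, 0.3), Q)$cost,
               bruteforce_cost_k2(c(0.5, 0.5), c(0.7, 0.3), Q),
               tolerance = 1e-6)
})

test_that("solution has the Gibbs form and satisfies the constraints", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    pi <- rand_simplex(k); pit <- rand_simplex(k); Q <- rand_joint(k)
    sol <- solve_bridge(pi, pit, Q)
    expect_lte(max(abs(rowSums(sol$optimal_joint) - pi)), 1e-10)
    expect_lte(max(abs(colSums(sol$optimal_joint) - pit)), 1e-10)
    # log(P*/Q) - alpha_i - beta_j constant (zero, with the gauge folded in)
    lr <- log(sol$optimal_joint / Q) -
      outer(sol$alpha, sol$beta, "+")
    expect_lt(max(abs(lr)), 1e-8)
    expect_gte(sol$cost, 0)
  }
})

test_that("zeros of Q are preserved exactly and infeasibility is loud", {
  # feasible sparse instance (row 1 can only reach column 1, etc.)
  Q <- rbind(c(0.5, 0, 0), c(0, 0.3, 0), c(0, 0.1, 0.1))
  pi <- rowSums(Q); pit <- c(0.5, 0.35, 0.15)
  sol <- solve_bridge(pi, pit, Q)
  expect_identical(sol$optimal_joint[Q == 0], rep(0, sum(Q == 0)))

  # target mass on a column with no support
  Qz <- rbind(c(0.5, 0), c(0.5, 0))
  expect_error(solve_bridge(c(0.5, 0.5), c(0.5, 0.5), Qz),
               class = "sbridge_infeasible")
  # necessary support condition holds but the polytope is empty:
  # non-convergence must surface as an error carrying the residual
  Qh <- rbind(c(0.5, 0), c(0, 0.5))
  err <- tryCatch(
    solve_bridge(c(0.9, 0.1), c(0.1, 0.9), Qh, max_iter = 500),
    error = identity)
  expect_s3_class(err, "sbridge_not_converged")
  expect_true(is.finite(err$residual))
})

test_that("optional uniform smoothing restores feasibility explicitly", {
  Qz <- rbind(c(0.5, 0), c(0.5, 0))
  sol <- solve_bridge(c(0.5, 0.5), c(0.5, 0.5), Qz, smoothing = 0.01)
  expect_true(sol$converged)
  expect_gt(sol$cost, 0)
})

test_that("transition_cost handles the zero-cost image and symmetry properties", {
  set.seed(9)
  K <- rand_kernel(4)
  pi <- rand_simplex(4)
  expect_lt(transition_cost(pi, as.vector(pi %*% K), K), 1e-10)

  # symmetric joint Q: transposition swaps the two problems
  for (rep in 1:5) {
    m <- matrix(runif(16, 0.05, 1), 4, 4)
    Q <- (m + t(m)); Q <- Q / sum(Q)
    a <- rand_simplex(4); b <- rand_simplex(4)
    expect_equal(solve_bridge(a, b, Q, tol = 1e-13)$cost,
                 solve_bridge(b, a, Q, tol = 1e-13)$cost,
                 tolerance = 1e-10)
  }

  # bits reporting is a fixed rescaling of nats
  expect_equal(transition_cost(c(0.6, 0.4), c(0.9, 0.1),
                               matrix(0.5, 2, 2), units = "bits"),
               transition_cost(c(0.6, 0.4), c(0.9, 0.1),
                               matrix(0.5, 2, 2)) / log(2))
})

test_that("the solver is deterministic: identical inputs, identical output", {
  set.seed(13)
  pi <- rand_simplex(5); pit <- rand_simplex(5); Q <- rand_joint(5)
  s1 <- solve_bridge(pi, pit, Q)
  s2 <- solve_bridge(pi, pit, Q)
  expect_identical(s1, s2)
})
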