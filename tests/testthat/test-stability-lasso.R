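# Exact Lasso solver, EDPP safe screening, undersampled stability selection.

soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

rand_problem <- function(m, n, seed, sparse = 5) {
  withr::with_seed(seed, {
    A <- scale(matrix(rnorm(m * n), m, n))
    A <- A / sqrt(m - 1)               # unit-norm-ish standardized columns
    colnames(A) <- paste0("f", seq_len(n))
    beta <- numeric(n)
    beta[sample(n, sparse)] <- rnorm(sparse, 0, 2)
    y <- as.vector(A %*% beta + rnorm(m, 0, 0.5))
    list(A = A, y = y - mean(y))
  })
}

test_that("lambda_max marks the edge of the zero solution", {
  p <- rand_problem(30, 50, seed = 1)
  lmax <- lambdaMax(p$A, p$y)
  expect_equal(lmax, max(abs(crossprod(p$A, p$y))))
  s <- solveLasso(p$A, p$y, 1.01 * lmax)
  expect_true(all(s$x == 0))
  ## a single column with a' y = 3
  a <- matrix(c(3, 0, 0), 3, 1, dimnames = list(NULL, "a"))
  y1 <- c(1, 0, 0)
  expect_equal(lambdaMax(a, y1), 3)
  ## y orthogonal to all columns
  A2 <- matrix(c(0, 1, 0, 0, 0, 1), 3, 2)
  expect_equal(lambdaMax(A2, c(1, 0, 0)), 0)
  expect_error(lambdaMax(p$A, rep(0, 30)), "zero")
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  withr::with_seed(3, {
    Q <- qr.Q(qr(matrix(rnorm(60 * 20), 60, 20)))
    colnames(Q) <- paste0("q", 1:20)
    y <- rnorm(60)
  })
  z <- as.vector(crossprod(Q, y))
  for (lam in c(0.1, 0.5, 1.2)) {
    s <- solveLasso(Q, y, lam, tol = 1e-12)
    expect_equal(unname(s$x), soft(z, lam), tolerance = 1e-10)
  }
})

test_that("solutions satisfy KKT, match the stored objective and are local minima", {
  p <- rand_problem(40, 80, seed = 5)
  lam <- 0.15 * lambdaMax(p$A, p$y)
  s <- solveLasso(p$A, p$y, lam)
  expect_lte(s$kkt, 1e-8)
  recomputed <- 0.5 * sum((p$A %*% s$x - p$y)^2) + lam * sum(abs(s$x))
  expect_equal(s$objective, recomputed, tolerance = 1e-10)
  ## 1000 random perturbations never beat the solution
  withr::with_seed(7, {
    worse <- replicate(1000, {
      xp <- s$x + rnorm(length(s$x), 0, 0.01)
      0.5 * sum((p$A %*% xp - p$y)^2) + lam * sum(abs(xp))
    })
  })
  expect_true(all(worse >= s$objective - 1e-12))
})

test_that("EDPP screening is safe and loses nothing", {
  for (seed in 1:20) {
    p <- rand_problem(20, 60, seed = 100 + seed)
    lmax <- lambdaMax(p$A, p$y)
    fracs <- seq(0.9, 0.1, length.out = 8)
    prev_lam <- lmax
    prev_x <- numeric(ncol(p$A))
    for (f in fracs) {
      lam <- f * lmax
      rej <- edppScreen(p$A, p$y, lambda0 = prev_lam, lambda1 = lam,
                        x0 = prev_x)
      oracle <- solveLasso(p$A, p$y, lam, tol = 1e-10)
      ## safety: no rejected feature is active in the oracle solution
      expect_false(any(rej & oracle$active))
      ## equivalence: solving the screened problem reproduces the oracle
      x <- numeric(ncol(p$A))
      if (any(!rej))
        x[!rej] <- solveLasso(p$A[, !rej, drop = FALSE], p$y, lam,
                              tol = 1e-10)$x
      expect_lt(max(abs(x - oracle$x)), 1e-8)
      prev_lam <- lam
      prev_x <- oracle$x
    }
  }
  p <- rand_problem(20, 60, seed = 3)
  expect_error(edppScreen(p$A, p$y, lambda0 = 1, lambda1 = 2), "lambda1")
})

test_that("the path solver agrees with glmnet on a shared grid", {
  skip_if_not_installed("glmnet")
  p <- rand_problem(50, 40, seed = 11)
  m <- nrow(p$A)
  lmax <- lambdaMax(p$A, p$y)
  lams <- seq(0.4, 0.1, length.out = 4) * lmax
  ours <- solveLassoPath(p$A, p$y, lams, tol = 1e-12)
  ## glmnet minimizes 1/(2m)||y - Ax||^2 + lambda||x||_1
  g <- glmnet::glmnet(p$A, p$y, lambda = lams / m, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  for (i in seq_along(lams)) {
    expect_equal(unname(ours[[i]]$x),
                 as.vector(g$beta[, i]), tolerance = 1e-5)
  }
})

test_that("balanced undersampling always equalizes the classes", {
  labels <- c(rep(1L, 10), rep(0L, 30))
  withr::with_seed(2, {
    for (r in 1:20) {
      rows <- mcicps:::balanced_undersample(labels)
      expect_length(rows, 20)
      expect_equal(sum(labels[rows] == 1), 10)
      expect_equal(sum(labels[rows] == 0), 10)
    }
  })
})

test_that("selection counts are bounded, reproducible and order-invariant", {
  withr::with_seed(4, {
    x <- matrix(rnorm(60 * 12), 60, 12)
    lab <- rep(0:1, each = 30)
    x[, 1] <- lab * 4 + rnorm(60, 0, 0.3)   # a dominating feature
    colnames(x) <- sprintf("v%02d", 1:12)
  })
  x <- scale(x)
  prof <- runStabilitySelection(x, lab, inner = 25L, outer = 4L, seed = 9)
  expect_true(all(prof$counts >= 0 & prof$counts <= prof$total_runs))
  expect_equal(prof$total_runs, 100L)
  ## the dominating feature is always selected
  expect_equal(unname(prof$counts["v01"]), prof$total_runs)
  ## deterministic given the seed
  prof2 <- runStabilitySelection(x, lab, inner = 25L, outer = 4L, seed = 9)
  expect_identical(prof$counts, prof2$counts)
  ## column order does not change a feature's count
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  prof3 <- runStabilitySelection(x[, perm], lab, inner = 25L, outer = 4L,
                                 seed = 9)
  expect_identical(prof$counts[colnames(x)[perm]], prof3$counts)
  expect_error(runStabilitySelection(x, rep(1, 60), inner = 2L, outer = 1L),
               "class")
})

test_that("injected conversion features out-rank null features", {
  meds <- vapply(1:3, function(s) {
    coh <- generateCohort(quick_cfg(seed = 700 + s, n_train = 80L,
                                    n_test = 10L))
    tr <- cohortTruth(coh)
    in1 <- which(unname(tr$subtype) == 1)
    x <- scale(modality(coh, "expr")[in1, ])
    lab <- unname(conversionLabels(coh))[in1]
    prof <- runStabilitySelection(x, lab, inner = 30L, outer = 5L,
                                  seed = s)
    inf <- tr$informative$expr_conv1
    null_f <- setdiff(colnames(x),
                      c(inf, tr$informative$expr_subtype,
                        tr$informative$expr_conv2))
    median(prof$counts[inf]) - median(prof$counts[null_f])
  }, numeric(1))
  expect_true(all(meds > 0))
})

test_that("the feature-count search finds small n for a lone signal", {
  withr::with_seed(8, {
    x <- matrix(rnorm(80 * 15), 80, 15)
    lab <- rep(0:1, each = 40)
    x[, 3] <- lab * 3 + rnorm(80, 0, 0.5)
    colnames(x) <- sprintf("g%02d", 1:15)
  })
  x <- scale(x)
  res <- chooseNFeatures(x, lab, n_grid = c(1:6, 10), cv_folds = 4,
                         cv_repeats = 2, inner = 15L, outer = 2L, seed = 5)
  expect_lte(res$n, 5)
  expect_identical(res$ranking[1], "g03")
  ## grid wider than the feature set is truncated with a warning
  expect_warning(
    chooseNFeatures(x[, 1:4], lab, n_grid = 1:10, cv_folds = 4,
                    cv_repeats = 1, inner = 5L, outer = 1L, seed = 5),
    "truncated")
})
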