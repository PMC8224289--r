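#' Smallest penalty with an all-zero Lasso solution
#'
#' For the problem `min 1/2 ||A x - y||^2 + lambda ||x||_1`,
#' `lambda_max = max_j |A_j' y|`: at or above it the zero vector satisfies
#' the KKT conditions and is the unique solution.
#'
#' @param A m x n design matrix (standardized columns).
#' @param y centered response of length m.
#' @return `lambda_max` as a single number.
#' @export
lambdaMax <- function(A, y) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  if (all(y == 0)) stop("response is identically zero", call. = FALSE)
  max(abs(crossprod(A, y)))
}

lasso_objective <- function(A, y, x, lambda) {
  r <- A %*% x - y
  0.5 * sum(r^2) + lambda * sum(abs(x))
}

## KKT residual of the Lasso: for active coordinates the stationarity gap
## |A_j'(Ax - y) + lambda sign(x_j)|, for inactive ones the dual violation
## max(0, |A_j'(y - Ax)| - lambda).
lasso_kkt <- function(A, y, x, lambda) {
  g <- as.vector(crossprod(A, A %*% x - y))
  act <- x != 0
  r_act <- if (any(act)) max(abs(g[act] + lambda * sign(x[act]))) else 0
  r_in <- if (any(!act)) max(0, max(abs(g[!act])) - lambda) else 0
  max(r_act, r_in)
}

#' Solve the Lasso by cyclic coordinate descent
#'
#' Exact solver for `min 1/2 ||A x - y||^2 + lambda ||x||_1` via cyclic
#' coordinate descent with soft-thresholding on the Gram form (compiled
#' inner loop).  Convergence is certified by the KKT residual, checked
#' independently of the solver loop; the sweep tolerance is tightened until
#' the residual falls below `tol`.
#'
#' @param A m x n design matrix.
#' @param y response of length m.
#' @param lambda penalty weight (> 0).
#' @param tol KKT residual tolerance.
#' @param max_iter maximum coordinate-descent sweeps.
#' @param x0 optional warm start.
#' @param G,c optional precomputed `crossprod(A)` and `crossprod(A, y)`.
#' @return A list of class `LassoSolution`: coefficients `x`, `objective`
#'   (which always equals the independently recomputed
#'   `1/2||Ax-y||^2 + lambda||x||_1`), `kkt` residual, logical `active`
#'   set, and sweep count.
#' @export
solveLasso <- function(A, y, lambda, tol = 1e-8, max_iter = 10000,
                       x0 = NULL, G = NULL, c = NULL) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  if (lambda <= 0) stop_field("lambda", "must be > 0")
  if (is.null(G)) G <- crossprod(A)
  if (is.null(c)) c <- as.vector(crossprod(A, y))
  n <- ncol(A)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  tol_change <- max(tol, 1e-12)
  kkt <- Inf
  for (round in 1:6) {
    fit <- lasso_cd_gram(G, c, lambda, x, tol_change, max_iter)
    x <- fit$x
    kkt <- lasso_kkt(A, y, x, lambda)
    if (kkt <= tol) break
    tol_change <- tol_change / 100
  }
  if (kkt > tol)
    stop(sprintf("lasso did not converge: KKT residual %.3g > %.3g",
                 kkt, tol), call. = FALSE)
  names(x) <- colnames(A)
  structure(list(x = x, objective = lasso_objective(A, y, x, lambda),
                 kkt = kkt, active = x != 0, lambda = lambda,
                 sweeps = fit$sweeps),
            class = "LassoSolution")
}

#' EDPP safe screening along a Lasso path
#'
#' Enhanced dual polytope projection (EDPP) rule: given the *exact* Lasso
#' solution at `lambda0` (possibly the trivial zero solution at
#' `lambda_max`), features guaranteed to have coefficient exactly zero in
#' the solution at `lambda1 < lambda0` are identified from a geometric
#' bound on the dual optimum, before any solving.  The rule is *safe*: a
#' rejected feature is never active in the true solution, so solving the
#' reduced problem reproduces the full solution.
#'
#' @param A m x n design matrix.
#' @param y response vector.
#' @param lambda0 penalty of the known solution (`x0`).
#' @param lambda1 target penalty, `0 < lambda1 < lambda0`.
#' @param x0 coefficient vector solving the problem at `lambda0`
#'   (default: the zero vector, valid when `lambda0 >= lambdaMax(A, y)`).
#' @return Logical vector of length n; `TRUE` marks features rejected
#'   (provably zero at `lambda1`).
#' @export
edppScreen <- function(A, y, lambda0, lambda1, x0 = NULL) {
  if (lambda1 >= lambda0) stop_field("lambda1", "must be < lambda0")
  if (lambda1 <= 0) stop_field("lambda1", "must be > 0")
  n <- ncol(A)
  if (is.null(x0)) x0 <- numeric(n)
  lmax <- lambdaMax(A, y)
  theta0 <- (y - A %*% x0) / lambda0                 # dual optimum at lambda0
  if (lambda0 >= lmax * (1 - 1e-12)) {
    j <- which.max(abs(crossprod(A, y)))
    v1 <- as.vector(sign(sum(A[, j] * y))) * A[, j]
  } else {
    v1 <- y / lambda0 - theta0
  }
  v2 <- y / lambda1 - theta0
  nv1 <- sum(v1^2)
  v2p <- if (nv1 > 0) v2 - as.numeric(crossprod(v1, v2) / nv1) * v1 else v2
  center <- theta0 + 0.5 * v2p
  radius_part <- 0.5 * sqrt(sum(v2p^2))
  lhs <- abs(as.vector(crossprod(A, center)))
  col_norms <- sqrt(colSums(A^2))
  rejected <- lhs < 1 - radius_part * col_norms
  names(rejected) <- colnames(A)
  rejected
}

#' Solve a decreasing lambda path with EDPP screening and warm starts
#'
#' @param A,y design and response.
#' @param lambdas decreasing vector of penalties (all below
#'   `lambdaMax(A, y)` is typical; larger values simply give zero
#'   solutions).
#' @param tol,max_iter passed to [solveLasso()].
#' @param screen apply [edppScreen()] sequentially along the path
#'   (default) or solve each problem in full.
#' @return List of `LassoSolution`, one per lambda.
#' @export
solveLassoPath <- function(A, y, lambdas, tol = 1e-8, max_iter = 10000,
                           screen = TRUE) {
  stopifnot(all(diff(lambdas) < 0))
  lmax <- lambdaMax(A, y)
  n <- ncol(A)
  out <- vector("list", length(lambdas))
  prev_lambda <- lmax
  prev_x <- numeric(n)
  G_full <- crossprod(A)
  c_full <- as.vector(crossprod(A, y))
  for (i in seq_along(lambdas)) {
    lam <- lambdas[i]
    if (lam >= lmax) {
      x <- stats::setNames(numeric(n), colnames(A))
      out[[i]] <- structure(list(x = x, objective = lasso_objective(A, y, x, lam),
                                 kkt = 0, active = x != 0, lambda = lam,
                                 sweeps = 0L), class = "LassoSolution")
      prev_lambda <- lam; prev_x <- x
      next
    }
    keep <- if (screen) {
      !edppScreen(A, y, lambda0 = prev_lambda, lambda1 = lam, x0 = prev_x)
    } else rep(TRUE, n)
    x <- numeric(n)
    if (any(keep)) {
      sol_sub <- solveLasso(A[, keep, drop = FALSE], y, lam, tol = tol,
                            max_iter = max_iter, x0 = prev_x[keep],
                            G = G_full[keep, keep, drop = FALSE],
                            c = c_full[keep])
      x[keep] <- sol_sub$x
    }
    names(x) <- colnames(A)
    kkt <- lasso_kkt(A, y, x, lam)
    out[[i]] <- structure(list(x = x, objective = lasso_objective(A, y, x, lam),
                               kkt = kkt, active = x != 0, lambda = lam,
                               sweeps = if (any(keep)) sol_sub$sweeps else 0L),
                          class = "LassoSolution")
    prev_lambda <- lam
    prev_x <- x
  }
  out
}

#' Repeated undersampled Lasso stability selection
#'
#' Ranks a modality's features by how often the Lasso selects them across
#' many class-balanced subproblems.  Each inner run draws a balanced
#' undersample (all minority-class samples plus an equal-size random draw
#' of the majority class), centers the 0/1 response, draws one penalty
#' fraction `f` uniformly from `lambda_fracs` and solves the Lasso at
#' `lambda = f * lambda_max` of the subproblem (with EDPP screening);
#' features with nonzero coefficients are counted.  Counts accumulate over
#' all `outer * inner` runs, the outer layer re-seeding the undersampler.
#'
#' @param x standardized samples x features matrix.
#' @param labels binary 0/1 conversion labels (1 = P-MCI).
#' @param lambda_fracs penalty fractions of `lambda_max`; default 10 evenly
#'   spaced values spanning the 0.05-0.5 range.
#' @param inner,outer repetition counts (headline protocol: 1000 x 50;
#'   reduce for desk-scale runs).
#' @param seed integer seed; counts are reproducible.
#' @param tol Lasso KKT tolerance.
#' @return A list of class `SelectionProfile`: integer `counts` per
#'   feature, `mean_abs_coef` across runs (tie-break key), `total_runs`,
#'   the grid and the repetition counts.
#' @export
runStabilitySelection <- function(x, labels,
                                  lambda_fracs = seq(0.05, 0.5, length.out = 10),
                                  inner = 1000L, outer = 50L, seed = 1L,
                                  tol = 1e-6) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  labels <- as.integer(labels)
  if (min(sum(labels == 1L), sum(labels == 0L)) < 2)
    stop("each class needs at least 2 samples", call. = FALSE)
  p <- ncol(x)
  counts <- integer(p)
  abs_sum <- numeric(p)
  for (o in seq_len(outer)) {
    with_seed(child_seed(seed, "stability", o), {
      for (i in seq_len(inner)) {
        rows <- balanced_undersample(labels)
        A <- x[rows, , drop = FALSE]
        yy <- labels[rows]
        y <- yy - mean(yy)
        lmax <- max(abs(crossprod(A, y)))
        if (lmax <= 0) next
        f <- lambda_fracs[sample.int(length(lambda_fracs), 1)]
        lam <- f * lmax
        keep <- !edppScreen(A, y, lambda0 = lmax, lambda1 = lam)
        if (!any(keep)) next
        sol <- solveLasso(A[, keep, drop = FALSE], y, lam, tol = tol)
        sel <- which(keep)[sol$active]
        counts[sel] <- counts[sel] + 1L
        abs_sum[sel] <- abs_sum[sel] + abs(sol$x[sol$active])
      }
    })
  }
  structure(list(counts = stats::setNames(counts, colnames(x)),
                 mean_abs_coef = stats::setNames(
                   ifelse(counts > 0, abs_sum / pmax(counts, 1), 0),
                   colnames(x)),
                 total_runs = as.integer(inner) * as.integer(outer),
                 inner = as.integer(inner), outer = as.integer(outer),
                 lambda_fracs = lambda_fracs, seed = as.integer(seed)),
            class = "SelectionProfile")
}

## One class-balanced undersample: every minority-class sample plus an
## equal-size random draw of the majority class (row indices).
balanced_undersample <- function(labels) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  c(minority, sample(majority, length(minority)))
}

#' Rank features from a selection profile
#'
#' Descending selection count; ties broken by larger mean absolute
#' coefficient across runs, then lexicographic feature id — a stable,
#' deterministic ordering.
#'
#' @param profile a `SelectionProfile`.
#' @return Character vector of feature ids, best first, with the counts as
#'   the `counts` attribute.
#' @export
rankFeatures <- function(profile) {
  stopifnot(inherits(profile, "SelectionProfile"))
  ids <- names(profile$counts)
  ord <- order(-profile$counts, -profile$mean_abs_coef, ids)
  structure(ids[ord], counts = profile$counts[ord])
}

#' Choose the number of features per modality by repeated CV
#'
#' For `n` in `n_grid`, the top-`n` features of the modality's stability
#' ranking are fed to a single-kernel VBpMKL classifier and scored by mean
#' AUC over repeated stratified five-fold cross-validation; the ranking is
#' re-computed inside every training fold so no test-fold information
#' reaches the selection.  Ties go to the smallest `n`.
#'
#' @param x standardized samples x features matrix (one modality).
#' @param labels binary conversion labels.
#' @param n_grid candidate counts (headline protocol 1..100); truncated
#'   with a warning if it exceeds the available features.
#' @param cv_folds,cv_repeats cross-validation shape.
#' @param inner,outer stability-selection repetitions inside each fold.
#' @param lambda_fracs passed to [runStabilitySelection()].
#' @param seed integer seed.
#' @return A list: chosen `n`, the mean CV `auc` per grid value, and the
#'   full-data ranking.
#' @export
chooseNFeatures <- function(x, labels, n_grid = 1:100, cv_folds = 5,
                            cv_repeats = 50, inner = 1000L, outer = 50L,
                            lambda_fracs = seq(0.05, 0.5, length.out = 10),
                            seed = 1L) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (max(n_grid) > ncol(x)) {
    warning(sprintf("n grid truncated to the %d available features", ncol(x)),
            call. = FALSE)
    n_grid <- n_grid[n_grid <= ncol(x)]
  }
  labels <- as.integer(labels)
  aucs <- matrix(NA_real_, cv_repeats * cv_folds, length(n_grid))
  row_i <- 0L
  for (r in seq_len(cv_repeats)) {
    folds <- make_folds(labels, cv_folds, child_seed(seed, "choose_n", r))
    for (f in seq_len(cv_folds)) {
      row_i <- row_i + 1L
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2)
        next
      prof <- runStabilitySelection(x[tr, , drop = FALSE], labels[tr],
                                    lambda_fracs = lambda_fracs,
                                    inner = inner, outer = outer,
                                    seed = child_seed(seed, "choose_sel", row_i))
      ranked <- rankFeatures(prof)
      for (gi in seq_along(n_grid)) {
        feats <- ranked[seq_len(n_grid[gi])]
        Xtr <- x[tr, feats, drop = FALSE]
        Xte <- x[te, feats, drop = FALSE]
        theta <- median_heuristic(Xtr)
        Ktr <- computeGram(Xtr, spec = kernelSpec("gaussian", theta))
        Kte <- computeGram(Xtr, Xte, spec = kernelSpec("gaussian", theta))
        fit <- fitVbpmkl(list(Ktr), labels[tr],
                         seed = child_seed(seed, "choose_fit", row_i))
        pr <- predictProba(fit, list(Kte))
        aucs[row_i, gi] <- auc_rank(pr$probabilities[, "1"], labels[te])
      }
    }
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  best <- n_grid[which.max(mean_auc)]   # which.max takes the first (smallest n)
  list(n = best, auc = stats::setNames(mean_auc, n_grid),
       ranking = rankFeatures(
         runStabilitySelection(x, labels, lambda_fracs = lambda_fracs,
                               inner = inner, outer = outer,
                               seed = child_seed(seed, "choose_full"))))
}

## Stratified fold ids (1..k): balanced within each label stratum, with the
## per-stratum remainders rotated across folds so total fold sizes differ by
## at most one (125 samples / 5 folds gives five folds of exactly 25).
make_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    offset <- 0L
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
    fold
  })
}
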