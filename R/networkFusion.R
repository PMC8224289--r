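#' Build a patient similarity network from one modality
#'
#' Scaled exponential similarity kernel: `W(i,j) = exp(-d^2(i,j)/(mu*eps))`
#' with the local scale `eps = (mean_K(i) + mean_K(j) + d(i,j)) / 3`, where
#' `mean_K(i)` is sample i's mean distance to its `K` nearest neighbours.
#' Distances are Euclidean by default; for additively coded genotypes a
#' chi-squared distance on 0/1/2 counts is available.
#'
#' @param x standardized samples x features matrix.
#' @param K neighbourhood size for the local scale (`K < N`).
#' @param mu bandwidth scale factor (typical range 0.3-0.8).
#' @param distance `"euclidean"` (default) or `"chisq"`.
#' @return An [AffinityNetwork-class].
#' @export
buildAffinity <- function(x, K = 20, mu = 0.5, distance = c("euclidean", "chisq")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (K >= n) stop_field("K", "must be smaller than the number of samples")
  d <- if (distance == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    ## chi-squared distance between nonnegative count profiles
    dd <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- x[i, ] + x[j, ]
      ok <- s > 0
      dd[i, j] <- dd[j, i] <- sqrt(sum((x[i, ok] - x[j, ok])^2 / s[ok]))
    }
    dd
  }
  ## mean distance to the K nearest neighbours (self excluded)
  sorted <- apply(d, 1, sort)           # columns are sorted rows of d
  mean_k <- colMeans(sorted[2:(K + 1), , drop = FALSE])
  eps <- (outer(mean_k, mean_k, "+") + d) / 3
  eps[eps <= .Machine$double.eps] <- .Machine$double.eps
  W <- exp(-d^2 / (mu * eps))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(x), rownames(x))
  new("AffinityNetwork", W = W, K = as.integer(K), mu = mu)
}

## Full-kernel transition form: off-diagonal mass halved and spread by row,
## diagonal fixed at 1/2 (keeps the update numerically stable).
snf_normalize <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

## Sparse KNN kernel: keep each row's K largest off-diagonal similarities,
## row-normalized.
snf_knn_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb]
  }
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

#' Similarity network fusion (SNF)
#'
#' Cross-diffusion of two or more per-modality patient similarity networks
#' into a single fused network.  Each network's full kernel is normalized
#' to a transition form `P_v`, a sparse K-nearest-neighbour kernel `S_v` is
#' derived, and for `T` iterations each layer is updated as
#' `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)`, symmetrized and
#' renormalized; the fused network is the average of the final layers.
#' Complementary similarity supported by several layers is reinforced while
#' modality-specific noise decays.
#'
#' @param affinities list of [AffinityNetwork-class] (or plain matrices) on
#'   the same ordered sample set.
#' @param K neighbourhood size of the sparse kernel.
#' @param T number of diffusion iterations.
#' @return A [FusedNetwork-class] with per-iteration mean change norms as a
#'   convergence diagnostic.
#' @export
snfFuse <- function(affinities, K = 20, T = 20) {
  Ws <- lapply(affinities, function(a) if (is(a, "AffinityNetwork")) a@W else a)
  if (length(Ws) < 2) stop("need at least two networks to fuse", call. = FALSE)
  n <- nrow(Ws[[1]])
  ids <- rownames(Ws[[1]])
  for (W in Ws) {
    if (nrow(W) != n || !identical(rownames(W), ids))
      stop("affinity networks disagree on the sample set", call. = FALSE)
  }
  K <- min(K, n - 1)
  P <- lapply(Ws, snf_normalize)
  S <- lapply(Ws, snf_knn_kernel, K = K)
  m <- length(P)
  deltas <- numeric(T)
  for (it in seq_len(T)) {
    newP <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      newP[[v]] <- snf_normalize(Q)
    }
    deltas[it] <- mean(vapply(seq_len(m), function(v)
      norm(newP[[v]] - P[[v]], "F"), numeric(1)))
    P <- newP
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  new("FusedNetwork", W = fused, iterations = as.integer(T), deltas = deltas)
}

#' RatioCut spectral clustering of a fused network
#'
#' Spectral relaxation of the RatioCut objective: eigenvectors of the `C`
#' smallest eigenvalues of the unnormalized Laplacian `L = D - W`, followed
#' by k-means on the embedded rows (multiple restarts, fixed seed).  If the
#' graph has more connected components than `C` a warning is raised and the
#' components themselves are returned as clusters.
#'
#' @param net a [FusedNetwork-class], [AffinityNetwork-class] or similarity
#'   matrix.
#' @param C number of clusters (default 2; two MCI subtypes).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return A [SubtypeAssignment-class] with `source = "clustered"`, one-hot
#'   membership scores and, as attribute `eigengap`, the Laplacian spectrum
#'   gap diagnostic.
#' @export
spectralCluster <- function(net, C = 2, seed = 1L, nstart = 25) {
  W <- if (is(net, "FusedNetwork") || is(net, "AffinityNetwork")) net@W else net
  if (C < 2) stop_field("C", "must be at least 2")
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  e <- eigen(L, symmetric = TRUE)
  evals <- rev(e$values)                       # ascending
  n_comp <- sum(evals < 1e-10 * max(1, max(abs(evals))))
  if (n_comp > C) {
    warning(sprintf("graph has %d connected components > C = %d; returning components",
                    n_comp, C), call. = FALSE)
    comp <- connected_components(W)
    return(assignment_from_labels(comp, rownames(W), "clustered"))
  }
  U <- e$vectors[, n:(n - C + 1), drop = FALSE]  # C smallest eigenvalues
  km <- with_seed(seed, stats::kmeans(U, centers = C, nstart = nstart,
                                      iter.max = 100))
  out <- assignment_from_labels(km$cluster, rownames(W), "clustered")
  attr(out, "eigengap") <- diff(evals)[C]
  out
}

connected_components <- function(W, tol = 1e-12) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(W[i, ] > tol & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

assignment_from_labels <- function(labels, ids, source) {
  C <- max(labels)
  scores <- matrix(0, length(labels), C)
  scores[cbind(seq_along(labels), labels)] <- 1
  rownames(scores) <- ids
  ## `Class =` spelled out: a named `C` argument would otherwise partially
  ## match new()'s Class parameter
  new(Class = "SubtypeAssignment",
      labels = stats::setNames(as.integer(labels), ids),
      C = as.integer(C), source = source, scores = scores)
}

#' Semi-supervised label propagation of subtype labels
#'
#' Assigns subtypes to new patients by diffusing the training subtype
#' labels over a fused similarity network built jointly on training and new
#' samples (genotype + expression layers by default).  The clamped
#' iteration `F <- alpha * P %*% F + (1 - alpha) * Y`, with training rows
#' reset to their one-hot labels after every step, is run until the largest
#' row change falls below `tol`; each new sample takes the subtype with the
#' highest propagated score.
#'
#' @param train_data named list of standardized training matrices (one per
#'   modality used for subtyping).
#' @param train_labels a [SubtypeAssignment-class] or named integer vector
#'   of training subtypes.
#' @param new_data named list of standardized matrices for the new samples
#'   (same modalities and feature columns).
#' @param K,mu affinity parameters (see [buildAffinity()]).
#' @param T SNF iterations for the joint network.
#' @param alpha clamping weight in (0, 1); high alpha trusts the graph.
#' @param tol,max_iter convergence control of the propagation loop.
#' @return A [SubtypeAssignment-class] for the new samples
#'   (`source = "propagated"`); scores rows sum to 1.
#' @export
labelPropagate <- function(train_data, train_labels, new_data,
                           K = 20, mu = 0.5, T = 20,
                           alpha = 0.99, tol = 1e-6, max_iter = 1000) {
  labs <- if (is(train_labels, "SubtypeAssignment"))
    train_labels@labels else as.integer(train_labels)
  mods <- names(train_data)
  if (!identical(sort(mods), sort(names(new_data))))
    stop("train and new data must share modalities", call. = FALSE)
  n_tr <- nrow(train_data[[1]])
  n_new <- nrow(new_data[[1]])
  if (length(labs) != n_tr)
    stop("one training label per training sample required", call. = FALSE)
  joint <- lapply(mods, function(tag) {
    if (!identical(colnames(train_data[[tag]]), colnames(new_data[[tag]])))
      stop(sprintf("feature columns of modality '%s' differ", tag),
           call. = FALSE)
    rbind(train_data[[tag]], new_data[[tag]])
  })
  ids <- c(rownames(train_data[[1]]), rownames(new_data[[1]]))
  Kc <- min(K, n_tr + n_new - 1)
  aff <- lapply(joint, function(x) {
    rownames(x) <- ids
    buildAffinity(x, K = Kc, mu = mu)
  })
  fused <- if (length(aff) >= 2) snfFuse(aff, K = Kc, T = T)@W
           else networkMatrix(aff[[1]])
  P <- fused / rowSums(fused)
  C <- max(labs)
  Y <- matrix(0, n_tr + n_new, C)
  Y[cbind(seq_len(n_tr), labs)] <- 1
  Fm <- Y
  converged <- FALSE
  delta <- NA_real_
  for (it in seq_len(max_iter)) {
    Fnew <- alpha * (P %*% Fm) + (1 - alpha) * Y
    Fnew[seq_len(n_tr), ] <- Y[seq_len(n_tr), ]   # clamp the labelled rows
    delta <- max(abs(Fnew - Fm))
    Fm <- Fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("label propagation did not converge in %d iterations (last change %.3g)",
                 max_iter, delta), call. = FALSE)
  Fnew_new <- Fm[n_tr + seq_len(n_new), , drop = FALSE]
  rs <- rowSums(Fnew_new)
  rs[rs == 0] <- 1
  scores <- Fnew_new / rs
  labels <- max.col(scores, ties.method = "first")
  rownames(scores) <- rownames(new_data[[1]])
  new(Class = "SubtypeAssignment",
      labels = stats::setNames(as.integer(labels), rownames(scores)),
      C = as.integer(C), source = "propagated", scores = scores)
}
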