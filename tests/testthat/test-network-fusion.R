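# Affinity construction, SNF, spectral clustering, label propagation.

block_affinity <- function(n1, n2, w_in = 1, w_out = 0) {
  n <- n1 + n2
  W <- matrix(w_out, n, n)
  W[1:n1, 1:n1] <- w_in
  W[(n1 + 1):n, (n1 + 1):n] <- w_in
  diag(W) <- 1
  dimnames(W) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  W
}

test_that("affinity kernel has the expected local structure", {
  bl <- make_blobs(n_per = 15, C = 2, sep = 6, seed = 2)
  aff <- buildAffinity(bl$x, K = 5, mu = 0.5)
  W <- networkMatrix(aff)
  expect_true(isSymmetric(W, tol = 1e-12))
  expect_true(all(W > 0))
  ## within-blob similarity dominates between-blob similarity
  in1 <- bl$y == 1
  expect_gt(mean(W[in1, in1][upper.tri(W[in1, in1])]),
            mean(W[in1, !in1]))
  ## duplicated samples: zero distance gives the off-diagonal row maximum
  xd <- rbind(bl$x, dup = bl$x[1, ])
  rownames(xd) <- c(rownames(bl$x), "dup")
  Wd <- networkMatrix(buildAffinity(xd, K = 5, mu = 0.5))
  i <- nrow(Wd)
  off <- Wd[i, -i]
  expect_equal(which.max(off), 1L, ignore_attr = TRUE)
  expect_error(buildAffinity(bl$x, K = 40), "K")
})

test_that("SNF preserves exact block structure and returns a valid network", {
  W <- block_affinity(10, 10)
  fused <- snfFuse(list(W, W, W), K = 5, T = 10)
  FW <- networkMatrix(fused)
  expect_true(isSymmetric(FW, tol = 1e-12))
  expect_true(all(FW >= 0))
  ## the two-block cut survives fusion of identical block-diagonal inputs
  cl <- subtypeLabels(spectralCluster(fused, C = 2, seed = 1))
  truth <- rep(1:2, each = 10)
  expect_equal(adjustedRandIndex(cl, truth), 1)
  expect_error(snfFuse(list(W), K = 5), "at least two")
})

test_that("SNF is permutation-equivariant", {
  bl <- make_blobs(n_per = 12, C = 2, sep = 3, seed = 7)
  a1 <- buildAffinity(bl$x, K = 6, mu = 0.5)
  a2 <- buildAffinity(bl$x + matrix(rnorm(length(bl$x), 0, 0.1),
                                    nrow(bl$x)), K = 6, mu = 0.5)
  f <- networkMatrix(snfFuse(list(a1, a2), K = 6, T = 8))
  perm <- withr::with_seed(1, sample(nrow(bl$x)))
  ## permuting the input networks permutes the fused network accordingly
  W1p <- networkMatrix(a1)[perm, perm]
  W2p <- networkMatrix(a2)[perm, perm]
  fp <- networkMatrix(snfFuse(list(W1p, W2p), K = 6, T = 8))
  expect_equal(fp, f[perm, perm], tolerance = 1e-12)
})

test_that("fusion diagnostics settle after a burn-in", {
  coh <- generateCohort(quick_cfg(seed = 13))
  z1 <- scale(modality(coh, "expr"))
  z2 <- scale(apply(modality(coh, "snp"), 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE); v
  }))
  rownames(z2) <- rownames(z1)
  f <- snfFuse(list(buildAffinity(z1, K = 10), buildAffinity(z2, K = 10)),
               K = 10, T = 20)
  d <- f@deltas
  expect_lt(d[length(d)], d[3])
})

test_that("spectral clustering: exact blocks, relabeling, components", {
  W <- block_affinity(8, 12)
  asg <- spectralCluster(W, C = 2, seed = 3)
  truth <- rep(1:2, times = c(8, 12))
  expect_equal(adjustedRandIndex(subtypeLabels(asg), truth), 1)
  ## one-hot scores
  expect_true(all(rowSums(subtypeScores(asg)) == 1))
  ## ARI invariant under label permutation
  expect_equal(adjustedRandIndex(3 - subtypeLabels(asg), truth), 1)
  ## a graph with 3 components but C = 2: components become clusters
  W3 <- matrix(0, 9, 9)
  for (b in 0:2) W3[b * 3 + 1:3, b * 3 + 1:3] <- 1
  dimnames(W3) <- list(letters[1:9], letters[1:9])
  expect_warning(asg3 <- spectralCluster(W3, C = 2, seed = 1), "components")
  expect_equal(adjustedRandIndex(subtypeLabels(asg3), rep(1:3, each = 3)), 1)
})

test_that("single-network clustering equals clustering M fused copies", {
  bl <- make_blobs(n_per = 15, C = 2, sep = 5, seed = 4)
  a <- buildAffinity(bl$x, K = 6, mu = 0.5)
  direct <- subtypeLabels(spectralCluster(a@W, C = 2, seed = 9))
  fused <- subtypeLabels(spectralCluster(snfFuse(list(a, a, a), K = 6, T = 10),
                                         C = 2, seed = 9))
  expect_equal(adjustedRandIndex(direct, fused), 1)
})

test_that("label propagation inherits and normalizes", {
  bl <- make_blobs(n_per = 15, C = 2, sep = 5, seed = 6)
  labs <- bl$y
  ## new data: exact duplicates of three training samples + a few noisy ones
  dup_idx <- c(1, 16, 30)
  newx <- rbind(bl$x[dup_idx, ], bl$x[c(2, 17), ] + 0.05)
  rownames(newx) <- sprintf("new%02d", seq_len(nrow(newx)))
  res <- labelPropagate(list(m = bl$x), labs, list(m = newx),
                        K = 6, mu = 0.5, T = 8)
  expect_equal(unname(subtypeLabels(res)[1:3]), labs[dup_idx])
  expect_equal(rowSums(subtypeScores(res)), rep(1, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_s4_class(res, "SubtypeAssignment")
  expect_identical(res@source, "propagated")
})

test_that("fused subtyping and propagation recover synthetic truth", {
  ok_cluster <- ok_prop <- numeric(0)
  for (s in 1:5) {
    coh <- generateCohort(syntheticConfig(n_train = 120L, n_test = 60L,
                                          seed = 500 + s))
    tr <- cohortSubset(coh, 1:120)
    te <- cohortSubset(coh, 121:180)
    prep <- mcicps:::prepare_train(tr, runConfig())
    aff <- list(buildAffinity(prep$z$snp, K = 20, mu = 0.5),
                buildAffinity(prep$z$expr, K = 20, mu = 0.5))
    fused <- snfFuse(aff, K = 20, T = 20)
    asg <- spectralCluster(fused, C = 2, seed = 1)
    ok_cluster <- c(ok_cluster,
                    adjustedRandIndex(subtypeLabels(asg),
                                      unname(subtypeTruth(tr))))
    z_new <- mcicps:::prepare_new(prep$preprocess, te)
    prop <- labelPropagate(prep$z[c("snp", "expr")], asg,
                           z_new[c("snp", "expr")], K = 20, mu = 0.5, T = 20)
    mapped <- map_clusters(subtypeLabels(asg), unname(subtypeTruth(tr)))
    key <- vapply(1:2, function(cl) {
      mapped[match(cl, subtypeLabels(asg))]
    }, integer(1))
    pred <- key[subtypeLabels(prop)]
    ok_prop <- c(ok_prop, mean(pred == unname(subtypeTruth(te))))
  }
  expect_gt(mean(ok_cluster), 0.9)
  expect_gt(mean(ok_prop), 0.9)
})
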