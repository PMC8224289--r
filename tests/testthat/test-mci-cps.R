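# Orchestration: evaluation metrics, end-to-end training/prediction,
# cross-validation and Gini importance.

test_that("confusion arithmetic reproduces the reference metric triple", {
  rep_ <- confusionReport(tp = 39, fn = 9, tn = 60, fp = 17)
  expect_equal(rep_$accuracy, 79.20, tolerance = 1e-10)
  expect_equal(rep_$sensitivity, 81.25, tolerance = 1e-10)
  expect_equal(rep_$specificity, 77.92, tolerance = 0.005)
  expect_equal(rep_$n, 125)
  expect_equal(sum(rep_$confusion), rep_$n)
})

test_that("AUC behaves at the extremes and under ties", {
  lab <- c(0, 0, 0, 1, 1)
  expect_equal(evaluateScores(c(0.1, 0.2, 0.3, 0.8, 0.9), lab)$auc, 1)
  expect_equal(evaluateScores(c(0.9, 0.8, 0.7, 0.2, 0.1), lab)$auc, 0)
  expect_equal(evaluateScores(rep(0.5, 5), lab)$auc, 0.5)
  expect_error(evaluateScores(1:5 / 10, rep(1, 5)), "one class")
})

test_that("rank AUC equals the trapezoidal ROC integral", {
  withr::with_seed(11, {
    for (r in 1:20) {
      n <- sample(20:80, 1)
      sc <- round(runif(n), sample(c(1, 2, 6), 1))  # forces some ties
      lab <- rbinom(n, 1, 0.4)
      if (length(unique(lab)) < 2) next
      rep_ <- evaluateScores(sc, lab)
      expect_lt(abs(rep_$auc - rep_$roc_auc), 1e-12)
    }
  })
})

test_that("training builds one bundle per subtype with three kernels each", {
  coh <- generateCohort(quick_cfg(seed = 51))
  tr <- cohortSubset(coh, 1:60)
  cfg <- fast_runconfig()
  m <- trainMciCps(tr, cfg, seed = 4)
  expect_s4_class(m, "CPSModel")
  expect_length(m@bundles, 2)
  for (b in m@bundles) {
    expect_length(b$specs, 3)
    expect_named(b$features, c("snp", "expr", "roi"))
    expect_equal(sum(b$model@beta), 1)
  }
  raw <- trainRawClassifier(tr, cfg, seed = 4)
  expect_length(raw@bundles, 1)
  expect_null(raw@subtyping)
})

test_that("selected features are enriched for the subtype's conversion set", {
  pvals <- c()
  for (s in 1:2) {
    coh <- generateCohort(quick_cfg(seed = 60 + s, n_train = 100L,
                                    conversion_effect = 1.5))
    tr <- cohortSubset(coh, 1:100)
    m <- trainMciCps(tr, fast_runconfig(n_features = 5L), seed = s)
    truth <- cohortTruth(tr)
    asg <- m@subtyping$assignment
    mapped <- map_clusters(subtypeLabels(asg), unname(subtypeTruth(tr)))
    for (b in seq_along(m@bundles)) {
      true_sub <- mapped[match(b, subtypeLabels(asg))]
      inf <- truth$informative[[paste0("expr_conv", true_sub)]]
      sel <- m@bundles[[b]]$features$expr
      hit <- length(intersect(sel, inf))
      p <- phyper(hit - 1, length(inf),
                  ncol(modality(tr, "expr")) - length(inf),
                  length(sel), lower.tail = FALSE)
      pvals <- c(pvals, p)
    }
  }
  expect_true(all(pvals < 0.01))
})

test_that("prediction routes samples and returns proper distributions", {
  coh <- generateCohort(quick_cfg(seed = 53))
  tr <- cohortSubset(coh, 1:60)
  te <- cohortSubset(coh, 61:100)
  m <- trainMciCps(tr, fast_runconfig(), seed = 6)
  pr <- predictMciCps(m, te)
  P <- pr$distribution$probabilities
  expect_equal(rownames(P), sampleIds(te))
  expect_true(all(P >= 0 & P <= 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-8)
  ## self-consistency: training samples propagate back to their own cluster
  self <- predictMciCps(m, tr)
  agree <- mean(subtypeLabels(self$assignment) ==
                subtypeLabels(m@subtyping$assignment))
  expect_gte(agree, 0.95)
  ## schema error on missing SNP columns
  te_bad <- te
  te_bad@modalities$snp <- te_bad@modalities$snp[, -(1:5)]
  expect_error(predictMciCps(m, te_bad), "SNP column")
})

test_that("own-subtype bundles beat swapped bundles on routed samples", {
  diffs <- vapply(1:3, function(s) {
    coh <- generateCohort(syntheticConfig(seed = 900 + s))
    tr <- cohortSubset(coh, 1:150)
    te <- cohortSubset(coh, 151:250)
    m <- trainMciCps(tr, fast_runconfig(), seed = s)
    pr <- predictMciCps(m, te)
    lab <- unname(conversionLabels(te))
    own <- evaluateScores(pr$distribution$probabilities[, "1"], lab)$auc
    ## swap the two bundles and re-route
    m2 <- m
    m2@bundles <- m@bundles[c(2, 1)]
    pr2 <- predictMciCps(m2, te)
    swapped <- evaluateScores(pr2$distribution$probabilities[, "1"], lab)$auc
    own - swapped
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  lab125 <- rep(c(0L, 1L), times = c(77, 48))
  folds <- mcicps:::make_folds(lab125, 5, seed = 3)
  expect_equal(as.vector(table(folds)), rep(25L, 5))
  for (f in 1:5)
    expect_lte(abs(sum(lab125[folds == f]) - 48 / 5), 1)

  coh <- generateCohort(quick_cfg(seed = 55, n_train = 70L, n_test = 10L))
  sub <- cohortSubset(coh, 1:70)
  cfg <- fast_runconfig(selection = list(inner = 10L, outer = 2L))
  r1 <- crossValidate(sub, "raw", cfg, folds = 5, seed = 8)
  r2 <- crossValidate(sub, "raw", cfg, folds = 5, seed = 8)
  expect_identical(r1$auc, r2$auc)
  expect_identical(attr(r1, "scores"), attr(r2, "scores"))
  expect_error(crossValidate(cohortSubset(sub, 1:12), "raw", cfg,
                             folds = 10), "folds")
})

test_that("cross-validated AUC is near chance on a null cohort", {
  aucs <- vapply(1:3, function(s) {
    coh <- generateCohort(quick_cfg(seed = 70 + s, n_train = 60L,
                                    n_test = 10L,
                                    conversion_effect = 0))
    crossValidate(cohortSubset(coh, 1:60), "raw",
                  fast_runconfig(selection = list(inner = 10L, outer = 2L)),
                  folds = 5, seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("Gini importance singles out separating features", {
  withr::with_seed(12, {
    x <- matrix(rnorm(100 * 8), 100, 8)
    lab <- rep(0:1, each = 50)
    x[, 4] <- lab * 5 + rnorm(100, 0, 0.2)   # near-perfect separator
    colnames(x) <- sprintf("f%d", 1:8)
  })
  rep_ <- giniImportance(x, lab, n_trees = 60L, repeats = 2L, seed = 1)
  expect_identical(rep_$importance$feature_id[1], "f4")
  expect_gt(rep_$importance$importance[1],
            3 * rep_$importance$importance[2])
  expect_true(all(rep_$importance$importance >= 0))
  ## label-permuted null: the noise features of the real fit sit within it
  withr::with_seed(13, perm <- sample(lab))
  null_rep <- giniImportance(x, perm, n_trees = 60L, repeats = 2L, seed = 2)
  noise_imp <- rep_$importance$importance[rep_$importance$feature_id != "f4"]
  expect_lt(median(noise_imp), quantile(null_rep$importance$importance, 0.95) + 1)
  ## constant features: zero importance with a warning
  xc <- cbind(x, const = 0)
  expect_warning(rc <- giniImportance(xc, lab, n_trees = 20L, repeats = 1L,
                                      seed = 3), "constant")
  expect_equal(rc$importance$importance[rc$importance$feature_id == "const"], 0)
})

test_that("per-source importance reflects the strongest modality", {
  ## construct features where the 'roi' block carries the largest effect
  withr::with_seed(14, {
    n <- 120
    lab <- rep(0:1, each = 60)
    x <- cbind(matrix(rnorm(n * 3) + 0.3 * lab, n, 3),   # snp-like, weak
               matrix(rnorm(n * 3) + 0.5 * lab, n, 3),   # expr, moderate
               matrix(rnorm(n * 3) + 2.0 * lab, n, 3))   # roi, strong
    colnames(x) <- c(paste0("s", 1:3), paste0("e", 1:3), paste0("r", 1:3))
  })
  src <- rep(c("snp", "expr", "roi"), each = 3)
  rep_ <- giniImportance(x, lab, source_tags = src, n_trees = 80L,
                         repeats = 2L, seed = 4)
  expect_equal(names(which.max(rep_$by_source)), "roi")
})
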