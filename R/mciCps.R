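#' Resolved pipeline configuration
#'
#' Builds the full configuration for [trainMciCps()] and friends, with
#' defaults matching the published protocol where one is stated: genotype
#' QC at missing rate > 0.05 / MAF < 0.05 / HWE p < 1e-3; penalty fractions
#' spanning 0.05-0.5 of `lambda_max`; 1000 inner x 50 outer selection runs;
#' a feature-count search bounded at 100; fivefold cross-validation; two
#' subtypes.  Values are overridden by named arguments whose structure
#' mirrors the defaults; unknown keys are rejected.
#'
#' @param ... named overrides, e.g. `selection = list(inner = 50)`.
#' @return A nested list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  defaults <- list(
    qc = list(max_missing = 0.05, min_maf = 0.05, hwe_alpha = 1e-3),
    snf = list(K = 20, mu = 0.5, T = 20, C = 2),
    propagation = list(alpha = 0.99, tol = 1e-6, max_iter = 1000),
    selection = list(lambda_fracs = seq(0.05, 0.5, length.out = 10),
                     inner = 1000L, outer = 50L, tol = 1e-6),
    n_features = 10L,          # per-modality count, or "auto" for the CV search
    n_grid = 1:100, cv_folds = 5L, cv_repeats = 50L,
    kernel = list(family = "gaussian", theta = "median"),
    vb = list(phi = 1, max_iter = 200, tol = 1e-5, quad_nodes = 64L,
              beta_update = FALSE),
    tau = 0.5,
    min_subtype_n = 10L,
    snp_distance = "euclidean")
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]])) {
      bad2 <- setdiff(names(overrides[[k]]), names(defaults[[k]]))
      if (length(bad2))
        stop(sprintf("unknown config key(s) under '%s': %s", k,
                     paste(bad2, collapse = ", ")), call. = FALSE)
      defaults[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  class(defaults) <- "RunConfig"
  defaults
}

## ---- training-side preprocessing (all statistics from training data) ----

prepare_train <- function(train, config) {
  qc <- qcGenotypes(modality(train, "snp"),
                    max_missing = config$qc$max_missing,
                    min_maf = config$qc$min_maf,
                    hwe_alpha = config$qc$hwe_alpha)
  adjuster <- fitIcvAdjuster(modality(train, "roi"), unname(icv(train)))
  roi_adj <- applyIcvAdjuster(adjuster, modality(train, "roi"),
                              unname(icv(train)))
  std <- list(snp = fitStandardizer(qc$matrix),
              expr = fitStandardizer(modality(train, "expr")),
              roi = fitStandardizer(roi_adj))
  z <- list(snp = applyStandardizer(std$snp, qc$matrix),
            expr = applyStandardizer(std$expr, modality(train, "expr")),
            roi = applyStandardizer(std$roi, roi_adj))
  list(preprocess = list(qc_report = qc$report,
                         kept_snps = colnames(qc$matrix),
                         adjuster = adjuster, standardizers = std),
       z = z)
}

prepare_new <- function(preprocess, cohort) {
  snp <- modality(cohort, "snp")
  missing_cols <- setdiff(preprocess$kept_snps, colnames(snp))
  if (length(missing_cols))
    stop(sprintf("new cohort lacks %d SNP column(s) used in training: %s",
                 length(missing_cols),
                 paste(utils::head(missing_cols, 5), collapse = ", ")),
         call. = FALSE)
  snp <- snp[, preprocess$kept_snps, drop = FALSE]
  if (any(is.na(icv(cohort))))
    stop("ICV missing for some samples but ROI modality present",
         call. = FALSE)
  roi_adj <- applyIcvAdjuster(preprocess$adjuster, modality(cohort, "roi"),
                              unname(icv(cohort)))
  list(snp = applyStandardizer(preprocess$standardizers$snp, snp),
       expr = applyStandardizer(preprocess$standardizers$expr,
                                modality(cohort, "expr")),
       roi = applyStandardizer(preprocess$standardizers$roi, roi_adj))
}

## Fit one subtype-specific classifier bundle: per-modality stability
## selection, top-n features, Gaussian base kernels, composite-kernel VB fit.
fit_bundle <- function(z, labels, config, seed) {
  feats <- list(); specs <- list(); train_feats <- list()
  for (tag in names(z)) {
    sel_seed <- child_seed(seed, paste0("select_", tag))
    if (identical(config$n_features, "auto")) {
      ch <- chooseNFeatures(z[[tag]], labels, n_grid = config$n_grid,
                            cv_folds = config$cv_folds,
                            cv_repeats = config$cv_repeats,
                            inner = config$selection$inner,
                            outer = config$selection$outer,
                            lambda_fracs = config$selection$lambda_fracs,
                            seed = sel_seed)
      n_take <- ch$n
      ranked <- ch$ranking
    } else {
      prof <- runStabilitySelection(z[[tag]], labels,
                                    lambda_fracs = config$selection$lambda_fracs,
                                    inner = config$selection$inner,
                                    outer = config$selection$outer,
                                    seed = sel_seed,
                                    tol = config$selection$tol)
      ranked <- rankFeatures(prof)
      n_take <- min(as.integer(config$n_features), length(ranked))
    }
    feats[[tag]] <- ranked[seq_len(n_take)]
    Xtr <- z[[tag]][, feats[[tag]], drop = FALSE]
    theta <- if (identical(config$kernel$theta, "median"))
      median_heuristic(Xtr) else config$kernel$theta
    specs[[tag]] <- kernelSpec(config$kernel$family, theta)
    train_feats[[tag]] <- Xtr
  }
  kernels <- Map(function(X, sp) computeGram(X, spec = sp),
                 train_feats, specs)
  model <- fitVbpmkl(unname(kernels), labels,
                     beta_update = isTRUE(config$vb$beta_update),
                     phi = config$vb$phi, max_iter = config$vb$max_iter,
                     tol = config$vb$tol, quad_nodes = config$vb$quad_nodes,
                     seed = child_seed(seed, "vb"))
  list(features = feats, specs = specs, train_feats = train_feats,
       model = model)
}

bundle_predict <- function(bundle, z_new, rows) {
  kt <- Map(function(Xtr, sp, tag)
    computeGram(Xtr, z_new[[tag]][rows, bundle$features[[tag]], drop = FALSE],
                spec = sp),
    bundle$train_feats, bundle$specs, names(bundle$train_feats))
  predictProba(bundle$model, unname(kt))
}

#' Train the subtype-based conversion prediction model
#'
#' Full training pipeline on a labelled cohort: genotype QC, ICV adjustment
#' of ROI volumes, z-score standardization (all fit on the training data),
#' SNF subtyping over the genotype + expression layers with RatioCut
#' spectral clustering, and — within each subtype — per-modality stability
#' Lasso feature selection, Gaussian base kernels, the mean composite
#' kernel and a variational-Bayes multiple-kernel probit classifier.
#'
#' @param train an [MciCohort] with conversion labels, ICV and all three
#'   modalities.
#' @param config a [runConfig()].
#' @param seed integer seed driving per-stage substreams.
#' @return A [CPSModel-class] with one classifier bundle per subtype.
#' @export
trainMciCps <- function(train, config = runConfig(), seed = 1L) {
  stopifnot(is(train, "MciCohort"))
  labels <- unname(conversionLabels(train))
  if (anyNA(labels)) stop("training labels missing", call. = FALSE)
  prep <- prepare_train(train, config)
  Ksnf <- min(config$snf$K, max(2L, floor(length(train) / 3)))
  aff <- list(
    buildAffinity(prep$z$snp, K = Ksnf, mu = config$snf$mu,
                  distance = config$snp_distance),
    buildAffinity(prep$z$expr, K = Ksnf, mu = config$snf$mu))
  fused <- snfFuse(aff, K = Ksnf, T = config$snf$T)
  assign <- spectralCluster(fused, C = config$snf$C,
                            seed = child_seed(seed, "cluster"))
  bundles <- vector("list", assign@C)
  for (s in seq_len(assign@C)) {
    rows <- which(assign@labels == s)
    if (length(rows) < config$min_subtype_n)
      stop(sprintf("subtype %d has only %d samples (minimum %d)",
                   s, length(rows), config$min_subtype_n), call. = FALSE)
    if (length(unique(labels[rows])) < 2)
      stop(sprintf("subtype %d lacks one conversion class", s), call. = FALSE)
    zs <- lapply(prep$z, function(m) m[rows, , drop = FALSE])
    bundles[[s]] <- fit_bundle(zs, labels[rows], config,
                               child_seed(seed, "bundle", s))
  }
  new("CPSModel", preprocess = prep$preprocess,
      subtyping = list(train_z = prep$z[c("snp", "expr")],
                       fused = fused, assignment = assign,
                       K = Ksnf, mu = config$snf$mu, T = config$snf$T,
                       propagation = config$propagation),
      bundles = bundles, config = unclass(config), seed = as.integer(seed))
}

#' Train the raw (no-subtyping) classifier
#'
#' Identical pipeline to [trainMciCps()] minus the subtyping stage: one
#' classifier bundle fitted on all training samples and applied to every
#' new patient.
#'
#' @inheritParams trainMciCps
#' @return A [CPSModel-class] with a single bundle and `subtyping = NULL`.
#' @export
trainRawClassifier <- function(train, config = runConfig(), seed = 1L) {
  stopifnot(is(train, "MciCohort"))
  labels <- unname(conversionLabels(train))
  if (anyNA(labels)) stop("training labels missing", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both conversion classes required", call. = FALSE)
  prep <- prepare_train(train, config)
  bundle <- fit_bundle(prep$z, labels, config, child_seed(seed, "bundle", 1L))
  new("CPSModel", preprocess = prep$preprocess, subtyping = NULL,
      bundles = list(bundle), config = unclass(config),
      seed = as.integer(seed))
}

#' Predict conversion for new patients
#'
#' New patients are preprocessed with the training statistics, assigned to
#' a subtype by label propagation over the joint fused genotype+expression
#' network (skipped for a raw model) and scored by the matching
#' subtype-specific classifier.
#'
#' @param model a [CPSModel-class].
#' @param new an [MciCohort] sharing the training feature spaces.
#' @return A list: `assignment` (a [SubtypeAssignment-class]) and
#'   `distribution` (a `PredictiveDistribution` whose `probabilities` rows
#'   follow the input sample order; column `"1"` is the P-MCI
#'   probability).
#' @export
predictMciCps <- function(model, new) {
  stopifnot(is(model, "CPSModel"), is(new, "MciCohort"))
  z_new <- prepare_new(model@preprocess, new)
  n <- length(new)
  if (is.null(model@subtyping)) {
    assign <- assignment_from_labels(rep(1L, n), sampleIds(new), "clustered")
  } else {
    st <- model@subtyping
    assign <- labelPropagate(st$train_z, st$assignment,
                             z_new[c("snp", "expr")],
                             K = st$K, mu = st$mu, T = st$T,
                             alpha = st$propagation$alpha,
                             tol = st$propagation$tol,
                             max_iter = st$propagation$max_iter)
  }
  classes <- model@bundles[[1]]$model@classes
  P <- matrix(NA_real_, n, length(classes),
              dimnames = list(sampleIds(new), classes))
  calls <- character(n)
  for (s in seq_along(model@bundles)) {
    rows <- which(assign@labels == s)
    if (!length(rows)) next
    pr <- bundle_predict(model@bundles[[s]], z_new, rows)
    P[rows, colnames(pr$probabilities)] <- pr$probabilities
    calls[rows] <- pr$call
  }
  list(assignment = assign,
       distribution = structure(list(probabilities = P, call = calls),
                                class = "PredictiveDistribution"))
}

## ---- evaluation ----

## Mann-Whitney AUC with midrank tie correction.
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC points over all score thresholds, plus the trapezoidal integral.
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- !duplicated(rev(s))          # keep the last index of each tie group
  idx <- rev(seq_along(s))[last]
  idx <- sort(idx)
  tpr <- c(0, tp[idx] / sum(l == 1))
  fpr <- c(0, fp[idx] / sum(l == 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate conversion scores against true labels
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction
#' (equal to the trapezoidal ROC integral), and accuracy / sensitivity /
#' specificity from the confusion matrix at threshold `tau`, with P-MCI
#' (label 1) as the positive class: `Sn = TP / (TP + FN)`,
#' `Sp = TN / (TN + FP)`.
#'
#' @param scores P-MCI posterior probabilities (or any ranking scores).
#' @param labels true 0/1 conversion labels.
#' @param tau decision threshold (call P-MCI iff `score >= tau`).
#' @return An `EvaluationReport` list: `auc` in \[0, 1\], `accuracy`,
#'   `sensitivity`, `specificity` in percent, `confusion` counts, `roc`
#'   points (FPR/TPR), `roc_auc` (trapezoidal, diagnostic) and `n`.
#' @export
evaluateScores <- function(scores, labels, tau = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC undefined: only one class present", call. = FALSE)
  auc <- auc_rank(scores, labels)
  roc <- roc_points(scores, labels)
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  confusionReport(tp = tp, fn = fn, tn = tn, fp = fp, auc = auc,
                  roc = roc$points, roc_auc = roc$auc)
}

#' Metrics from confusion counts
#'
#' @param tp,fn,tn,fp confusion counts with P-MCI as the positive class.
#' @param auc,roc,roc_auc optional fields carried through from
#'   [evaluateScores()].
#' @return An `EvaluationReport` list; accuracy/sensitivity/specificity in
#'   percent.
#' @export
confusionReport <- function(tp, fn, tn, fp, auc = NA_real_, roc = NULL,
                            roc_auc = NA_real_) {
  n <- tp + fn + tn + fp
  structure(list(auc = auc,
                 accuracy = 100 * (tp + tn) / n,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 roc = roc, roc_auc = roc_auc, n = n),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport on %d samples\n", x$n))
  cat(sprintf("  AUC %.4f | Acc %.2f%% | Sn %.2f%% | Sp %.2f%%\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["tp"], x$confusion["fn"],
              x$confusion["tn"], x$confusion["fp"]))
  invisible(x)
}

#' Cross-validated evaluation of the pipeline
#'
#' Repeated stratified k-fold cross-validation of the full pipeline
#' (subtyping, feature selection and classifier all re-fit inside each
#' training fold; test-fold patients are subtyped by label propagation),
#' pooling the out-of-fold P-MCI scores of each repeat into one report.
#' Stratification uses the conversion label crossed with the true subtype
#' when one is recorded.
#'
#' @param cohort a labelled [MciCohort].
#' @param kind `"cps"` (subtype-based) or `"raw"` (no subtyping).
#' @param config a [runConfig()].
#' @param folds,repeats cross-validation shape (default fivefold, once).
#' @param seed integer seed; the report is reproducible.
#' @return An `EvaluationReport` with metrics averaged over repeats; the
#'   per-repeat reports are attached as attribute `"repeats"`, the pooled
#'   out-of-fold scores of the first repeat as attribute `"scores"`.
#' @export
crossValidate <- function(cohort, kind = c("cps", "raw"),
                          config = runConfig(), folds = 5L, repeats = 1L,
                          seed = 1L) {
  kind <- match.arg(kind)
  labels <- unname(conversionLabels(cohort))
  if (min(table(labels)) < folds)
    stop("need at least `folds` samples per class", call. = FALSE)
  strat <- labels
  st_truth <- unname(subtypeTruth(cohort))
  if (!all(is.na(st_truth)))
    strat <- as.integer(interaction(labels, st_truth, drop = TRUE))
  reports <- vector("list", repeats)
  first_scores <- NULL
  for (r in seq_len(repeats)) {
    fold <- make_folds(strat, folds, child_seed(seed, "cvfold", r))
    scores <- rep(NA_real_, length(labels))
    for (f in seq_len(folds)) {
      tr_idx <- which(fold != f)
      te_idx <- which(fold == f)
      tr <- cohortSubset(cohort, tr_idx)
      te <- cohortSubset(cohort, te_idx)
      mseed <- child_seed(seed, "cvfit", r * 1000 + f)
      model <- if (kind == "cps") trainMciCps(tr, config, seed = mseed)
               else trainRawClassifier(tr, config, seed = mseed)
      pr <- predictMciCps(model, te)
      scores[te_idx] <- pr$distribution$probabilities[, "1"]
    }
    reports[[r]] <- evaluateScores(scores, labels, tau = config$tau)
    if (r == 1L) first_scores <- scores
  }
  out <- reports[[1]]
  for (k in c("auc", "accuracy", "sensitivity", "specificity"))
    out[[k]] <- mean(vapply(reports, function(rep_) rep_[[k]], numeric(1)))
  attr(out, "repeats") <- reports
  attr(out, "scores") <- first_scores
  out
}
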