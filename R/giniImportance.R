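## Bagged CART ensemble with Gini splits, written in-package because no
## tree package is assumed at run time.  Small by design: the inputs are
## the few dozen features the stability selection retains.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

## Best Gini split of one feature at a node; returns decrease in
## n * impurity and the threshold, or NULL if no split helps.
best_split_feature <- function(xf, y, n_class) {
  ord <- order(xf)
  xs <- xf[ord]; ys <- y[ord]
  n <- length(ys)
  cum <- matrix(0, n, n_class)
  for (c_ in seq_len(n_class)) cum[, c_] <- cumsum(ys == c_)
  total <- cum[n, ]
  cut_ok <- which(xs[-n] < xs[-1])     # split only between distinct values
  if (!length(cut_ok)) return(NULL)
  parent <- sum(total) * gini_impurity(total)
  best <- list(decrease = 0, threshold = NA_real_)
  for (i in cut_ok) {
    left <- cum[i, ]; right <- total - left
    dec <- parent - sum(left) * gini_impurity(left) -
      sum(right) * gini_impurity(right)
    if (dec > best$decrease) {
      best$decrease <- dec
      best$threshold <- (xs[i] + xs[i + 1]) / 2
    }
  }
  if (best$decrease <= 0) NULL else best
}

grow_tree <- function(X, y, n_class, mtry, max_depth, min_node, imp_env) {
  recurse <- function(rows, depth) {
    yy <- y[rows]
    if (depth >= max_depth || length(rows) < min_node ||
        length(unique(yy)) == 1) return(NULL)
    feats <- sample.int(ncol(X), mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      cand <- best_split_feature(X[rows, f], yy, n_class)
      if (!is.null(cand) &&
          (is.null(best) || cand$decrease > best$decrease)) {
        best <- cand; best_f <- f
      }
    }
    if (is.null(best)) return(NULL)
    imp_env$imp[best_f] <- imp_env$imp[best_f] + best$decrease
    left <- rows[X[rows, best_f] <= best$threshold]
    right <- setdiff(rows, left)
    recurse(left, depth + 1)
    recurse(right, depth + 1)
    invisible(NULL)
  }
  recurse(seq_len(nrow(X)), 0)
}

#' Mean decrease in Gini impurity from a bagged tree ensemble
#'
#' Fits a bagged ensemble of CART trees (Gini split criterion,
#' `sqrt(p)` features tried per node, bootstrap resampling) on the selected
#' features and credits each feature with the total decrease in node Gini
#' impurity over its splits, averaged over trees and over `repeats`
#' independent ensemble seeds.  Constant features get zero importance with
#' a warning.
#'
#' @param x samples x features matrix (typically the selected, standardized
#'   training features of all modalities).
#' @param labels class label per sample (>= 2 classes).
#' @param source_tags optional per-feature modality tag
#'   (`"snp"`/`"expr"`/`"roi"`); per-source mean importances are reported
#'   when given.
#' @param n_trees trees per ensemble.
#' @param repeats independent ensemble repetitions to average over.
#' @param mtry features tried per split (default `sqrt(p)`).
#' @param max_depth,min_node tree shape control.
#' @param seed integer seed.
#' @return A `GiniImportanceReport` list: `importance` data.frame (feature,
#'   source, importance; sorted descending) and `by_source` mean importance
#'   per modality.
#' @export
giniImportance <- function(x, labels, source_tags = NULL,
                           n_trees = 500L, repeats = 10L, mtry = NULL,
                           max_depth = 10L, min_node = 5L, seed = 1L) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  y <- match(labels, classes)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    warning(sprintf("%d constant feature(s) get zero importance", sum(const)),
            call. = FALSE)
  imp_total <- numeric(ncol(x))
  for (r in seq_len(repeats)) {
    with_seed(child_seed(seed, "gini", r), {
      for (b in seq_len(n_trees)) {
        rows <- sample.int(nrow(x), replace = TRUE)
        env <- new.env()
        env$imp <- numeric(ncol(x))
        grow_tree(x[rows, , drop = FALSE], y[rows], length(classes),
                  mtry, max_depth, min_node, env)
        imp_total <- imp_total + env$imp
      }
    })
  }
  imp <- imp_total / (n_trees * repeats)
  if (is.null(source_tags)) source_tags <- rep(NA_character_, ncol(x))
  df <- data.frame(feature_id = colnames(x), source = source_tags,
                   importance = imp, stringsAsFactors = FALSE)
  df <- df[order(-df$importance, df$feature_id), ]
  rownames(df) <- NULL
  by_source <- if (!all(is.na(source_tags)))
    tapply(df$importance, df$source, mean) else NULL
  structure(list(importance = df, by_source = by_source,
                 n_trees = n_trees, repeats = repeats),
            class = "GiniImportanceReport")
}

#' @export
print.GiniImportanceReport <- function(x, ...) {
  cat(sprintf("GiniImportanceReport (%d trees x %d repeats)\n",
              x$n_trees, x$repeats))
  print(utils::head(x$importance, 10))
  if (!is.null(x$by_source)) {
    cat("mean importance by source:\n")
    print(x$by_source)
  }
  invisible(x)
}
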