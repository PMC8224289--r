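# Shared fixtures, built in code at test time.

## Small synthetic cohort config for fast unit tests.
quick_cfg <- function(seed = 1L, ...) {
  args <- list(n_train = 60L, n_test = 40L, n_snp = 40L, n_expr = 40L,
               n_roi = 20L, n_subtype_informative_snp = 12L,
               n_subtype_informative_expr = 12L,
               n_conv_informative_per_modality = 3L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}

## Fast pipeline config (reduced selection reps).
fast_runconfig <- function(...) {
  args <- list(selection = list(inner = 20L, outer = 5L), n_features = 6L,
               min_subtype_n = 5L)
  ov <- list(...)
  for (k in names(ov)) {
    if (is.list(args[[k]]) && is.list(ov[[k]]))
      args[[k]][names(ov[[k]])] <- ov[[k]]
    else args[[k]] <- ov[[k]]
  }
  do.call(runConfig, args)
}

## Gaussian blobs with class labels, for clustering/classifier tests.
make_blobs <- function(n_per = 20, C = 2, d = 5, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(C), function(c_) {
      center <- rnorm(d) * 0 + sep * (c_ - 1)
      matrix(rnorm(n_per * d), n_per, d) +
        matrix(center, n_per, d, byrow = TRUE)
    }))
    rownames(X) <- sprintf("b%03d", seq_len(nrow(X)))
    list(x = X, y = rep(seq_len(C), each = n_per))
  })
}

## Map cluster labels onto reference labels by majority overlap.
map_clusters <- function(pred, ref) {
  tab <- table(pred, ref)
  map <- as.integer(colnames(tab))[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  unname(map[as.character(pred)])
}
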