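#' Genotype quality control
#'
#' Filters SNP columns by per-feature missing rate, minor allele frequency
#' (MAF) and a Hardy-Weinberg equilibrium (HWE) test, the standard QC
#' triplet for array genotypes.  Filters are applied in order
#' missing -> MAF -> HWE, each computed on non-missing calls, with strict
#' inequalities: drop when missing rate > `max_missing`, MAF < `min_maf`,
#' or HWE p-value < `hwe_alpha`.  The HWE test is the 1-df chi-square of
#' observed genotype counts against Hardy-Weinberg expectations at the
#' observed allele frequency, without continuity correction (PLINK defaults
#' to an exact test; at the 1e-3 threshold the difference is immaterial and
#' the chi-square form is transparent).
#'
#' @param snp samples x SNPs matrix coded 0/1/2 with `NA` missing.
#' @param max_missing maximum tolerated missing rate (default 0.05).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param hwe_alpha HWE p-value threshold (default 1e-3).
#' @return A list: `matrix` restricted to kept SNPs (missing calls still
#'   `NA`; impute downstream on training statistics) and `report`, a
#'   data.frame with per-SNP missing rate, MAF, HWE chi-square and p-value,
#'   `keep` flag and drop `reason` in `{missing, maf, hwe}`.
#' @export
qcGenotypes <- function(snp, max_missing = 0.05, min_maf = 0.05,
                        hwe_alpha = 1e-3) {
  if (!is.matrix(snp)) stop("snp must be a matrix", call. = FALSE)
  vals <- snp[!is.na(snp)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("genotypes must be coded 0/1/2 (NA for missing)", call. = FALSE)
  n <- nrow(snp)
  miss <- colMeans(is.na(snp))
  n0 <- colSums(snp == 0, na.rm = TRUE)
  n1 <- colSums(snp == 1, na.rm = TRUE)
  n2 <- colSums(snp == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  p <- ifelse(nn > 0, (2 * n2 + n1) / (2 * nn), NA)   # coded-allele frequency
  maf <- pmin(p, 1 - p)
  ## 1-df chi-square against HWE expectations at the observed frequency
  e0 <- nn * (1 - p)^2; e1 <- 2 * nn * p * (1 - p); e2 <- nn * p^2
  chisq <- rep(NA_real_, ncol(snp))
  ok <- !is.na(p) & p > 0 & p < 1
  chisq[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] + (n2[ok] - e2[ok])^2 / e2[ok]
  chisq[!ok & !is.na(p)] <- 0      # monomorphic: no HWE departure testable
  hwe_p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  reason <- rep(NA_character_, ncol(snp))
  reason[miss > max_missing] <- "missing"
  reason[is.na(reason) & (is.na(maf) | maf < min_maf)] <- "maf"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  keep <- is.na(reason)
  report <- data.frame(feature_id = colnames(snp), missing_rate = miss,
                       maf = maf, hwe_chisq = chisq, hwe_p = hwe_p,
                       keep = keep, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(matrix = snp[, keep, drop = FALSE], report = report)
}

#' Fit the ICV adjustment for regional brain volumes
#'
#' Regional volumes scale with head size; the standard correction regresses
#' each region-of-interest (ROI) volume on intracranial volume (ICV) in the
#' training set and removes the slope component about the training ICV mean:
#' `adjusted_i = raw_i - theta_i * (ICV - ICV_mean)`, where `theta_i` is the
#' ordinary-least-squares slope of ROI `i` on ICV.  The intercept is
#' retained so volumes keep their physical scale.
#'
#' @param roi training samples x ROIs volume matrix (mL).
#' @param icv training per-sample ICV (mL).
#' @return An object of class `ICVAdjuster`: slopes `theta` per ROI, the
#'   training `icv_mean`, and per-ROI intercepts (diagnostics only).
#' @export
fitIcvAdjuster <- function(roi, icv) {
  stopifnot(is.matrix(roi), length(icv) == nrow(roi))
  if (nrow(roi) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(icv) == 0)
    stop("ICV is constant: degenerate regressor", call. = FALSE)
  icv_c <- icv - mean(icv)
  theta <- as.vector(crossprod(icv_c, scale(roi, scale = FALSE))) /
    sum(icv_c^2)
  names(theta) <- colnames(roi)
  intercept <- colMeans(roi) - theta * mean(icv)
  structure(list(theta = theta, icv_mean = mean(icv), intercept = intercept),
            class = "ICVAdjuster")
}

#' Apply a fitted ICV adjustment
#'
#' @param adjuster an [fitIcvAdjuster()] result.
#' @param roi samples x ROIs volume matrix with the training columns.
#' @param icv per-sample ICV (mL).
#' @return The adjusted volume matrix.  On the training set each adjusted
#'   column is uncorrelated with ICV (OLS residual orthogonality).
#' @export
applyIcvAdjuster <- function(adjuster, roi, icv) {
  stopifnot(inherits(adjuster, "ICVAdjuster"), is.matrix(roi),
            length(icv) == nrow(roi))
  if (!identical(colnames(roi), names(adjuster$theta)))
    stop("ROI columns do not match the fitted adjuster", call. = FALSE)
  roi - outer(icv - adjuster$icv_mean, adjuster$theta)
}

#' Fit / apply per-feature z-score standardization
#'
#' Means and SDs are learned on training data only and re-used on test data
#' (no statistic is ever computed from test samples).  Zero-variance
#' training columns are dropped with a warning.  Missing entries are
#' ignored when fitting; `applyStandardizer()` imputes them at the training
#' mean (standardized value 0), the minimal stand-in for reference-panel
#' genotype imputation.
#'
#' @param x training samples x features matrix (may contain `NA`).
#' @return `fitStandardizer()`: a `Standardizer` with per-feature `mean`,
#'   `sd` and the retained feature ids.
#' @export
fitStandardizer <- function(x) {
  stopifnot(is.matrix(x))
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sdv) & sdv > 0
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep),
                    paste(utils::head(colnames(x)[!keep], 5), collapse = ", ")),
            call. = FALSE)
  structure(list(mean = mu[keep], sd = sdv[keep],
                 features = colnames(x)[keep]),
            class = "Standardizer")
}

#' @rdname fitStandardizer
#' @param s a fitted `Standardizer`.
#' @param impute_missing replace `NA` by the training mean (standardized 0).
#' @return `applyStandardizer()`: the standardized matrix restricted to the
#'   retained features.
#' @export
applyStandardizer <- function(s, x, impute_missing = TRUE) {
  stopifnot(inherits(s, "Standardizer"), is.matrix(x))
  if (!all(s$features %in% colnames(x)))
    stop("input lacks features the standardizer was fitted on", call. = FALSE)
  x <- x[, s$features, drop = FALSE]
  z <- sweep(sweep(x, 2, s$mean, "-"), 2, s$sd, "/")
  if (impute_missing) z[is.na(z)] <- 0
  z
}
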