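#' Configuration for the synthetic multi-modal MCI cohort generator
#'
#' The generator emulates the structure the prediction pipeline is designed
#' to exploit: two latent molecular subtypes expressed in the SNP and
#' expression layers, subtype-specific conversion-informative features in
#' all three layers (disjoint between subtypes and disjoint from the
#' subtype-informative sets), and regional brain volumes linearly confounded
#' by intracranial volume (ICV).
#'
#' Defaults describe a realistic desk-scale cohort: 150 training + 100 test
#' patients (the restricted ADNI cohorts the method targets are of this
#' order), a ~40% three-year conversion rate in both subtypes, an allele
#' frequency separation of 0.15 between subtypes at informative SNPs with a
#' 1 SD expression separation, a 1 SD conversion shift on informative
#' features, adult ICV ~ N(1500, 150^2) mL, per-ROI ICV slopes in
#' [0.002, 0.02] mL per mL, residual ROI noise of 0.5 mL, and a 2% missing
#' genotype rate.
#'
#' @param n_train,n_test sample counts (the generator produces
#'   `n_train + n_test` samples; split with [splitCohort()] or
#'   [cohortSubset()]).
#' @param n_snp,n_expr,n_roi feature counts per modality.
#' @param n_subtype_informative_snp,n_subtype_informative_expr number of
#'   features separating the two subtypes in each layer.
#' @param n_conv_informative_per_modality conversion-informative features
#'   per subtype per modality (disjoint sets).
#' @param subtype_effect_snp allele-frequency shift (+/-) at
#'   subtype-informative SNPs.
#' @param subtype_effect_expr standardized mean shift (+/-) at
#'   subtype-informative expression features.
#' @param conversion_effect standardized mean shift applied to converters on
#'   their own subtype's conversion-informative features (volume loss,
#'   i.e. negative shift, for ROI features).
#' @param conversion_rate_subtype1,conversion_rate_subtype2 three-year
#'   conversion probabilities per subtype.
#' @param icv_mean,icv_sd intracranial volume distribution (mL).
#' @param roi_icv_slope_range interval from which per-ROI ICV slopes
#'   `theta_j` are drawn (mL ROI per mL ICV).
#' @param noise_sd residual ROI noise SD (mL); the ROI conversion shift is
#'   `conversion_effect * noise_sd` so its standardized magnitude is exact.
#' @param snp_missing_rate probability that a genotype call is missing.
#' @param seed integer seed; the cohort is reproduced bit-identically.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_train = 150L, n_test = 100L,
                            n_snp = 100L, n_expr = 100L, n_roi = 50L,
                            n_subtype_informative_snp = 30L,
                            n_subtype_informative_expr = 30L,
                            n_conv_informative_per_modality = 5L,
                            subtype_effect_snp = 0.15,
                            subtype_effect_expr = 1.0,
                            conversion_effect = 1.0,
                            conversion_rate_subtype1 = 0.4,
                            conversion_rate_subtype2 = 0.4,
                            icv_mean = 1500, icv_sd = 150,
                            roi_icv_slope_range = c(0.002, 0.02),
                            noise_sd = 0.5,
                            snp_missing_rate = 0.02,
                            seed = 1L) {
  cfg <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
              n_snp = as.integer(n_snp), n_expr = as.integer(n_expr),
              n_roi = as.integer(n_roi),
              n_subtype_informative_snp = as.integer(n_subtype_informative_snp),
              n_subtype_informative_expr = as.integer(n_subtype_informative_expr),
              n_conv_informative_per_modality =
                as.integer(n_conv_informative_per_modality),
              subtype_effect_snp = subtype_effect_snp,
              subtype_effect_expr = subtype_effect_expr,
              conversion_effect = conversion_effect,
              conversion_rate_subtype1 = conversion_rate_subtype1,
              conversion_rate_subtype2 = conversion_rate_subtype2,
              icv_mean = icv_mean, icv_sd = icv_sd,
              roi_icv_slope_range = roi_icv_slope_range,
              noise_sd = noise_sd, snp_missing_rate = snp_missing_rate,
              seed = as.integer(seed))
  for (f in c("n_train", "n_test", "n_snp", "n_expr", "n_roi"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) stop_field(f, "must be a positive count")
  for (f in c("n_subtype_informative_snp", "n_subtype_informative_expr",
              "n_conv_informative_per_modality"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop_field(f, "must be a nonnegative count")
  k <- cfg$n_conv_informative_per_modality
  if (cfg$n_subtype_informative_snp + 2 * k > cfg$n_snp)
    stop_field("n_subtype_informative_snp",
               "informative SNP sets exceed n_snp")
  if (cfg$n_subtype_informative_expr + 2 * k > cfg$n_expr)
    stop_field("n_subtype_informative_expr",
               "informative expression sets exceed n_expr")
  if (2 * k > cfg$n_roi)
    stop_field("n_conv_informative_per_modality",
               "conversion-informative ROI sets exceed n_roi")
  for (f in c("conversion_rate_subtype1", "conversion_rate_subtype2",
              "snp_missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0,1]")
  if (cfg$icv_mean <= 0 || cfg$icv_sd < 0) stop_field("icv_mean", "ICV must be positive")
  if (length(cfg$roi_icv_slope_range) != 2 ||
      diff(cfg$roi_icv_slope_range) < 0)
    stop_field("roi_icv_slope_range", "must be an increasing interval")
  if (cfg$noise_sd <= 0) stop_field("noise_sd", "must be positive")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a synthetic multi-modal cohort with known ground truth
#'
#' Draws `n_train + n_test` patients.  Subtype `z ~ Bernoulli(0.5) + 1`.
#' Genotypes are `Binomial(2, p_j)` with `p_j ~ U(0.05, 0.5)`;
#' subtype-informative SNPs use `p_j + subtype_effect_snp` in subtype 1 and
#' `p_j - subtype_effect_snp` in subtype 2 (clipped to \[0.05, 0.95\]).
#' Expression is standard normal with subtype-informative features shifted
#' by +/- `subtype_effect_expr`.  The conversion label is Bernoulli with the
#' subtype's rate; converters receive a `conversion_effect` standardized
#' shift on the conversion-informative features of their *own* subtype in
#' all three layers (for SNPs, via an allele-frequency shift of
#' `conversion_effect * sqrt(2 p (1-p)) / 2`, so the standardized genotype
#' shift matches; for ROI, a volume *loss* of
#' `conversion_effect * noise_sd`).  Raw ROI volume is
#' `baseline_j + theta_j * ICV + shift + N(0, noise_sd^2)` with
#' `ICV ~ N(icv_mean, icv_sd^2)`.  A fraction `snp_missing_rate` of genotype
#' calls is masked missing.  Deterministic given `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @return An [MciCohort] whose `truth` list records the subtype of every
#'   sample, the informative feature sets (`snp_subtype`, `expr_subtype`,
#'   and per-subtype conversion sets `*_conv1`, `*_conv2`), the per-ROI
#'   slopes `theta` and baselines, and the SNP allele frequencies.
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must be created by syntheticConfig()", call. = FALSE)
  cfg <- config
  n <- cfg$n_train + cfg$n_test
  k <- cfg$n_conv_informative_per_modality
  with_seed(cfg$seed, {
    ids <- sprintf("S%04d", seq_len(n))
    z <- rbinom(n, 1, 0.5) + 1L            # latent subtype
    rate <- ifelse(z == 1L, cfg$conversion_rate_subtype1,
                   cfg$conversion_rate_subtype2)
    lab <- rbinom(n, 1, rate)              # 1 = P-MCI (converter)

    ## disjoint informative index sets per modality
    snp_sub <- seq_len(cfg$n_subtype_informative_snp)
    snp_c1 <- cfg$n_subtype_informative_snp + seq_len(k)
    snp_c2 <- cfg$n_subtype_informative_snp + k + seq_len(k)
    expr_sub <- seq_len(cfg$n_subtype_informative_expr)
    expr_c1 <- cfg$n_subtype_informative_expr + seq_len(k)
    expr_c2 <- cfg$n_subtype_informative_expr + k + seq_len(k)
    roi_c1 <- seq_len(k)
    roi_c2 <- k + seq_len(k)

    ## --- SNP layer ---
    p <- runif(cfg$n_snp, 0.05, 0.5)
    P <- matrix(p, n, cfg$n_snp, byrow = TRUE)
    P[, snp_sub] <- P[, snp_sub] +
      ifelse(z == 1L, cfg$subtype_effect_snp, -cfg$subtype_effect_snp)
    shift_af <- function(P, cols, who) {
      ## allele-frequency shift giving a `conversion_effect` SD genotype shift
      d <- cfg$conversion_effect * sqrt(2 * P[, cols] * (1 - P[, cols])) / 2
      P[, cols] <- P[, cols] + d * who
      P
    }
    P <- shift_af(P, snp_c1, as.numeric(z == 1L & lab == 1L))
    P <- shift_af(P, snp_c2, as.numeric(z == 2L & lab == 1L))
    P <- pmin(pmax(P, 0.05), 0.95)
    snp <- matrix(rbinom(n * cfg$n_snp, 2, as.vector(P)), n, cfg$n_snp)
    if (cfg$snp_missing_rate > 0)
      snp[runif(n * cfg$n_snp) < cfg$snp_missing_rate] <- NA
    dimnames(snp) <- list(ids, sprintf("rs%05d", seq_len(cfg$n_snp)))

    ## --- expression layer ---
    expr <- matrix(rnorm(n * cfg$n_expr), n, cfg$n_expr)
    expr[, expr_sub] <- expr[, expr_sub] +
      ifelse(z == 1L, cfg$subtype_effect_expr, -cfg$subtype_effect_expr)
    expr[z == 1L & lab == 1L, expr_c1] <-
      expr[z == 1L & lab == 1L, expr_c1] + cfg$conversion_effect
    expr[z == 2L & lab == 1L, expr_c2] <-
      expr[z == 2L & lab == 1L, expr_c2] + cfg$conversion_effect
    dimnames(expr) <- list(ids, sprintf("gene%04d", seq_len(cfg$n_expr)))

    ## --- ROI layer, confounded by head size ---
    icv_v <- rnorm(n, cfg$icv_mean, cfg$icv_sd)
    icv_v <- pmax(icv_v, cfg$icv_mean / 3)   # keep ICV physical
    theta <- runif(cfg$n_roi, cfg$roi_icv_slope_range[1],
                   cfg$roi_icv_slope_range[2])
    baseline <- runif(cfg$n_roi, 2, 20)
    roi <- matrix(baseline, n, cfg$n_roi, byrow = TRUE) +
      outer(icv_v, theta) +
      matrix(rnorm(n * cfg$n_roi, 0, cfg$noise_sd), n, cfg$n_roi)
    dshift <- cfg$conversion_effect * cfg$noise_sd
    roi[z == 1L & lab == 1L, roi_c1] <- roi[z == 1L & lab == 1L, roi_c1] - dshift
    roi[z == 2L & lab == 1L, roi_c2] <- roi[z == 2L & lab == 1L, roi_c2] - dshift
    dimnames(roi) <- list(ids, sprintf("roi%03d", seq_len(cfg$n_roi)))

    truth <- list(
      subtype = stats::setNames(z, ids),
      informative = list(
        snp_subtype = colnames(snp)[snp_sub],
        snp_conv1 = colnames(snp)[snp_c1], snp_conv2 = colnames(snp)[snp_c2],
        expr_subtype = colnames(expr)[expr_sub],
        expr_conv1 = colnames(expr)[expr_c1], expr_conv2 = colnames(expr)[expr_c2],
        roi_conv1 = colnames(roi)[roi_c1], roi_conv2 = colnames(roi)[roi_c2]),
      theta = stats::setNames(theta, colnames(roi)),
      baseline = stats::setNames(baseline, colnames(roi)),
      allele_freq = stats::setNames(p, colnames(snp)),
      config = unclass(cfg))

    MciCohort(list(snp = snp, expr = expr, roi = roi),
              data.frame(sample_id = ids, label = lab, icv = icv_v,
                         subtype = z, stringsAsFactors = FALSE),
              truth = truth)
  })
}

#' Stratified train/test split of a cohort
#'
#' Partitions samples into a training and a test cohort while preserving the
#' proportions of the stratification labels.  Within each stratum the
#' training share is `floor(fraction * n_stratum)`; remaining training slots
#' up to `floor(fraction * N)` are assigned to the strata with the largest
#' fractional parts (largest-remainder rule), so e.g. `fraction = 0.8` on
#' 125 samples always yields sizes 100 and 25.
#'
#' @param cohort an [MciCohort].
#' @param fraction training fraction in (0, 1).
#' @param stratify_on metadata columns to stratify on; defaults to the
#'   conversion label plus the subtype when present.
#' @param seed integer seed (same seed, same split).
#' @return A list with elements `train` and `test` (both `MciCohort`).
#' @export
splitCohort <- function(cohort, fraction = 0.8,
                        stratify_on = c("label", "subtype"), seed = 1L) {
  stopifnot(is(cohort, "MciCohort"))
  if (fraction <= 0 || fraction >= 1)
    stop_field("fraction", "must be in (0,1)")
  sd_ <- sampleData(cohort)
  cols <- intersect(stratify_on, colnames(sd_))
  cols <- cols[vapply(cols, function(cc) !all(is.na(sd_[[cc]])), logical(1))]
  strata <- if (length(cols))
    interaction(sd_[cols], drop = TRUE) else factor(rep(1, nrow(sd_)))
  sizes <- table(strata)
  if (any(sizes < 2))
    stop(sprintf("stratum '%s' has fewer than 2 samples",
                 names(sizes)[which(sizes < 2)[1]]), call. = FALSE)
  n_train_total <- floor(fraction * nrow(sd_))
  raw <- fraction * as.numeric(sizes)
  base <- floor(raw)
  rem <- n_train_total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(raw - base)
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(seq_along(sizes), function(s) {
      members <- which(strata == names(sizes)[s])
      sample(members, base[s])
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(sd_)), idx_train)
  list(train = cohortSubset(cohort, idx_train),
       test = cohortSubset(cohort, idx_test))
}
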