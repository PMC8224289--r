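## Central S4 containers.  Modality blocks are plain numeric matrices
## (samples x features, dimnames mandatory); NA encodes a missing genotype
## call so the missing mask is carried by the matrix itself.

setClassUnion("listOrNULL", c("list", "NULL"))

#' MciCohort: aligned multi-modal patient cohort
#'
#' Holds one samples-by-features numeric matrix per modality (`snp`, `expr`,
#' `roi`), per-sample metadata (three-year conversion label, intracranial
#' volume, optional molecular subtype) and, for synthetic cohorts, the
#' generator's ground truth (informative feature sets, ICV slopes, subtypes).
#'
#' Genotype matrices are additively coded 0/1/2 with `NA` for missing calls;
#' all modality blocks share one ordered set of sample identifiers
#' (the matrices' rownames).
#'
#' @slot modalities named list of numeric matrices (samples x features).
#' @slot sampleData data.frame with columns `sample_id`, `label`
#'   (0 = stable MCI, 1 = progressive MCI, or `NA`), `icv` (mL, or `NA`),
#'   `subtype` (integer or `NA`).
#' @slot truth list of generator ground truth (empty for real data).
#' @export
setClass("MciCohort",
  representation(modalities = "list", sampleData = "data.frame",
                 truth = "list"))

setValidity("MciCohort", function(object) {
  m <- object@modalities
  sd_ <- object@sampleData
  if (length(m) == 0) return("at least one modality required")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("modalities must be named")
  if (!all(c("sample_id", "label", "icv", "subtype") %in% colnames(sd_)))
    return("sampleData needs columns sample_id, label, icv, subtype")
  ids <- sd_$sample_id
  if (anyDuplicated(ids)) return("duplicate sample ids")
  for (tag in names(m)) {
    x <- m[[tag]]
    if (!is.matrix(x) || !is.numeric(x))
      return(sprintf("modality '%s' is not a numeric matrix", tag))
    if (is.null(rownames(x)) || !identical(rownames(x), as.character(ids)))
      return(sprintf("modality '%s' rownames do not match sample ids", tag))
    if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
      return(sprintf("modality '%s' needs unique feature ids", tag))
    if (tag == "snp") {
      v <- x[!is.na(x)]
      if (length(v) && !all(v %in% c(0, 1, 2)))
        return("snp modality must be coded 0/1/2 with NA for missing")
    }
  }
  lab <- sd_$label[!is.na(sd_$label)]
  if (length(lab) && !all(lab %in% c(0, 1)))
    return("conversion labels must be 0 (S-MCI) or 1 (P-MCI)")
  icv <- sd_$icv[!is.na(sd_$icv)]
  if (length(icv) && any(icv <= 0)) return("ICV must be strictly positive")
  TRUE
})

#' @describeIn MciCohort constructor.
#' @param modalities,sampleData,truth see slots.
#' @export
MciCohort <- function(modalities, sampleData, truth = list()) {
  sampleData$sample_id <- as.character(sampleData$sample_id)
  for (k in c("label", "icv", "subtype"))
    if (is.null(sampleData[[k]])) sampleData[[k]] <- NA
  sampleData <- sampleData[, c("sample_id", "label", "icv", "subtype",
                               setdiff(colnames(sampleData),
                                       c("sample_id", "label", "icv",
                                         "subtype"))), drop = FALSE]
  new("MciCohort", modalities = modalities, sampleData = sampleData,
      truth = truth)
}

#' AffinityNetwork: patient-by-patient similarity network
#'
#' Symmetric nonnegative N x N similarity matrix built from one modality
#' with a scaled exponential kernel.
#'
#' @slot W numeric similarity matrix with sample ids as dimnames.
#' @slot K neighbourhood size used in the local scale.
#' @slot mu bandwidth scale factor.
#' @export
setClass("AffinityNetwork",
  representation(W = "matrix", K = "integer", mu = "numeric"))

setValidity("AffinityNetwork", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("W must be square")
  if (any(!is.finite(W))) return("W must be finite")
  if (any(W < 0)) return("W must be nonnegative")
  if (max(abs(W - t(W))) > 1e-12) return("W must be symmetric")
  TRUE
})

#' FusedNetwork: similarity network fused across modalities
#'
#' Result of the SNF cross-diffusion iteration; carries the per-iteration
#' change norms as a convergence diagnostic.
#'
#' @slot W fused symmetric nonnegative similarity matrix.
#' @slot iterations number of diffusion iterations performed.
#' @slot deltas per-iteration Frobenius change norms (averaged over layers).
#' @export
setClass("FusedNetwork",
  representation(W = "matrix", iterations = "integer", deltas = "numeric"))

setValidity("FusedNetwork", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("W must be square")
  if (any(!is.finite(W)) || any(W < 0)) return("W must be finite nonnegative")
  if (max(abs(W - t(W))) > 1e-12) return("W must be symmetric")
  TRUE
})

#' SubtypeAssignment: per-sample molecular subtype labels
#'
#' @slot labels named integer vector of subtype labels in `1..C`.
#' @slot C number of subtypes.
#' @slot source `"clustered"` (spectral clustering of the fused network) or
#'   `"propagated"` (semi-supervised label propagation).
#' @slot scores N x C membership score matrix; rows sum to 1.
#' @export
setClass("SubtypeAssignment",
  representation(labels = "integer", C = "integer", source = "character",
                 scores = "matrix"))

setValidity("SubtypeAssignment", function(object) {
  if (!object@source %in% c("clustered", "propagated"))
    return("source must be 'clustered' or 'propagated'")
  if (any(object@labels < 1L | object@labels > object@C))
    return("labels must lie in 1..C")
  if (nrow(object@scores) != length(object@labels))
    return("scores rows must match labels")
  if (ncol(object@scores) != object@C) return("scores must have C columns")
  if (max(abs(rowSums(object@scores) - 1)) > 1e-6)
    return("score rows must sum to 1")
  TRUE
})

#' VBpMKLModel: variational-Bayes multiple-kernel multinomial-probit model
#'
#' Posterior summaries of the kernel-expansion regressors for each class,
#' the kernel combination weights and everything needed to score new
#' samples from their test-vs-train Gram blocks.
#'
#' @slot Wmean N x C posterior mean of the regressors in kernel expansion
#'   space (one column per class).
#' @slot Vcov shared N x N posterior covariance of each class's regressor.
#' @slot beta kernel combination weights on the simplex.
#' @slot phi Gaussian prior precision on the regressors.
#' @slot classes class labels, column order of `Wmean`.
#' @slot trace per-iteration max change in the auxiliary-variable means.
#' @slot converged logical.
#' @slot quadNodes number of Gauss-Hermite nodes for the predictive integral.
#' @slot trainInfo list set by callers (kernel specs, training features)
#'   needed to rebuild test kernels.
#' @export
setClass("VBpMKLModel",
  representation(Wmean = "matrix", Vcov = "matrix", beta = "numeric",
                 phi = "numeric", classes = "character", trace = "numeric",
                 converged = "logical", quadNodes = "integer",
                 trainInfo = "list"))

setValidity("VBpMKLModel", function(object) {
  if (ncol(object@Wmean) != length(object@classes))
    return("one Wmean column per class required")
  if (abs(sum(object@beta) - 1) > 1e-8 || any(object@beta < 0))
    return("beta must be nonnegative and sum to 1")
  TRUE
})

#' CPSModel: full subtype-based conversion prediction model
#'
#' The trained pipeline: preprocessing state fitted on training data,
#' subtype clustering over the fused genotype+expression network, and one
#' classifier bundle per subtype (selected features per modality, kernel
#' specs and a fitted [VBpMKLModel]).  A "raw" model (no subtyping) is the
#' degenerate case with a single bundle.
#'
#' @slot preprocess list: QC report/kept features, ICV adjuster, per-modality
#'   standardizers.
#' @slot subtyping list: training affinity inputs, fused network, subtype
#'   labels, propagation parameters (`NULL` for the raw model).
#' @slot bundles list of per-subtype classifier bundles.
#' @slot config resolved configuration snapshot sufficient to retrain.
#' @slot seed integer seed the model was trained under.
#' @export
setClass("CPSModel",
  representation(preprocess = "list", subtyping = "listOrNULL",
                 bundles = "list", config = "list", seed = "integer"))

setValidity("CPSModel", function(object) {
  if (length(object@bundles) < 1) return("at least one bundle required")
  TRUE
})

## ---- accessors ----

#' @describeIn MciCohort number of samples.
#' @param x,object an `MciCohort`.
#' @export
setMethod("length", "MciCohort", function(x) nrow(x@sampleData))

#' Accessors for MciCohort
#'
#' @param x an `MciCohort`.
#' @param tag modality name (`"snp"`, `"expr"`, `"roi"`).
#' @return `modality()` the samples x features matrix; `sampleIds()` a
#'   character vector; `conversionLabels()`, `icv()`, `subtypeTruth()`
#'   per-sample vectors; `sampleData()` the metadata data.frame;
#'   `cohortTruth()` the generator ground-truth list.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
modality <- function(x, tag) {
  stopifnot(is(x, "MciCohort"))
  if (!tag %in% names(x@modalities))
    stop(sprintf("modality '%s' not present (have: %s)", tag,
                 paste(names(x@modalities), collapse = ", ")), call. = FALSE)
  x@modalities[[tag]]
}

#' @rdname cohort-accessors
#' @export
modalityNames <- function(x) names(x@modalities)

#' @rdname cohort-accessors
#' @export
sampleIds <- function(x) x@sampleData$sample_id

#' @rdname cohort-accessors
#' @export
conversionLabels <- function(x) {
  stats::setNames(x@sampleData$label, x@sampleData$sample_id)
}

#' @rdname cohort-accessors
#' @export
icv <- function(x) stats::setNames(x@sampleData$icv, x@sampleData$sample_id)

#' @rdname cohort-accessors
#' @export
subtypeTruth <- function(x) {
  stats::setNames(x@sampleData$subtype, x@sampleData$sample_id)
}

#' @rdname cohort-accessors
#' @export
sampleData <- function(x) x@sampleData

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) x@truth

#' Subset a cohort by sample
#'
#' @param x an `MciCohort`.
#' @param idx integer, logical or character (sample id) index.
#' @return An `MciCohort` restricted to the selected samples, in the
#'   requested order.
#' @export
cohortSubset <- function(x, idx) {
  ids <- sampleIds(x)
  if (is.character(idx)) idx <- match(idx, ids)
  if (is.logical(idx)) idx <- which(idx)
  if (anyNA(idx) || any(idx < 1 | idx > length(ids)))
    stop("subset index out of range", call. = FALSE)
  mods <- lapply(x@modalities, function(m) m[idx, , drop = FALSE])
  MciCohort(mods, x@sampleData[idx, , drop = FALSE], truth = x@truth)
}

## ---- show methods ----

setMethod("show", "MciCohort", function(object) {
  cat(sprintf("MciCohort with %d samples\n", length(object)))
  for (tag in names(object@modalities)) {
    m <- object@modalities[[tag]]
    cat(sprintf("  %-5s %5d features  (%d missing entries)\n",
                tag, ncol(m), sum(is.na(m))))
  }
  lab <- object@sampleData$label
  if (!all(is.na(lab)))
    cat(sprintf("  labels: %d P-MCI / %d S-MCI\n",
                sum(lab == 1, na.rm = TRUE), sum(lab == 0, na.rm = TRUE)))
  if (length(object@truth))
    cat("  synthetic ground truth attached\n")
})

setMethod("show", "FusedNetwork", function(object) {
  cat(sprintf("FusedNetwork on %d samples (%d SNF iterations, final delta %.3g)\n",
              nrow(object@W), object@iterations,
              if (length(object@deltas)) object@deltas[length(object@deltas)]
              else NA_real_))
})

setMethod("show", "SubtypeAssignment", function(object) {
  cat(sprintf("SubtypeAssignment (%s): %d samples in %d subtypes\n",
              object@source, length(object@labels), object@C))
  print(table(subtype = object@labels))
})

setMethod("show", "VBpMKLModel", function(object) {
  cat(sprintf("VBpMKLModel: %d classes, %d kernels, %s after %d iterations\n",
              length(object@classes), length(object@beta),
              if (object@converged) "converged" else "NOT converged",
              length(object@trace)))
  cat("  beta:", paste(sprintf("%.3f", object@beta), collapse = " "), "\n")
})

setMethod("show", "CPSModel", function(object) {
  kind <- if (is.null(object@subtyping)) "raw (no subtyping)"
          else sprintf("%d subtypes", length(object@bundles))
  cat(sprintf("CPSModel: %s, %d classifier bundle(s)\n",
              kind, length(object@bundles)))
})

#' Subtype labels of an assignment
#' @param x a `SubtypeAssignment`.
#' @export
subtypeLabels <- function(x) x@labels

#' Membership scores of an assignment
#' @param x a `SubtypeAssignment`.
#' @export
subtypeScores <- function(x) x@scores

#' Fused similarity matrix of a network object
#' @param x an `AffinityNetwork` or `FusedNetwork`.
#' @export
networkMatrix <- function(x) x@W
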