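#' Read / write a modality matrix
#'
#' Tab-separated text with the sample id in the first column and feature
#' ids in the header; `NA` encodes a missing genotype call.  The
#' round-trip `readModality(writeModality(x))` reproduces the matrix,
#' missing mask included, in the original sample order.
#'
#' @param path file path.
#' @param tag modality tag (`"snp"` matrices are checked for 0/1/2
#'   coding).
#' @return `readModality()`: a numeric samples x features matrix with
#'   dimnames.
#' @export
readModality <- function(path, tag = c("expr", "snp", "roi")) {
  tag <- match.arg(tag)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("modality file needs sample_id + features",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate sample id '%s' in %s", dup, path), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 2,
                       function(v) any(is.na(suppressWarnings(as.numeric(v))) &
                                       !is.na(v) & v != "NA")))[1]
    stop(sprintf("non-numeric cells in column %d of %s", bad + 1, path),
         call. = FALSE)
  }
  rownames(m) <- ids
  if (tag == "snp") {
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      stop(sprintf("snp matrix in %s must be coded 0/1/2/NA", path),
           call. = FALSE)
  }
  m
}

#' @rdname readModality
#' @param x samples x features matrix with dimnames.
#' @export
writeModality <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `label`, `icv` and optionally
#' `subtype`.  Conversion labels accept both codings: `0`/`S-MCI` (stable)
#' and `1`/`P-MCI` (progressive).
#'
#' @param path file path.
#' @return data.frame with `sample_id`, numeric `label`, `icv`, `subtype`.
#' @export
readMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop("metadata needs at least sample_id and label columns", call. = FALSE)
  map <- c("0" = 0, "1" = 1, "S-MCI" = 0, "P-MCI" = 1,
           "SMCI" = 0, "PMCI" = 1)
  lab_chr <- toupper(trimws(as.character(df$label)))
  lab <- unname(map[lab_chr])
  if (any(is.na(lab) & !is.na(df$label)))
    stop(sprintf("unrecognized conversion label '%s'",
                 df$label[which(is.na(lab) & !is.na(df$label))[1]]),
         call. = FALSE)
  df$label <- lab
  if (is.null(df$icv)) df$icv <- NA_real_
  if (is.null(df$subtype)) df$subtype <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Assemble a cohort from modality files and metadata
#'
#' @param snp,expr,roi paths to modality TSVs (any subset; at least one).
#' @param metadata path to the metadata TSV.
#' @return An [MciCohort] with modalities aligned to the metadata sample
#'   order; sample sets must agree exactly (the symmetric difference is
#'   reported otherwise).
#' @export
cohortFromFiles <- function(metadata, snp = NULL, expr = NULL, roi = NULL) {
  meta <- readMetadata(metadata)
  paths <- list(snp = snp, expr = expr, roi = roi)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) stop("at least one modality file required", call. = FALSE)
  mods <- Map(function(p, tag) readModality(p, tag), paths, names(paths))
  for (tag in names(mods)) {
    d1 <- setdiff(meta$sample_id, rownames(mods[[tag]]))
    d2 <- setdiff(rownames(mods[[tag]]), meta$sample_id)
    if (length(d1) || length(d2))
      stop(sprintf("sample sets differ for modality '%s': %s",
                   tag, paste(utils::head(c(d1, d2), 10), collapse = ", ")),
           call. = FALSE)
    mods[[tag]] <- mods[[tag]][meta$sample_id, , drop = FALSE]
  }
  if ("roi" %in% names(mods) && any(is.na(meta$icv)))
    stop("ICV missing for some samples but an ROI modality is present",
         call. = FALSE)
  MciCohort(mods, meta)
}

#' Write a cohort to a directory
#'
#' One TSV per modality, a metadata TSV, and (for synthetic cohorts) the
#' ground truth as JSON.
#'
#' @param cohort an [MciCohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tag in modalityNames(cohort))
    writeModality(modality(cohort, tag), file.path(dir, paste0(tag, ".tsv")))
  utils::write.table(sampleData(cohort), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohortTruth(cohort)
  if (length(tr))
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}

MODEL_SERIAL_VERSION <- 1L

#' Serialize / load a trained model
#'
#' Versioned archive; `loadModel(serializeModel(m))` reproduces predictions
#' bit-identically.  A version mismatch raises an explicit upgrade error.
#'
#' @param model a [CPSModel-class] (or any fitted model object).
#' @param path file path for the archive.
#' @export
serializeModel <- function(model, path) {
  saveRDS(list(serial_version = MODEL_SERIAL_VERSION,
               package_version = as.character(utils::packageVersion("mcicps")),
               model = model),
          path)
  invisible(path)
}

#' @rdname serializeModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$serial_version))
    stop("not an mcicps model archive", call. = FALSE)
  if (obj$serial_version != MODEL_SERIAL_VERSION)
    stop(sprintf("model archive version %d needs upgrading (current %d)",
                 obj$serial_version, MODEL_SERIAL_VERSION), call. = FALSE)
  obj$model
}

#' Read a run configuration from YAML
#'
#' The YAML structure mirrors [runConfig()]; unknown keys are rejected
#' before any computation.
#'
#' @param path YAML file.
#' @return A validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}

#' Import a PLINK additive-coding export
#'
#' Convenience reader for PLINK `.raw` files (`--recode A`): whitespace
#' separated, per-SNP additive dosage columns after the six pedigree
#' columns.
#'
#' @param path `.raw` file path.
#' @return samples x SNPs 0/1/2 matrix with IID rownames.
#' @export
readPlinkRaw <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% colnames(df)))
    stop("not a PLINK .raw export (pedigree columns missing)", call. = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), fixed), drop = FALSE])
  rownames(m) <- as.character(df$IID)
  v <- m[!is.na(m)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    stop("dosages outside 0/1/2: not an additive-coding export", call. = FALSE)
  m
}
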