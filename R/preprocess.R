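#' Preprocessing filters for descriptor tables
#'
#' The standard QSAR cleanup applied before modeling:
#' * `dropQuasiConstant()` removes constant and quasi-constant descriptors —
#'   those whose fraction of values differing from the statistical mode is
#'   below `minVariation` (default 1%). The mode of a continuous column is its
#'   most frequent exact value, ties broken by the smallest value.
#' * `dropAutocorrelated()` removes auto-correlated descriptors: scanning
#'   columns in table order, each retained column knocks out all later columns
#'   with absolute Pearson correlation above `rMax` (default 0.9,
#'   pairwise-complete observations). The earlier column always survives, so
#'   the result is deterministic given the column order.
#' * `imputeMissing()` fills missing values with the column median (binary
#'   columns: the column mode).
#' * `normalizeCap()` z-scores continuous descriptors and clips them to
#'   `[-capSD, +capSD]` (default 2) standard deviations; binary descriptors
#'   pass through. The fitted means/SDs are stored so screening or test tables
#'   are transformed with *training* statistics via [applyNormalizer()] —
#'   capping at transform time is what keeps external compounds inside a broad
#'   applicability domain.
#'
#' Each filter appends its report to `metadata(x)$preprocess`;
#' [preprocessReport()] consolidates them.
#'
#' @param x a [DescriptorSet-class]
#' @param minVariation minimum fraction of off-mode values a column must have
#'   to be kept.
#' @param rMax absolute Pearson correlation above which the later column of a
#'   pair is dropped.
#' @param capSD clip z-scores to `[-capSD, capSD]`.
#' @return the filtered/transformed `DescriptorSet`.
#' @name preprocess
NULL

#' @rdname preprocess
#' @export
dropQuasiConstant <- function(x, minVariation = 0.01) {
  m <- assay(x, "descriptors")        # descriptors x compounds
  if (nrow(m) == 0L) stopf("empty descriptor table")
  n <- ncol(m)
  offFrac <- apply(m, 1L, function(v) sum(v != statMode(v), na.rm = TRUE) / n)
  drop <- offFrac < minVariation
  if (all(drop)) stopf("all %d descriptors are quasi-constant; nothing left to model", nrow(m))
  out <- x[!drop, ]
  md <- metadata(out)
  md$preprocess$quasi_constant <- list(
    dropped = rownames(m)[drop],
    min_variation = minVariation
  )
  metadata(out) <- md
  out
}

#' @rdname preprocess
#' @export
dropAutocorrelated <- function(x, rMax = 0.9) {
  m <- descriptorMatrix(x)            # compounds x descriptors
  p <- ncol(m)
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  keep <- rep(TRUE, p)
  partner <- character(0); droppedNames <- character(0); rDrop <- numeric(0)
  for (j in seq_len(p)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(p) > j & abs(cm[j, ]) > rMax)
    if (length(later)) {
      keep[later] <- FALSE
      droppedNames <- c(droppedNames, colnames(m)[later])
      partner <- c(partner, rep(colnames(m)[j], length(later)))
      rDrop <- c(rDrop, cm[j, later])
    }
  }
  out <- x[keep, ]
  md <- metadata(out)
  md$preprocess$autocorrelated <- list(
    dropped = data.frame(dropped = droppedNames, partner = partner,
                         r = rDrop, stringsAsFactors = FALSE),
    r_max = rMax
  )
  metadata(out) <- md
  out
}

#' @rdname preprocess
#' @export
imputeMissing <- function(x) {
  m <- assay(x, "descriptors")
  nImp <- 0L
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (any(miss)) {
      fill <- if (descriptorKind(x)[i] == "binary") statMode(m[i, ])
              else stats::median(m[i, ], na.rm = TRUE)
      m[i, miss] <- fill
      nImp <- nImp + sum(miss)
    }
  }
  out <- BiocGenerics_replaceAssay(x, m)
  md <- metadata(out)
  md$preprocess$imputation <- list(imputed_cells = nImp)
  metadata(out) <- md
  out
}

## assay<- without importing the generic chain noisily
BiocGenerics_replaceAssay <- function(x, m) {
  SummarizedExperiment::assay(x, "descriptors") <- m
  x
}

#' @rdname preprocess
#' @export
normalizeCap <- function(x, capSD = 2) {
  kind <- descriptorKind(x)
  m <- assay(x, "descriptors")
  cont <- which(kind == "continuous")
  mu <- rowMeans(m[cont, , drop = FALSE], na.rm = TRUE)
  sdv <- apply(m[cont, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  if (any(sdv == 0 | is.na(sdv)))
    stopf("zero-SD continuous descriptors (run dropQuasiConstant first): %s",
          paste(rownames(m)[cont][sdv == 0 | is.na(sdv)], collapse = ", "))
  fit <- list(mean = mu, sd = sdv, cap_sd = capSD,
              continuous = rownames(m)[cont],
              descriptors = rownames(m))
  out <- applyNormalizer(x, fit)
  md <- metadata(out)
  md$normalizer <- fit
  metadata(out) <- md
  out
}

#' Apply a fitted normalize-and-cap transform to a new table
#'
#' @param x a [DescriptorSet-class] (e.g. an external screening library).
#' @param fit fitted parameters from [normalizeCap()] (or
#'   [normalizerParams()] of the training set).
#' @return the transformed `DescriptorSet`, restricted to the fitted
#'   descriptors in their fitted order; every continuous cell is in
#'   `[-cap_sd, cap_sd]`.
#' @export
applyNormalizer <- function(x, fit) {
  missing <- setdiff(fit$descriptors, rownames(x))
  if (length(missing))
    stopf("table lacks fitted descriptors: %s", paste(missing, collapse = ", "))
  x <- x[fit$descriptors, ]
  m <- assay(x, "descriptors")
  cont <- fit$continuous
  z <- (m[cont, , drop = FALSE] - fit$mean[cont]) / fit$sd[cont]
  capped <- sum(abs(z) > fit$cap_sd, na.rm = TRUE)
  z[z > fit$cap_sd] <- fit$cap_sd
  z[z < -fit$cap_sd] <- -fit$cap_sd
  m[cont, ] <- z
  out <- BiocGenerics_replaceAssay(x, m)
  md <- metadata(out)
  md$preprocess$normalize_cap <- list(capped_cells = capped, cap_sd = fit$cap_sd)
  metadata(out) <- md
  out
}

#' @rdname preprocess
#' @export
normalizerParams <- function(x) metadata(x)$normalizer

#' Run the full preprocessing pipeline
#'
#' Quasi-constant filter, auto-correlation filter, median imputation, then
#' normalize-and-cap, in that order.
#'
#' @inheritParams preprocess
#' @export
preprocessDescriptors <- function(x, minVariation = 0.01, rMax = 0.9, capSD = 2) {
  x <- dropQuasiConstant(x, minVariation)
  x <- dropAutocorrelated(x, rMax)
  x <- imputeMissing(x)
  normalizeCap(x, capSD)
}

#' Consolidated preprocessing report
#'
#' @param x a [DescriptorSet-class] that went through the preprocessing
#'   filters.
#' @return a list of class `PreprocessReport`: dropped quasi-constant names,
#'   dropped auto-correlated names with the partner that triggered each drop,
#'   imputed/capped cell counts, kept descriptor names and the parameters
#'   used.
#' @export
preprocessReport <- function(x) {
  pp <- metadata(x)$preprocess
  rep <- list(
    dropped_quasi_constant = pp$quasi_constant$dropped %||% character(),
    dropped_autocorrelated = pp$autocorrelated$dropped %||%
      data.frame(dropped = character(), partner = character(), r = numeric()),
    imputed_cells = pp$imputation$imputed_cells %||% 0L,
    capped_cells = pp$normalize_cap$capped_cells %||% 0L,
    kept = rownames(x),
    parameters = list(
      min_variation = pp$quasi_constant$min_variation %||% NA_real_,
      r_max = pp$autocorrelated$r_max %||% NA_real_,
      cap_sd = pp$normalize_cap$cap_sd %||% NA_real_
    )
  )
  class(rep) <- "PreprocessReport"
  rep
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat(sprintf("PreprocessReport: %d kept; %d quasi-constant and %d auto-correlated dropped; %d cells imputed, %d capped\n",
              length(x$kept), length(x$dropped_quasi_constant),
              nrow(x$dropped_autocorrelated), x$imputed_cells, x$capped_cells))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
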