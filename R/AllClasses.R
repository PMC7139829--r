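#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' DescriptorSet: compounds-by-descriptor data with compound metadata
#'
#' `DescriptorSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a molecular-descriptor table together with per-compound metadata. Following
#' the features-by-samples convention, descriptors are rows and compounds are
#' columns; [descriptorMatrix()] returns the transposed, compounds-by-descriptor
#' view used by learners. `rowData` carries the per-descriptor `kind`
#' (`"continuous"` or `"binary"`); `colData` carries compound name, DILI-concern
#' category, the collapsed binary label (1 = DILI concern), optional maximum
#' daily dose and treatment duration, and exclusion flags. Preprocessing
#' reports and fitted normalization parameters accumulate in `metadata()`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [DescriptorSet()], [preprocessDescriptors()]
#' @export
setClass("DescriptorSet", contains = "SummarizedExperiment")

setValidity("DescriptorSet", function(object) {
  msg <- character()
  if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'descriptors' is required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate compound ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate descriptor names")
  rd <- rowData(object)
  if (!"kind" %in% colnames(rd)) {
    msg <- c(msg, "rowData must have a 'kind' column")
  } else {
    if (!all(rd$kind %in% c("continuous", "binary")))
      msg <- c(msg, "descriptor kind must be 'continuous' or 'binary'")
    if (any(rd$kind == "binary")) {
      bm <- assay(object, "descriptors")[rd$kind == "binary", , drop = FALSE]
      if (!all(bm %in% c(0, 1) | is.na(bm)))
        msg <- c(msg, "binary descriptors may only contain 0, 1 or NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DescriptorSet
#'
#' @param values numeric matrix of descriptor values, compounds in rows and
#'   descriptors in columns (the layout of a descriptor CSV). Row names are
#'   compound ids, column names descriptor names.
#' @param meta `data.frame` (or `DataFrame`) of per-compound metadata aligned
#'   with `rownames(values)`; typically the output of [readDilirank()].
#'   May be `NULL`.
#' @param kind per-descriptor kind, `"continuous"` or `"binary"`. By default
#'   a column whose observed values are all in \{0, 1\} is treated as binary.
#' @return a [DescriptorSet-class] object.
#' @examples
#' fix <- makeMicroFixture()
#' fix
#' @export
DescriptorSet <- function(values, meta = NULL, kind = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cpd_%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stopf("descriptor columns must be named")
  storage.mode(values) <- "double"
  if (is.null(kind)) {
    kind <- apply(values, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
    })
  }
  kind <- rep_len(kind, ncol(values))
  if (is.null(meta)) {
    meta <- DataFrame(row.names = rownames(values))
  } else {
    meta <- as(meta, "DataFrame")
    if (is.null(rownames(meta)) && "compound_id" %in% colnames(meta))
      rownames(meta) <- meta$compound_id
    if (!setequal(rownames(meta), rownames(values)))
      stopf("compound ids of 'values' and 'meta' do not match")
    meta <- meta[rownames(values), , drop = FALSE]
  }
  se <- SummarizedExperiment(
    assays = list(descriptors = t(values)),
    rowData = DataFrame(kind = unname(kind), row.names = colnames(values)),
    colData = meta
  )
  new("DescriptorSet", se)
}

#' @describeIn DescriptorSet-class number of compounds / descriptors
#' @param object,x a `DescriptorSet`
#' @export
setMethod("show", "DescriptorSet", function(object) {
  kind <- descriptorKind(object)
  cat(sprintf("DescriptorSet: %d compounds x %d descriptors (%d continuous, %d binary)\n",
              ncol(object), nrow(object),
              sum(kind == "continuous"), sum(kind == "binary")))
  lab <- compoundLabels(object)
  if (!all(is.na(lab)))
    cat(sprintf("labels: %d DILI concern, %d no concern, %d unlabeled\n",
                sum(lab == 1, na.rm = TRUE), sum(lab == 0, na.rm = TRUE),
                sum(is.na(lab))))
  pp <- metadata(object)$preprocess
  if (!is.null(pp)) cat("preprocessing:", paste(names(pp), collapse = ", "), "\n")
  invisible(NULL)
})
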