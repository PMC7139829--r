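#' Accessors for DescriptorSet
#'
#' `descriptorMatrix()` returns the compounds-by-descriptor numeric matrix (the
#' orientation expected by learners); `descriptorKind()` the per-descriptor
#' kind; `compoundIds()` and `descriptorNames()` the dimension names;
#' `compoundLabels()` the binary DILI label (`NA` when absent or excluded);
#' `compoundMeta()` the compound metadata as a `data.frame`.
#'
#' @param x a [DescriptorSet-class]
#' @return see individual descriptions.
#' @name DescriptorSet-accessors
NULL

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("descriptorMatrix", "DescriptorSet", function(x)
  t(assay(x, "descriptors")))

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("descriptorKind", function(x) standardGeneric("descriptorKind"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("descriptorKind", "DescriptorSet", function(x) {
  k <- rowData(x)$kind
  names(k) <- rownames(x)
  k
})

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("compoundIds", "DescriptorSet", function(x) colnames(x))

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("descriptorNames", "DescriptorSet", function(x) rownames(x))

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("compoundLabels", "DescriptorSet", function(x) {
  cd <- colData(x)
  lab <- if ("label" %in% colnames(cd)) as.integer(cd$label)
         else rep(NA_integer_, ncol(x))
  names(lab) <- colnames(x)
  lab
})

#' @rdname DescriptorSet-accessors
#' @export
setGeneric("compoundMeta", function(x) standardGeneric("compoundMeta"))
#' @rdname DescriptorSet-accessors
#' @export
setMethod("compoundMeta", "DescriptorSet", function(x)
  as.data.frame(colData(x)))

#' Keep a named subset of descriptors
#'
#' @param x a [DescriptorSet-class]
#' @param names descriptor names to keep (order preserved).
#' @return the subsetted `DescriptorSet`.
#' @export
selectDescriptors <- function(x, names) {
  missing <- setdiff(names, rownames(x))
  if (length(missing))
    stopf("descriptors not present: %s", paste(missing, collapse = ", "))
  x[names, ]
}
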