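#' Rescaled Gower dissimilarity matrix
#'
#' Chemical-diversity metric for mixed continuous/binary descriptor tables.
#' Per-column contributions are `|xi - xj| / range` for continuous descriptors
#' (range taken over the whole table) and simple 0/1 mismatch for binary
#' descriptors; the distance between two compounds is the mean contribution
#' over the columns observed in both. The matrix is then rescaled by its
#' global maximum so distances span exactly \[0, 1\]. Note the rescaled Gower
#' dissimilarity is not guaranteed to satisfy the triangle inequality.
#'
#' @param x a [DescriptorSet-class] with at least two compounds.
#' @return symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   compound ids as dimnames; the raw (pre-rescaling) maximum is attached as
#'   attribute `"rawMax"`.
#' @examples
#' gowerMatrix(makeMicroFixture())[1:3, 1:3]
#' @export
gowerMatrix <- function(x) {
  m <- descriptorMatrix(x)
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 compounds")
  kind <- descriptorKind(x)
  contrib <- matrix(0, n, n)
  weight <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- !is.na(v)
    if (kind[j] == "continuous") {
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0)
        stopf("zero-range continuous descriptor '%s' (should have been filtered)",
              colnames(m)[j])
      d <- abs(outer(v, v, "-")) / rng
    } else {
      d <- abs(outer(v, v, "-"))   # 0/1 mismatch
    }
    both <- outer(obs, obs, "&")
    d[!both] <- 0
    contrib <- contrib + d
    weight <- weight + both
  }
  if (any(weight[upper.tri(weight)] == 0))
    stopf("compound pair with no jointly observed descriptors")
  D <- contrib / weight
  diag(D) <- 0
  rawMax <- max(D)
  if (rawMax > 0) D <- D / rawMax
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "rawMax") <- rawMax
  D
}

#' Summarize a dissimilarity matrix per compound
#'
#' Per-compound nearest, median and maximum scaled distance (diagonal
#' excluded) plus pooled quartiles of the per-compound medians — the usual way
#' to read the chemical diversity of a modeling set.
#'
#' @param D symmetric dissimilarity matrix, e.g. from [gowerMatrix()].
#' @return list with `perCompound` (`data.frame`: `compound_id`, `nearest`,
#'   `median`, `max`) and `pooled` (quartiles of the per-compound medians).
#' @export
diversitySummary <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stopf("need at least 2 compounds")
  offdiag <- function(i) D[i, -i]
  per <- data.frame(
    compound_id = rownames(D) %||% as.character(seq_len(n)),
    nearest = vapply(seq_len(n), function(i) min(offdiag(i)), 0),
    median = vapply(seq_len(n), function(i) stats::median(offdiag(i)), 0),
    max = vapply(seq_len(n), function(i) max(offdiag(i)), 0),
    stringsAsFactors = FALSE
  )
  list(perCompound = per,
       pooled = stats::quantile(per$median, c(0.25, 0.5, 0.75), names = TRUE))
}
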