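## Internal helpers shared across modules.

#' Derive a child RNG seed from a parent seed and a stream index
#'
#' Keeps all derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#' @noRd
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629L + 1)
}

#' Evaluate an expression under a local, seeded RNG state
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Rank-based AUC (Mann-Whitney statistic) of a score for a 0/1 outcome;
## average ranks handle ties. NA scores are dropped pairwise with their labels.
rankAUC <- function(score, label) {
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Statistical mode of a vector: most frequent exact value, ties broken by the
## smallest value. NAs ignored.
statMode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[tab == max(tab)][1L]  # table() sorts numerically, first hit is smallest
}

## Equal-frequency discretization into at most nbins bins. Binary or
## low-cardinality vectors are passed through as their own categories.
equalFreqBins <- function(x, nbins = 5L) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= nbins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nbins + 1L),
                               na.rm = TRUE, names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(x))
  cut(x, breaks = br, include.lowest = TRUE)
}

## Shannon entropy (log2) of a factor / contingency margin.
entropyOf <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Squared Euclidean cross-distance matrix between rows of A and rows of B.
crossDist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
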