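## Outlier detection and applicability-domain (AD) assessment.
## All distances are Euclidean on the normalized-and-capped descriptor table.

asX <- function(x) {
  m <- if (is(x, "DescriptorSet")) descriptorMatrix(x) else as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}

#' Isolation-forest anomaly scores
#'
#' Standard isolation forest: random binary trees isolate points by recursive
#' random axis-parallel splits; the anomaly score of a point is
#' `s(x) = 2^(-E[h(x)] / c(psi))` where `h` is the path length, `psi` the
#' subsample size and `c(.)` the average path length of an unsuccessful BST
#' search. Scores lie in (0, 1); isolated points score close to 1, while
#' unremarkable members of a homogeneous dataset typically score around
#' 0.3-0.55.
#'
#' @param x a [DescriptorSet-class] or numeric matrix (compounds in rows).
#' @param nTrees number of isolation trees (default 100).
#' @param sampleSize subsample size per tree (default `min(256, n)`).
#' @param seed RNG seed; scores are reproducible for a fixed seed.
#' @param flagThreshold scores above this are flagged (default 0.7).
#' @return an `OutlierReport` list: `method`, named `score`, `flagged` ids,
#'   `policy`.
#' @export
iforestScores <- function(x, nTrees = 100L, sampleSize = NULL, seed = 1L,
                          flagThreshold = 0.7) {
  X <- asX(x)
  n <- nrow(X)
  if (n < 2L) stopf("need at least 2 compounds")
  psi <- min(sampleSize %||% 256L, n)
  maxDepth <- ceiling(log2(psi))
  trees <- withSeed(childSeed(seed, 11L), {
    lapply(seq_len(nTrees), function(t)
      growITree(X, sample.int(n, psi), 0L, maxDepth))
  })
  paths <- matrix(0, n, nTrees)
  for (t in seq_len(nTrees))
    for (i in seq_len(n)) paths[i, t] <- iPathLength(trees[[t]], X[i, ])
  score <- 2^(-rowMeans(paths) / cBST(psi))
  names(score) <- rownames(X)
  structure(list(method = "iforest", score = score,
                 flagged = names(score)[score > flagThreshold],
                 policy = sprintf("score > %.2f", flagThreshold)),
            class = "OutlierReport")
}

growITree <- function(X, idx, depth, maxDepth) {
  n <- length(idx)
  if (n <= 1L || depth >= maxDepth) return(list(size = n))
  sub <- X[idx, , drop = FALSE]
  rng <- apply(sub, 2L, range)
  cand <- which(rng[2L, ] > rng[1L, ])
  if (!length(cand)) return(list(size = n))
  q <- if (length(cand) == 1L) cand else sample(cand, 1L)
  sp <- stats::runif(1L, rng[1L, q], rng[2L, q])
  left <- idx[sub[, q] < sp]
  list(q = q, sp = sp,
       left = growITree(X, left, depth + 1L, maxDepth),
       right = growITree(X, setdiff(idx, left), depth + 1L, maxDepth))
}

iPathLength <- function(node, xrow, depth = 0) {
  while (is.null(node$size)) {
    node <- if (xrow[node$q] < node$sp) node$left else node$right
    depth <- depth + 1
  }
  depth + cBST(node$size)
}

## Average path length of an unsuccessful binary-search-tree lookup.
cBST <- function(n) {
  if (n < 2) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("OutlierReport[%s]: %d compounds scored, %d flagged (%s); score range %.3f-%.3f\n",
              x$method, length(x$score), length(x$flagged), x$policy,
              min(x$score), max(x$score)))
  invisible(x)
}

#' Subspace outlier detection (SOD)
#'
#' For each compound, a reference set of `refSize` points is chosen by
#' shared-nearest-neighbor similarity (overlap of `kNeighbors`-NN lists). The
#' reference set defines an axis-parallel subspace: dimensions whose reference
#' variance is below `alpha` times the mean reference variance are the
#' relevant ones, and the score is the distance of the compound to the
#' reference mean inside that subspace, normalized by its dimensionality.
#' The top `ceiling(frac * n)` scores are flagged as outliers.
#'
#' @inheritParams iforestScores
#' @param kNeighbors neighborhood size for the shared-nearest-neighbor
#'   similarity (default 20).
#' @param refSize reference-set size (default 10).
#' @param alpha variance-selection factor (default 0.8).
#' @param frac fraction of the dataset to flag (default 0.05).
#' @return an `OutlierReport` (see [iforestScores()]).
#' @export
sodOutliers <- function(x, kNeighbors = 20L, refSize = 10L, alpha = 0.8,
                        frac = 0.05) {
  X <- asX(x)
  n <- nrow(X)
  if (frac <= 0 || frac >= 1) stopf("frac must be in (0, 1)")
  if (n <= kNeighbors) stopf("need more compounds than kNeighbors")
  kNeighbors <- min(kNeighbors, n - 1L)
  refSize <- min(refSize, n - 1L)
  D <- crossDist(X, X); diag(D) <- Inf
  A <- matrix(0, n, n)   # neighbor indicator; SNN similarity = A %*% t(A)
  for (i in seq_len(n)) A[i, order(D[i, ])[seq_len(kNeighbors)]] <- 1
  SNN <- tcrossprod(A)
  score <- numeric(n)
  for (i in seq_len(n)) {
    snn <- SNN[i, ]
    snn[i] <- -1
    ref <- order(-snn, seq_len(n))[seq_len(refSize)]
    mu <- colMeans(X[ref, , drop = FALSE])
    v <- apply(X[ref, , drop = FALSE], 2L, stats::var)
    rel <- which(v < alpha * mean(v))
    if (!length(rel)) rel <- which.min(v)
    score[i] <- sqrt(sum((X[i, rel] - mu[rel])^2) / length(rel))
  }
  names(score) <- rownames(X)
  nFlag <- ceiling(frac * n)
  flagged <- names(score)[order(-score, seq_len(n))[seq_len(nFlag)]]
  structure(list(method = "sod", score = score, flagged = flagged,
                 policy = sprintf("top %.0f%% (%d of %d)", 100 * frac, nFlag, n)),
            class = "OutlierReport")
}

#' kNN-threshold applicability domain (three-stage heuristic)
#'
#' Stage 1 fixes the neighborhood size `k` (default `ceiling(sqrt(n))`, a
#' cheap deterministic choice; pass `k` to override). Stage 2 gives every
#' training compound its own decision threshold: the mean distance to its `k`
#' nearest training neighbors. Stage 3 declares a test compound in-domain iff
#' its distance to at least one training compound is within that compound's
#' threshold — each new observation thus faces individual decision
#' thresholds rather than one global cutoff.
#'
#' @param train,test [DescriptorSet-class]s or matrices on the same
#'   descriptors; `test` must already be transformed with the training
#'   normalizer.
#' @param k neighborhood size; `NULL` for the default.
#' @param thresholds optional precomputed per-training-compound thresholds
#'   (stage 2); supplying them fixes the decision surface, e.g. when deleting
#'   training compounds without refitting. Note that with refit thresholds,
#'   deleting a training compound can *enlarge* the in-domain set (the
#'   survivors' k-th neighbors move outward); holding thresholds fixed makes
#'   deletion strictly shrinking.
#' @return `data.frame` with `id`, `method` (`"knn_threshold"`), `score`
#'   (`min_i(d(test, train_i) - t_i)`; non-positive = inside) and `in_domain`.
#' @export
adKnnThreshold <- function(train, test, k = NULL, thresholds = NULL) {
  Tr <- asX(train); Te <- asX(test)
  n <- nrow(Tr)
  k <- k %||% ceiling(sqrt(n))
  if (k >= n) stopf("k must be smaller than the training-set size")
  if (is.null(thresholds)) {
    Dtt <- crossDist(Tr, Tr); diag(Dtt) <- Inf
    thresh <- apply(Dtt, 1L, function(d) mean(sort(d)[seq_len(k)]))
  } else {
    if (length(thresholds) != n)
      stopf("thresholds must have one entry per training compound")
    thresh <- thresholds
  }
  Dte <- crossDist(Te, Tr)
  slack <- sweep(Dte, 2L, thresh, "-")
  score <- apply(slack, 1L, min)
  data.frame(id = rownames(Te) %||% as.character(seq_len(nrow(Te))),
             method = "knn_threshold", score = score,
             in_domain = score <= 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

## k-distance and density over a distance matrix row (Inf-masked self).
kDistOf <- function(drow, k) sort(drow)[k]

#' INFLO applicability-domain scores
#'
#' Influenced Outlierness: the local density of an observation
#' (`1 / k-distance`) is compared with the mean density over its influence
#' space — the union of its k-nearest neighbors and its reverse k-nearest
#' neighbors in the training set. Interior points of a uniform cloud score
#' about 1; isolated points score well above 1. A compound is in-domain when
#' its score is at most `threshold` (default 1.2; the score is always
#' reported raw).
#'
#' @inheritParams adKnnThreshold
#' @param k neighborhood size.
#' @param threshold in-domain cutoff on the score.
#' @return `data.frame` with `id`, `method` (`"inflo"`), `score`,
#'   `in_domain`.
#' @export
infloScores <- function(train, test = NULL, k = 5L, threshold = 1.2) {
  Tr <- asX(train)
  n <- nrow(Tr)
  if (n <= k) stopf("need more training compounds than k")
  floorD <- 1e-12
  Dtt <- crossDist(Tr, Tr); diag(Dtt) <- Inf
  kdTrain <- apply(Dtt, 1L, kDistOf, k = k)
  densTrain <- 1 / pmax(kdTrain, floorD)
  selfScoring <- is.null(test)
  Te <- if (selfScoring) Tr else asX(test)
  Dte <- if (selfScoring) Dtt else crossDist(Te, Tr)
  score <- numeric(nrow(Te))
  for (i in seq_len(nrow(Te))) {
    d <- Dte[i, ]
    kd <- kDistOf(d, k)
    dens <- 1 / pmax(kd, floorD)
    knn <- order(d)[seq_len(k)]
    rnn <- which(d <= kdTrain + floorD & is.finite(d))
    infl <- union(knn, rnn)
    score[i] <- mean(densTrain[infl]) / dens
  }
  data.frame(id = rownames(Te) %||% as.character(seq_len(nrow(Te))),
             method = "inflo", score = score, in_domain = score <= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' COF applicability-domain scores
#'
#' Connectivity-based Outlier Factor: distinguishes "low density" from
#' "isolativity" through chaining distances. The average chaining distance of
#' a point is the weighted mean of the edge lengths along the set-based
#' nearest path greedily linking the point through its k-neighborhood (later
#' edges weighted less); the score is the point's average chaining distance
#' divided by the mean over its k neighbors. Points lying *on* a sparse but
#' connected pattern (e.g. a line) score about 1 even though their disc
#' density is low; points off the pattern score above 1.
#'
#' @inheritParams infloScores
#' @return `data.frame` with `id`, `method` (`"cof"`), `score`, `in_domain`.
#' @export
cofScores <- function(train, test = NULL, k = 5L, threshold = 1.2) {
  Tr <- asX(train)
  n <- nrow(Tr)
  if (n <= k) stopf("need more training compounds than k")
  Dtt <- crossDist(Tr, Tr); diag(Dtt) <- Inf
  acTrain <- vapply(seq_len(n), function(i) {
    nb <- order(Dtt[i, ])[seq_len(k)]
    acDist(i, nb, Dtt, selfRow = Dtt[i, ])
  }, 0)
  selfScoring <- is.null(test)
  Te <- if (selfScoring) Tr else asX(test)
  Dte <- if (selfScoring) Dtt else crossDist(Te, Tr)
  score <- numeric(nrow(Te))
  for (i in seq_len(nrow(Te))) {
    nb <- order(Dte[i, ])[seq_len(k)]
    ac <- acDist(0L, nb, Dtt, selfRow = Dte[i, ])
    score[i] <- ac / mean(acTrain[nb])
  }
  data.frame(id = rownames(Te) %||% as.character(seq_len(nrow(Te))),
             method = "cof", score = score, in_domain = score <= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Average chaining distance of a point (distances to training points in
## selfRow) through its neighborhood nb (training indices); Dtt holds
## train-train distances. Greedy set-based nearest path; edge i gets weight
## 2 * (r + 1 - i) / (r * (r + 1)).
acDist <- function(self, nb, Dtt, selfRow) {
  r <- length(nb)
  remaining <- nb
  distToChain <- selfRow[remaining]          # distances from the start point
  edges <- numeric(r)
  for (i in seq_len(r)) {
    j <- which.min(distToChain)
    edges[i] <- distToChain[j]
    newPt <- remaining[j]
    remaining <- remaining[-j]
    distToChain <- distToChain[-j]
    if (length(remaining))
      distToChain <- pmin(distToChain, Dtt[newPt, remaining])
  }
  w <- 2 * (r + 1 - seq_len(r)) / (r * (r + 1))
  sum(w * edges)
}

#' Audit compounds misclassified by the model majority
#'
#' Lists compounds wrongly predicted by more than half of the models,
#' annotated with the number of models misclassifying them and their outlier
#' status under each supplied report — separating "hard because chemically
#' atypical" from "hard despite being ordinary".
#'
#' @param preds compounds-by-models matrix of out-of-fold 0/1 predictions.
#' @param labels true binary labels aligned with `preds` rows.
#' @param reports list of `OutlierReport`s (e.g. from [iforestScores()] and
#'   [sodOutliers()]).
#' @return `data.frame` of misclassified compounds: `compound_id`,
#'   `wrong_by`, `n_models`, one logical column per report method, and
#'   `any_outlier`; the fraction of misclassified compounds flagged by at
#'   least one method is attached as attribute `"flaggedFraction"`.
#' @export
misclassifiedAudit <- function(preds, labels, reports = list()) {
  preds <- as.matrix(preds)
  labels <- as.integer(labels)
  wrong <- preds != labels
  wrongBy <- rowSums(wrong)
  mis <- which(wrongBy > ncol(preds) / 2)
  ids <- rownames(preds) %||% as.character(seq_len(nrow(preds)))
  out <- data.frame(compound_id = ids[mis], wrong_by = wrongBy[mis],
                    n_models = rep(ncol(preds), length(mis)),
                    stringsAsFactors = FALSE)
  anyFlag <- rep(FALSE, length(mis))
  for (rep_ in reports) {
    flag <- out$compound_id %in% rep_$flagged
    out[[paste0("outlier_", rep_$method)]] <- flag
    anyFlag <- anyFlag | flag
  }
  out$any_outlier <- anyFlag
  out <- out[order(-out$wrong_by, out$compound_id), ]
  rownames(out) <- NULL
  attr(out, "flaggedFraction") <-
    if (nrow(out)) mean(out$any_outlier) else NA_real_
  out
}
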