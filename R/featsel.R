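#' Univariate feature-selection filters
#'
#' A registry of filter-style scorers mirroring the families commonly used in
#' QSAR work. Every method consumes a descriptor table plus binary labels and
#' emits a `FeatureScores` object under one contract: a named numeric score
#' per descriptor, higher is better, plus a deterministic ranking (ties broken
#' by descriptor name).
#'
#' Registered methods:
#' * `anova_f` — two-group ANOVA F statistic.
#' * `auc` — distance of the rank AUC from 0.5.
#' * `kruskal_wallis` — Kruskal-Wallis rank-sum statistic (tie-corrected).
#' * `variance` — column variance (unsupervised).
#' * `chi_squared`, `info_gain`, `gain_ratio`, `symmetrical_uncertainty`,
#'   `one_r` — contingency/entropy filters; continuous descriptors are
#'   discretized into 5 equal-frequency bins.
#' * `relief` — ReliefF with 10 neighbors over all instances (Kononenko
#'   variant), range-normalized differences.
#' * `permutation_importance`, `impurity_importance` — random-forest mean
#'   decrease in accuracy / Gini.
#' * `univariate_model_score` — per-descriptor 5-fold cross-validated balanced
#'   accuracy of a single-split decision tree.
#'
#' @name featureSelection
NULL

#' @rdname featureSelection
#' @return `listSelectors()`: character vector of registered method ids.
#' @export
listSelectors <- function() {
  c("anova_f", "auc", "kruskal_wallis", "variance", "chi_squared",
    "info_gain", "gain_ratio", "symmetrical_uncertainty", "one_r", "relief",
    "permutation_importance", "impurity_importance", "univariate_model_score")
}

#' Score descriptors against the binary label
#'
#' @param x a [DescriptorSet-class] or compounds-by-descriptor numeric matrix.
#' @param labels binary labels (0/1); defaults to `compoundLabels(x)`.
#' @param method a registered method id (see [listSelectors()]) or a function
#'   `(matrix, labels) -> named numeric scores` for custom filters.
#' @param seed RNG seed for the stochastic methods (`relief` resolves ties,
#'   `permutation_importance`, `impurity_importance`,
#'   `univariate_model_score`).
#' @return a `FeatureScores` object: `method`, named `scores`, `ranking`
#'   (best first) and `higherIsBetter`.
#' @examples
#' fix <- preprocessDescriptors(makeMicroFixture())
#' scoreFeatures(fix, method = "kruskal_wallis")
#' @export
scoreFeatures <- function(x, labels = NULL, method = "anova_f", seed = 1L) {
  m <- if (is(x, "DescriptorSet")) descriptorMatrix(x) else as.matrix(x)
  if (is.null(labels) && is(x, "DescriptorSet")) labels <- compoundLabels(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(m)) stopf("labels must match the compound count")
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stopf("both classes must be present")
  if (is.function(method)) {
    scores <- method(m, labels)
    id <- "custom"
  } else {
    id <- match.arg(method, listSelectors())
    scorer <- switch(id,
      anova_f = scoreAnovaF, auc = scoreAUC, kruskal_wallis = scoreKruskal,
      variance = function(m, y) apply(m, 2L, stats::var),
      chi_squared = scoreChisq, info_gain = scoreInfoGain,
      gain_ratio = scoreGainRatio,
      symmetrical_uncertainty = scoreSymmetricalUncertainty,
      one_r = scoreOneR, relief = scoreRelief,
      permutation_importance = scoreForestPermutation,
      impurity_importance = scoreForestImpurity,
      univariate_model_score = scoreUnivariateModel)
    scores <- withSeed(childSeed(seed, match(id, listSelectors())),
                       scorer(m, labels))
  }
  names(scores) <- colnames(m)
  ranking <- names(scores)[order(-scores, names(scores))]
  structure(list(method = id, scores = scores, ranking = ranking,
                 higherIsBetter = TRUE),
            class = "FeatureScores")
}

#' @export
print.FeatureScores <- function(x, ...) {
  cat(sprintf("FeatureScores[%s]: %d descriptors; top 5: %s\n", x$method,
              length(x$scores),
              paste(utils::head(x$ranking, 5L), collapse = ", ")))
  invisible(x)
}

scoreAnovaF <- function(m, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  m1 <- colMeans(m[y == 1, , drop = FALSE])
  m0 <- colMeans(m[y == 0, , drop = FALSE])
  gm <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((m[y == 1, , drop = FALSE] - rep(m1, each = n1))^2) +
         colSums((m[y == 0, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ssb / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  f
}

scoreAUC <- function(m, y) {
  abs(apply(m, 2L, rankAUC, label = y) - 0.5)
}

scoreKruskal <- function(m, y) {
  n <- length(y)
  apply(m, 2L, function(v) {
    r <- rank(v)
    h <- 12 / (n * (n + 1)) *
      (sum(r[y == 1])^2 / sum(y == 1) + sum(r[y == 0])^2 / sum(y == 0)) -
      3 * (n + 1)
    ties <- table(v)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr > 0) h / corr else 0
  })
}

contingency <- function(v, y) table(equalFreqBins(v), y)

scoreChisq <- function(m, y) {
  apply(m, 2L, function(v) {
    tab <- contingency(v, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  })
}

infoGainOf <- function(tab) {
  hy <- entropyOf(colSums(tab))
  hx <- entropyOf(rowSums(tab))
  hxy <- entropyOf(as.vector(tab))
  list(ig = hy + hx - hxy, hx = hx, hy = hy)
}

scoreInfoGain <- function(m, y)
  apply(m, 2L, function(v) infoGainOf(contingency(v, y))$ig)

scoreGainRatio <- function(m, y) {
  apply(m, 2L, function(v) {
    g <- infoGainOf(contingency(v, y))
    if (g$hx == 0) 0 else g$ig / g$hx
  })
}

scoreSymmetricalUncertainty <- function(m, y) {
  apply(m, 2L, function(v) {
    g <- infoGainOf(contingency(v, y))
    if (g$hx + g$hy == 0) 0 else 2 * g$ig / (g$hx + g$hy)
  })
}

## OneR: one rule per bin (majority class), score = training accuracy.
scoreOneR <- function(m, y) {
  apply(m, 2L, function(v) {
    tab <- contingency(v, y)
    sum(apply(tab, 1L, max)) / length(y)
  })
}

## ReliefF, k neighbors, all instances; Manhattan distance on
## range-normalized descriptors; two-class weight update.
scoreRelief <- function(m, y, k = 10L) {
  n <- nrow(m); p <- ncol(m)
  rng <- apply(m, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  z <- sweep(m, 2L, apply(m, 2L, min), "-")
  z <- sweep(z, 2L, rng, "/")
  w <- numeric(p)
  priors <- table(y) / n
  for (i in seq_len(n)) {
    diffs <- abs(sweep(z, 2L, z[i, ], "-"))     # n x p normalized diffs
    d <- rowSums(diffs)
    d[i] <- Inf
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls & d < Inf)
      kk <- min(k, length(idx))
      if (kk == 0L) next
      nb <- idx[order(d[idx])[seq_len(kk)]]
      contrib <- colSums(diffs[nb, , drop = FALSE]) / kk
      if (cls == y[i]) {
        w <- w - contrib / n                     # nearest hits
      } else {
        pc <- priors[as.character(cls)] / (1 - priors[as.character(y[i])])
        w <- w + as.numeric(pc) * contrib / n    # nearest misses
      }
    }
  }
  w
}

forestFit <- function(m, y) {
  randomForest::randomForest(m, factor(y, levels = c(0L, 1L)),
                             ntree = 200L, importance = TRUE)
}

scoreForestPermutation <- function(m, y)
  forestFit(m, y)$importance[, "MeanDecreaseAccuracy"]

scoreForestImpurity <- function(m, y)
  forestFit(m, y)$importance[, "MeanDecreaseGini"]

## Per-descriptor resampled score: 5-fold CV balanced accuracy of a
## single-variable decision tree.
scoreUnivariateModel <- function(m, y, folds = 5L) {
  n <- nrow(m)
  fold <- sample(rep_len(seq_len(folds), n))
  apply(m, 2L, function(v) {
    pred <- integer(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      df <- data.frame(v = v[tr], y = factor(y[tr], levels = c(0L, 1L)))
      fitT <- rpart::rpart(y ~ v, data = df, method = "class",
                           control = rpart::rpart.control(cp = 0.01, minsplit = 5L))
      pred[!tr] <- as.integer(as.character(
        stats::predict(fitT, data.frame(v = v[!tr]), type = "class")))
    }
    tpr <- sum(pred == 1 & y == 1) / sum(y == 1)
    tnr <- sum(pred == 0 & y == 0) / sum(y == 0)
    (tpr + tnr) / 2
  })
}

#' Select the top-k descriptors from a FeatureScores
#'
#' Ties at the boundary are broken by descriptor-name lexicographic order
#' (already folded into the ranking).
#'
#' @param scores a `FeatureScores` from [scoreFeatures()].
#' @param k number of descriptors to keep (default 50).
#' @return character vector of descriptor names, best first.
#' @export
selectTopK <- function(scores, k = 50L) {
  stopifnot(inherits(scores, "FeatureScores"))
  if (k <= 0L) stopf("k must be positive")
  if (k > length(scores$ranking))
    stopf("k = %d exceeds the %d scored descriptors", k, length(scores$ranking))
  scores$ranking[seq_len(k)]
}

#' Frequency of descriptors among each method's top-5
#'
#' Counts, for every descriptor, how many selection methods rank it among
#' their `top` most important features, and expresses the count as a
#' percentage of the number of methods — the usual way to read off which
#' descriptors are consistently associated with the outcome. By default only
#' descriptors occurring at least twice are reported.
#'
#' @param scoresList list of `FeatureScores`, one per method.
#' @param top size of each method's head to inspect (default 5).
#' @param minCount minimum number of methods a descriptor must appear for
#'   (default 2).
#' @return `data.frame` with `descriptor`, `count`, `percentage`, sorted by
#'   count descending (ties by name).
#' @export
topFeatureFrequency <- function(scoresList, top = 5L, minCount = 2L) {
  if (length(scoresList) == 0L) stopf("need at least one method's scores")
  heads <- unlist(lapply(scoresList, function(s) utils::head(s$ranking, top)))
  tab <- table(heads)
  out <- data.frame(descriptor = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- round(100 * out$count / length(scoresList), 2)
  out <- out[out$count >= minCount, , drop = FALSE]
  out <- out[order(-out$count, out$descriptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
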