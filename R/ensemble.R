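#' Majority vote over base-model predictions
#'
#' A compound is labeled toxic when at least half of the models vote toxic;
#' the exact-tie convention (tie -> toxic) is precautionary, chosen so a
#' hepatotoxic compound is not mislabeled as innocuous by a split jury.
#'
#' @param preds compounds-by-models matrix of 0/1 predictions.
#' @return integer vector of 0/1 ensemble labels.
#' @export
voteMajority <- function(preds) {
  preds <- as.matrix(preds)
  if (ncol(preds) < 1L) stopf("need at least one model")
  if (anyNA(preds)) stopf("compound missing from a model's predictions")
  as.integer(2 * rowSums(preds) >= ncol(preds))
}

#' Pool per-model probabilities and threshold them
#'
#' Pools each compound's predicted probabilities across models with the mean
#' or the median (models without a probability for a compound are skipped) and
#' labels the compound toxic when the pooled probability is `>= threshold`
#' (boundary -> toxic, same precautionary convention as [voteMajority()]).
#'
#' @param probs compounds-by-models matrix of probabilities (may contain `NA`
#'   for probability-free models).
#' @param stat `"mean"` or `"median"`.
#' @param threshold decision threshold in (0, 1); 0.5 default, 0.67 supported.
#' @return `data.frame` with `prob` (pooled) and `label`.
#' @export
poolProbabilities <- function(probs, stat = c("mean", "median"),
                              threshold = 0.5) {
  stat <- match.arg(stat)
  probs <- as.matrix(probs)
  if (ncol(probs) < 1L) stopf("need at least one probability-emitting model")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  nAvail <- rowSums(!is.na(probs))
  if (any(nAvail == 0L))
    stopf("compound with zero available probabilities: %s",
          paste(utils::head(rownames(probs)[nAvail == 0L]), collapse = ", "))
  pooled <- apply(probs, 1L, stat, na.rm = TRUE)
  data.frame(prob = pooled, label = as.integer(pooled >= threshold),
             row.names = rownames(probs))
}

#' Out-of-fold prediction or probability matrix from nested-CV results
#'
#' @param results named list of [runNestedCV()] results over the same fold
#'   plan.
#' @param what `"pred"` for binary predictions, `"prob"` for probabilities.
#' @return compounds-by-models matrix.
#' @export
predictionMatrix <- function(results, what = c("pred", "prob")) {
  what <- match.arg(what)
  cols <- lapply(results, function(r) r$predictions[[what]])
  m <- do.call(cbind, cols)
  rownames(m) <- results[[1L]]$predictions$compound_id
  colnames(m) <- names(results)
  m
}

#' Stack nested-CV results into an ensemble and score it
#'
#' Convenience wrapper: builds the out-of-fold prediction/probability matrix
#' from a list of [runNestedCV()] results, applies the requested stacking
#' scheme and scores the stacked predictions against the true labels.
#'
#' @param results named list of `NestedCVResult`s (e.g. the selected models).
#' @param scheme `"majority"`, or `"pooled_prob"`.
#' @param stat,threshold pooling statistic and decision threshold for
#'   `"pooled_prob"`.
#' @return list with `label`, `prob` (pooled probability or `NULL`), and
#'   `summary` (a `PerformanceSummary`).
#' @export
stackModels <- function(results, scheme = c("majority", "pooled_prob"),
                        stat = "mean", threshold = 0.5) {
  scheme <- match.arg(scheme)
  labels <- results[[1L]]$predictions$label
  if (scheme == "majority") {
    lab <- voteMajority(predictionMatrix(results, "pred"))
    list(label = lab, prob = NULL, summary = computeMetrics(lab, labels))
  } else {
    pm <- predictionMatrix(results, "prob")
    pm <- pm[, colSums(!is.na(pm)) > 0, drop = FALSE]
    pooled <- poolProbabilities(pm, stat = stat, threshold = threshold)
    list(label = pooled$label, prob = pooled$prob,
         summary = computeMetrics(pooled$label, labels, prob = pooled$prob))
  }
}

#' Meta-model over out-of-fold base predictions
#'
#' Stacking scheme (c): a second-level classifier trained on the base models'
#' out-of-fold predictions. The `nBase` most informative base-model columns
#' are chosen by a feature-selection filter applied to the prediction matrix;
#' maximum daily dose and treatment duration can be appended as extra
#' features. The meta-learner is evaluated by a fresh stratified
#' cross-validation over compounds, repeated over `seeds`, and reported as
#' mean and SD per metric. Constant prediction columns are dropped with a
#' warning. Using out-of-fold predictions as the feature matrix is what keeps
#' the meta-model leakage-safe.
#'
#' @param results named list of `NestedCVResult`s (base models).
#' @param metaLearner learner id for the second level (default
#'   `"random_forest"`; `"svm_radial"`, `"knn"`, `"naive_bayes"`, `"cart"`
#'   are the usual alternatives).
#' @param selector filter used to pick base-model columns (default `"one_r"`).
#' @param nBase number of base models entering the meta-model (default 50;
#'   exceeding the number of available models is an error).
#' @param useProb stack probabilities instead of binary predictions.
#' @param includeDose,includeDuration append dose / duration columns taken
#'   from `meta`.
#' @param meta compound metadata (`data.frame` with `max_daily_dose`,
#'   `duration_days`) aligned with the compounds; required when dose or
#'   duration is included.
#' @param folds evaluation folds (default 10).
#' @param seeds integer vector of seeds for repeated runs.
#' @return a `MetaModelResult` list: `perSeed` (`data.frame` of metrics per
#'   seed), `mean`, `sd`, `baseModels` (columns used), `metaLearner`.
#' @export
buildMetaModel <- function(results, metaLearner = "random_forest",
                           selector = "one_r", nBase = 50L, useProb = FALSE,
                           includeDose = TRUE, includeDuration = FALSE,
                           meta = NULL, folds = 10L, seeds = 1:5) {
  pm <- predictionMatrix(results, if (useProb) "prob" else "pred")
  labels <- results[[1L]]$predictions$label
  keep <- apply(pm, 2L, function(v) length(unique(v[!is.na(v)])) > 1L)
  if (any(!keep)) {
    warnf("dropping %d constant base-model columns", sum(!keep))
    pm <- pm[, keep, drop = FALSE]
  }
  if (ncol(pm) == 0L) stopf("no usable base-model columns")
  if (nBase > ncol(pm))
    stopf("nBase = %d exceeds the %d available base models", nBase, ncol(pm))
  if (nBase < ncol(pm)) {
    sc <- scoreFeatures(pm, labels, method = selector, seed = seeds[1L])
    pm <- pm[, selectTopK(sc, nBase), drop = FALSE]
  }
  X <- pm
  if (includeDose) {
    if (is.null(meta) || is.null(meta$max_daily_dose))
      stopf("includeDose = TRUE needs 'meta' with a max_daily_dose column")
    X <- cbind(X, max_daily_dose = log1p(meta$max_daily_dose))
  }
  if (includeDuration) {
    if (is.null(meta) || is.null(meta$duration_days))
      stopf("includeDuration = TRUE needs 'meta' with a duration_days column")
    X <- cbind(X, duration_days = log1p(meta$duration_days))
  }
  learner <- getLearner(metaLearner)
  rows <- lapply(seeds, function(s) {
    fold <- innerFolds(labels, folds, childSeed(s, 21L))
    pred <- rep(NA_integer_, length(labels)); prob <- rep(NA_real_, length(labels))
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- withSeed(childSeed(s, 22L + f),
                        learner$fit(X[tr, , drop = FALSE], labels[tr], NULL))
      out <- learner$predict(model, X[!tr, , drop = FALSE])
      pred[!tr] <- out$label
      if (!is.null(out$prob)) prob[!tr] <- out$prob
    }
    sm <- computeMetrics(pred, labels,
                         prob = if (all(is.na(prob))) NULL else prob)
    data.frame(seed = s, BA = sm$BA, MMCE = sm$MMCE, TPR = sm$TPR,
               TNR = sm$TNR, PPV = sm$PPV, AUC = sm$AUC)
  })
  perSeed <- do.call(rbind, rows)
  metrics <- c("BA", "MMCE", "TPR", "TNR", "PPV", "AUC")
  structure(list(
    perSeed = perSeed,
    mean = vapply(metrics, function(k) mean(perSeed[[k]]), 0),
    sd = vapply(metrics, function(k) stats::sd(perSeed[[k]]), 0),
    baseModels = colnames(pm), metaLearner = if (is.list(metaLearner))
      "custom" else metaLearner
  ), class = "MetaModelResult")
}

#' @export
print.MetaModelResult <- function(x, ...) {
  cat(sprintf("MetaModelResult[%s]: %d base models, %d seeded runs; BA %.3f +/- %.3f, TPR %.3f, TNR %.3f\n",
              x$metaLearner, length(x$baseModels), nrow(x$perSeed),
              x$mean[["BA"]], x$sd[["BA"]], x$mean[["TPR"]], x$mean[["TNR"]]))
  invisible(x)
}

#' Refit selected models on the full training set for screening
#'
#' Freezes an ensemble: for each spec, feature selection is rerun on the full
#' training table, hyperparameters are tuned by a stratified inner CV, and the
#' final model is fit on all training compounds. The training normalizer is
#' stored so external libraries are transformed with training statistics.
#'
#' @param x the preprocessed training [DescriptorSet-class].
#' @param specs list of [modelSpec()]s (typically the selected models).
#' @param inner inner folds for the tuning pass (default 5).
#' @return a `FrozenEnsemble` list of fitted models plus the normalizer
#'   parameters.
#' @export
freezeEnsemble <- function(x, specs, inner = 5L) {
  m <- descriptorMatrix(x)
  y <- compoundLabels(x)
  models <- lapply(specs, function(spec) {
    learner <- getLearner(spec$learner)
    sc <- scoreFeatures(m, y, method = spec$selector, seed = spec$seed)
    feats <- selectTopK(sc, min(spec$nFeatures, length(sc$ranking)))
    params <- tuneLearner(learner, m[, feats, drop = FALSE], y, inner,
                          spec$nSearchDraws, childSeed(spec$seed, 77L))
    fit <- withSeed(childSeed(spec$seed, 78L),
                    learner$fit(m[, feats, drop = FALSE], y, params))
    list(key = spec$key, learner = learner, model = fit, features = feats)
  })
  names(models) <- vapply(specs, `[[`, "", "key")
  structure(list(models = models, normalizer = normalizerParams(x)),
            class = "FrozenEnsemble")
}

#' Screen an external compound library
#'
#' Applies a frozen ensemble to a descriptor table of untested compounds: the
#' library is transformed with the *training* normalize-and-cap parameters,
#' every model predicts, probabilities are pooled (mean and median both
#' reported; `stat` decides the labeling), and compounds are ranked by
#' ascending pooled probability — the head of the report is the candidates
#' most confidently predicted free of liver toxicity. Per-compound
#' applicability-domain flags can be attached.
#'
#' @param library a [DescriptorSet-class] for the external library (raw
#'   descriptor values; it is normalized here).
#' @param ensemble a [freezeEnsemble()] result.
#' @param stat pooling statistic used for the labels (`"mean"` or
#'   `"median"`).
#' @param threshold decision threshold (default 0.5).
#' @param ad optional `data.frame` of AD verdicts (`id`, `method`,
#'   `in_domain`) from the applicability functions; summarized per compound.
#' @return a `ScreeningReport` list: `table` (`data.frame`: `compound_id`,
#'   `prob_mean`, `prob_median`, `prob`, `label`, `rank`, and `n_in_ad` when
#'   `ad` is given) sorted ascending by pooled probability, and
#'   `fractionNonToxic` for both pooling statistics.
#' @export
screenLibrary <- function(library, ensemble, stat = c("mean", "median"),
                          threshold = 0.5, ad = NULL) {
  stat <- match.arg(stat)
  stopifnot(inherits(ensemble, "FrozenEnsemble"))
  lib <- applyNormalizer(library, ensemble$normalizer)
  m <- descriptorMatrix(lib)
  probs <- vapply(ensemble$models, function(mod) {
    out <- mod$learner$predict(mod$model, m[, mod$features, drop = FALSE])
    if (is.null(out$prob)) rep(NA_real_, nrow(m)) else out$prob
  }, numeric(nrow(m)))
  rownames(probs) <- rownames(m)
  pooledMean <- poolProbabilities(probs, "mean", threshold)
  pooledMedian <- poolProbabilities(probs, "median", threshold)
  chosen <- if (stat == "mean") pooledMean else pooledMedian
  tab <- data.frame(compound_id = rownames(m),
                    prob_mean = pooledMean$prob,
                    prob_median = pooledMedian$prob,
                    prob = chosen$prob, label = chosen$label,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$prob, tab$compound_id), ]
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(ad)) {
    cnt <- tapply(ad$in_domain, ad$id, sum)
    tab$n_in_ad <- as.integer(cnt[tab$compound_id])
  }
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    fractionNonToxic = c(mean = mean(pooledMean$label == 0L),
                         median = mean(pooledMedian$label == 0L)),
    threshold = threshold, stat = stat
  ), class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat(sprintf("ScreeningReport: %d compounds at threshold %.2f; predicted non-toxic: %.2f%% (mean pooling) / %.2f%% (median pooling)\n",
              nrow(x$table), x$threshold, 100 * x$fractionNonToxic[["mean"]],
              100 * x$fractionNonToxic[["median"]]))
  invisible(x)
}
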