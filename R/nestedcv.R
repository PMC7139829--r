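#' Stratified fold plan for nested cross-validation
#'
#' Assigns every compound to one of `outer` folds, stratified by label:
#' within-class shuffled indices are dealt cyclically over the folds, so fold
#' sizes differ by at most one overall and per class. Inner folds are defined
#' per outer-training set at run time, seeded deterministically from
#' `(seed, outer fold)`.
#'
#' @param labels binary labels (0/1).
#' @param outer,inner number of outer / inner folds (defaults 10 and 5).
#' @param seed RNG seed; the same seed reproduces the same assignment.
#' @return a `FoldPlan` object: `n`, `outer`, `inner`, `assignment`
#'   (integer fold per compound), `seed`.
#' @export
makeFoldPlan <- function(labels, outer = 10L, inner = 5L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < outer) stopf("n = %d is smaller than %d outer folds", n, outer)
  counts <- table(labels)
  if (length(counts) < 2L) stopf("both classes must be present")
  if (any(counts < outer))
    stopf("class with %d members cannot be spread over %d folds; use fewer folds",
          min(counts), outer)
  assignment <- integer(n)
  withSeed(childSeed(seed, 1L), {
    ord <- c(sample(which(labels == 0L)), sample(which(labels == 1L)))
    assignment[ord] <- rep_len(sample(seq_len(outer)), n)
  })
  names(assignment) <- names(labels)
  structure(list(n = n, outer = as.integer(outer), inner = as.integer(inner),
                 assignment = assignment, seed = as.integer(seed)),
            class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat(sprintf("FoldPlan: %d compounds, %d outer x %d inner folds (seed %d); fold sizes %s\n",
              x$n, x$outer, x$inner, x$seed,
              paste(tabulate(x$assignment, x$outer), collapse = "/")))
  invisible(x)
}

## Stratified inner-fold assignment for one outer-training set.
innerFolds <- function(labels, k, seed) {
  n <- length(labels)
  assignment <- integer(n)
  withSeed(seed, {
    ord <- c(sample(which(labels == 0L)), sample(which(labels == 1L)))
    assignment[ord] <- rep_len(sample(seq_len(k)), n)
  })
  assignment
}

#' Specification of one (selector, learner, k-features) model
#'
#' @param learner learner id from [listLearners()] (or a custom learner list
#'   with `fit`/`predict`/`sample` entries).
#' @param selector feature-selection method id from [listSelectors()] (or a
#'   scoring function, see [scoreFeatures()]).
#' @param nFeatures number of descriptors each model uses (default 50).
#' @param nSearchDraws random hyperparameter draws in the inner loop
#'   (default 20; ignored for learners without tunable hyperparameters).
#' @param seed RNG seed for selection, search and stochastic learners.
#' @param key model key; defaults to `"<selector>+<learner>"`.
#' @return a `ModelSpec` list.
#' @export
modelSpec <- function(learner, selector = "anova_f", nFeatures = 50L,
                      nSearchDraws = 20L, seed = 1L, key = NULL) {
  if (is.null(key))
    key <- paste0(if (is.function(selector)) "custom" else selector, "+",
                  if (is.list(learner)) "custom" else learner)
  structure(list(learner = learner, selector = selector,
                 nFeatures = as.integer(nFeatures),
                 nSearchDraws = as.integer(nSearchDraws),
                 seed = as.integer(seed), key = key),
            class = "ModelSpec")
}

#' Nested cross-validation of one model specification
#'
#' For each outer fold: feature selection to `nFeatures` descriptors and a
#' random hyperparameter search (maximizing inner-CV balanced accuracy over
#' `inner` folds) are run on the outer-training compounds only; the winning
#' configuration is refit on the full outer-training set and predicts the
#' held-out fold. Out-of-fold predictions therefore come from models that
#' never saw the compound during selection, tuning or fitting.
#'
#' @param x a preprocessed [DescriptorSet-class] with labels.
#' @param spec a [modelSpec()].
#' @param plan a [makeFoldPlan()] on the same compounds.
#' @return a `NestedCVResult` list: `predictions` (`data.frame` with
#'   `compound_id`, `fold`, `label`, `pred`, `prob`), `pooled` and
#'   `foldMean` `PerformanceSummary`s, `perFold` summaries, `features`
#'   (selected names per fold), `failedFolds`, `valid` (FALSE when more than
#'   two folds failed), `spec`.
#' @export
runNestedCV <- function(x, spec, plan) {
  stopifnot(inherits(spec, "ModelSpec"), inherits(plan, "FoldPlan"))
  m <- descriptorMatrix(x)
  y <- compoundLabels(x)
  if (plan$n != nrow(m)) stopf("fold plan does not match the compound count")
  learner <- getLearner(spec$learner)
  pred <- rep(NA_integer_, plan$n); prob <- rep(NA_real_, plan$n)
  perFold <- vector("list", plan$outer)
  features <- vector("list", plan$outer)
  failed <- integer(0)
  for (f in seq_len(plan$outer)) {
    test <- which(plan$assignment == f)
    train <- which(plan$assignment != f)
    foldSeed <- childSeed(spec$seed, 100L + f)
    res <- tryCatch({
      sc <- scoreFeatures(m[train, , drop = FALSE], y[train],
                          method = spec$selector, seed = foldSeed)
      feats <- selectTopK(sc, min(spec$nFeatures, length(sc$ranking)))
      Xtr <- m[train, feats, drop = FALSE]
      params <- tuneLearner(learner, Xtr, y[train], plan$inner,
                            spec$nSearchDraws, foldSeed)
      model <- withSeed(childSeed(foldSeed, 7L),
                        learner$fit(Xtr, y[train], params))
      out <- withSeed(childSeed(foldSeed, 8L),
                      learner$predict(model, m[test, feats, drop = FALSE]))
      list(feats = feats, out = out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, f)
      warnf("fold %d failed: %s", f, conditionMessage(res))
      next
    }
    features[[f]] <- res$feats
    pred[test] <- res$out$label
    prob[test] <- if (is.null(res$out$prob)) NA_real_ else res$out$prob
    perFold[[f]] <- computeMetrics(res$out$label, y[test],
                                   prob = res$out$prob)
  }
  ok <- !is.na(pred)
  hasProb <- any(!is.na(prob))
  pooled <- computeMetrics(pred[ok], y[ok],
                           prob = if (hasProb) prob[ok] else NULL)
  done <- perFold[!vapply(perFold, is.null, logical(1))]
  foldMean <- lapply(stats::setNames(nm = c("BA", "MMCE", "TPR", "TNR", "PPV", "AUC")),
                     function(k) mean(vapply(done, `[[`, 0, k), na.rm = TRUE))
  structure(list(
    predictions = data.frame(compound_id = rownames(m), fold = plan$assignment,
                             label = y, pred = pred, prob = prob,
                             stringsAsFactors = FALSE),
    pooled = pooled, foldMean = foldMean, perFold = perFold,
    features = features, failedFolds = failed,
    valid = length(failed) <= 2L, spec = spec
  ), class = "NestedCVResult")
}

#' @export
print.NestedCVResult <- function(x, ...) {
  cat(sprintf("NestedCVResult[%s]%s pooled: ", x$spec$key,
              if (x$valid) "" else " (INVALID)"))
  print(x$pooled)
  invisible(x)
}

## Inner-loop random search maximizing pooled inner-CV balanced accuracy.
tuneLearner <- function(learner, X, y, inner, nDraws, seed) {
  if (is.null(learner$sample) || nDraws <= 0L) return(NULL)
  fold <- innerFolds(y, inner, childSeed(seed, 2L))
  bestBA <- -Inf; best <- NULL
  for (d in seq_len(nDraws)) {
    params <- withSeed(childSeed(seed, 10L + d), learner$sample())
    predIn <- rep(NA_integer_, length(y))
    ba <- tryCatch({
      for (g in seq_len(inner)) {
        tr <- fold != g
        model <- withSeed(childSeed(seed, 1000L + d * 10L + g),
                          learner$fit(X[tr, , drop = FALSE], y[tr], params))
        predIn[!tr] <- learner$predict(model, X[!tr, , drop = FALSE])$label
      }
      computeMetrics(predIn, y)$BA
    }, error = function(e) NA_real_)
    if (!is.na(ba) && ba > bestBA) { bestBA <- ba; best <- params }
  }
  best
}

#' Run a grid of model specifications
#'
#' @param x a preprocessed [DescriptorSet-class].
#' @param specs list of [modelSpec()]s.
#' @param plan a [makeFoldPlan()].
#' @return named list of `NestedCVResult`s (names = model keys).
#' @export
runModelGrid <- function(x, specs, plan) {
  res <- lapply(specs, function(s) runNestedCV(x, s, plan))
  names(res) <- vapply(specs, `[[`, "", "key")
  res
}

#' y-randomization (response scrambling) test
#'
#' Permutes the DILI labels uniformly, reruns the *entire* pipeline (feature
#' selection inside nested CV, tuning, fitting) on the scrambled labels, and
#' repeats. Because permutation preserves the class counts, scrambled runs are
#' always well-defined. Models reflecting a genuine structure-toxicity
#' relationship must beat every scrambled run, whose balanced accuracy is
#' expected to center near 0.5.
#'
#' @param x a preprocessed [DescriptorSet-class].
#' @param specs list of [modelSpec()]s; repeats cycle through them so each
#'   scrambled run exercises a (possibly) different algorithm.
#' @param repeats number of scrambled repeats (default 10).
#' @param seed RNG seed for the permutations.
#' @param genuine optional named list of genuine `PerformanceSummary`s (pooled
#'   out-of-fold) for the comparison flag.
#' @param outer,inner fold counts for the scrambled runs.
#' @return a `YRandReport` list: `perRepeat` (`data.frame` with repeat, model
#'   key and the six metrics), `meanBA`, and when `genuine` is given,
#'   `genuineBA` and `separated` (TRUE when every scrambled BA is below every
#'   genuine BA).
#' @export
yRandomization <- function(x, specs, repeats = 10L, seed = 1L,
                           genuine = NULL, outer = 10L, inner = 5L) {
  if (length(specs) == 0L) stopf("need at least one model spec")
  if (inherits(specs, "ModelSpec")) specs <- list(specs)
  y <- compoundLabels(x)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    perm <- withSeed(childSeed(seed, 300L + r), sample(y))
    xr <- x
    SummarizedExperiment::colData(xr)$label <- perm
    spec <- specs[[(r - 1L) %% length(specs) + 1L]]
    spec$seed <- childSeed(seed, 400L + r)
    plan <- makeFoldPlan(perm, outer = outer, inner = inner,
                         seed = childSeed(seed, 500L + r))
    fit <- runNestedCV(xr, spec, plan)
    s <- fit$pooled
    rows[[r]] <- data.frame(repeat_id = r, model = spec$key, BA = s$BA,
                            MMCE = s$MMCE, TPR = s$TPR, TNR = s$TNR,
                            PPV = s$PPV, AUC = s$AUC)
  }
  perRepeat <- do.call(rbind, rows)
  out <- list(perRepeat = perRepeat, meanBA = mean(perRepeat$BA))
  if (!is.null(genuine)) {
    gBA <- vapply(genuine, `[[`, 0, "BA")
    out$genuineBA <- gBA
    out$separated <- max(perRepeat$BA) < min(gBA)
  }
  class(out) <- "YRandReport"
  out
}

#' @export
print.YRandReport <- function(x, ...) {
  cat(sprintf("y-randomization: %d repeats, scrambled BA mean %.3f (range %.3f-%.3f)\n",
              nrow(x$perRepeat), x$meanBA, min(x$perRepeat$BA),
              max(x$perRepeat$BA)))
  if (!is.null(x$separated))
    cat(sprintf("all scrambled below all genuine: %s (genuine min BA %.3f)\n",
                x$separated, min(x$genuineBA)))
  invisible(x)
}
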