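#' Pluggable classification learners
#'
#' Off-the-shelf binary classifiers behind one interface, used by the nested
#' cross-validation engine. Each registry entry provides `fit(X, y, params)`,
#' `predict(model, X)` returning `list(label, prob)` (prob = P(DILI concern),
#' or `NULL` for probability-free learners), and `sample()` drawing one random
#' hyperparameter setting from bounded ranges for the inner-loop search.
#'
#' Registered: `logistic` (glm), `elastic_net` (glmnet), `cart` (rpart),
#' `random_forest` (randomForest), `svm_linear` / `svm_radial` / `svm_sigmoid`
#' (e1071), `knn` (class, k in 1..30; tuned in the inner loop),
#' `naive_bayes` (e1071), `neural_net` (nnet).
#'
#' @return `listLearners()`: character vector of learner ids.
#' @export
listLearners <- function() names(learnerRegistry())

yFactor <- function(y) factor(y, levels = c(0L, 1L))

learnerRegistry <- function() {
  list(
    logistic = list(
      hasProb = TRUE, sample = NULL,
      fit = function(X, y, params) {
        df <- data.frame(X, check.names = FALSE)
        df$.y <- y
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(model, X) {
        p <- suppressWarnings(
          stats::predict(model, data.frame(X, check.names = FALSE),
                         type = "response"))
        list(label = as.integer(p >= 0.5), prob = as.numeric(p))
      }
    ),
    elastic_net = list(
      hasProb = TRUE,
      sample = function() list(alpha = stats::runif(1),
                               lambda = 10^stats::runif(1, -4, 0.5)),
      fit = function(X, y, params) {
        params <- params %||% list(alpha = 0.5, lambda = 0.01)
        glmnet::glmnet(X, yFactor(y), family = "binomial",
                       alpha = params$alpha, lambda = params$lambda)
      },
      predict = function(model, X) {
        p <- as.numeric(stats::predict(model, X, type = "response"))
        list(label = as.integer(p >= 0.5), prob = p)
      }
    ),
    cart = list(
      hasProb = TRUE,
      sample = function() list(cp = 10^stats::runif(1, -4, -1),
                               minsplit = sample(5:40, 1L)),
      fit = function(X, y, params) {
        params <- params %||% list(cp = 0.01, minsplit = 20L)
        df <- data.frame(X, check.names = FALSE); df$.y <- yFactor(y)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = params$cp,
                                                    minsplit = params$minsplit))
      },
      predict = function(model, X) {
        p <- stats::predict(model, data.frame(X, check.names = FALSE),
                            type = "prob")[, "1"]
        list(label = as.integer(p >= 0.5), prob = as.numeric(p))
      }
    ),
    random_forest = list(
      hasProb = TRUE,
      sample = function() list(mtry = NA_integer_,   # resolved against p at fit
                               mtryFrac = stats::runif(1, 0.05, 0.8),
                               nodesize = sample(1:10, 1L)),
      fit = function(X, y, params) {
        params <- params %||% list(mtryFrac = NA, nodesize = 1L)
        mtry <- if (is.null(params$mtryFrac) || is.na(params$mtryFrac))
          max(1L, floor(sqrt(ncol(X)))) else max(1L, round(params$mtryFrac * ncol(X)))
        randomForest::randomForest(X, yFactor(y), ntree = 300L,
                                   mtry = min(mtry, ncol(X)),
                                   nodesize = params$nodesize %||% 1L)
      },
      predict = function(model, X) {
        p <- stats::predict(model, X, type = "prob")[, "1"]
        list(label = as.integer(p >= 0.5), prob = as.numeric(p))
      }
    ),
    svm_linear = svmEntry("linear"),
    svm_radial = svmEntry("radial"),
    svm_sigmoid = svmEntry("sigmoid"),
    knn = list(
      hasProb = TRUE,
      sample = function() list(k = sample(1:30, 1L)),
      fit = function(X, y, params) {
        params <- params %||% list(k = 5L)
        list(X = X, y = y, k = min(params$k, nrow(X)))
      },
      predict = function(model, X) {
        pr <- class::knn(model$X, X, yFactor(model$y), k = model$k, prob = TRUE)
        win <- attr(pr, "prob")
        lab <- as.integer(as.character(pr))
        list(label = lab, prob = ifelse(lab == 1L, win, 1 - win))
      }
    ),
    naive_bayes = list(
      hasProb = TRUE,
      sample = function() list(laplace = stats::runif(1, 0, 1)),
      fit = function(X, y, params) {
        params <- params %||% list(laplace = 0)
        e1071::naiveBayes(data.frame(X, check.names = FALSE), yFactor(y),
                          laplace = params$laplace)
      },
      predict = function(model, X) {
        p <- stats::predict(model, data.frame(X, check.names = FALSE),
                            type = "raw")[, "1"]
        list(label = as.integer(p >= 0.5), prob = as.numeric(p))
      }
    ),
    neural_net = list(
      hasProb = TRUE,
      sample = function() list(size = sample(1:8, 1L),
                               decay = 10^stats::runif(1, -4, 0)),
      fit = function(X, y, params) {
        params <- params %||% list(size = 3L, decay = 0.01)
        nnet::nnet(X, y, size = params$size, decay = params$decay,
                   entropy = TRUE, maxit = 150L, trace = FALSE,
                   MaxNWts = 5000L)
      },
      predict = function(model, X) {
        p <- as.numeric(stats::predict(model, X))
        list(label = as.integer(p >= 0.5), prob = p)
      }
    )
  )
}

svmEntry <- function(kernel) {
  list(
    hasProb = TRUE,
    sample = function() list(cost = 2^stats::runif(1, -5, 7),
                             gamma = 2^stats::runif(1, -10, 2)),
    fit = function(X, y, params) {
      params <- params %||% list(cost = 1, gamma = 1 / ncol(X))
      e1071::svm(X, yFactor(y), kernel = kernel, cost = params$cost,
                 gamma = params$gamma %||% (1 / ncol(X)), probability = TRUE)
    },
    predict = function(model, X) {
      pr <- stats::predict(model, X, probability = TRUE)
      p <- attr(pr, "probabilities")[, "1"]
      list(label = as.integer(as.character(pr)), prob = as.numeric(p))
    }
  )
}

getLearner <- function(id) {
  if (is.list(id) && all(c("fit", "predict") %in% names(id))) return(id)
  reg <- learnerRegistry()
  if (!id %in% names(reg)) stopf("unknown learner '%s'", id)
  reg[[id]]
}
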