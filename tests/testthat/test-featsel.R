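# Shared fixture: a binary descriptor identical to the label, plus noise.
sepFixture <- function(n = 60, seed = 3) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    m <- cbind(perfect = as.numeric(y),
               weak = rnorm(n) + 0.4 * y,
               noise1 = rnorm(n), noise2 = rnorm(n),
               noise3 = rbinom(n, 1, 0.5))
    rownames(m) <- paste0("c", seq_len(n))
    list(m = m, y = y)
  })
}

test_that("a perfect separator ranks first under every supervised method", {
  fx <- sepFixture()
  # `variance` is unsupervised (it never sees the labels), so it is the one
  # registered filter for which this cannot hold.
  for (id in setdiff(listSelectors(), "variance")) {
    sc <- scoreFeatures(fx$m, fx$y, method = id, seed = 11)
    expect_identical(sc$ranking[1], "perfect")
  }
})

test_that("symmetrical uncertainty of a label-identical feature is 1", {
  fx <- sepFixture()
  sc <- scoreFeatures(fx$m, fx$y, method = "symmetrical_uncertainty")
  expect_equal(unname(sc$scores["perfect"]), 1)
})

test_that("chi-squared statistic matches hand evaluation on a 2x2 table", {
  # observed (52,48,48,52) against expected (50,50,50,50):
  # sum((O-E)^2/E) = 4 * (2^2/50) = 0.32
  y <- rep(c(0L, 1L), each = 100)
  v <- c(rep(0, 52), rep(1, 48), rep(0, 48), rep(1, 52))
  m <- cbind(f = v, pad = rnorm(200))
  rownames(m) <- paste0("c", 1:200)
  sc <- scoreFeatures(m, y, method = "chi_squared")
  expect_equal(unname(sc$scores["f"]), 0.32, tolerance = 1e-12)
  # cross-check against the stats oracle (uncorrected chi-squared)
  ref <- suppressWarnings(chisq.test(table(v, y), correct = FALSE))$statistic
  expect_equal(unname(sc$scores["f"]), unname(ref), tolerance = 1e-12)
})

test_that("anova, kruskal and auc scores match their reference implementations", {
  fx <- sepFixture(n = 80, seed = 9)
  sA <- scoreFeatures(fx$m, fx$y, method = "anova_f")$scores
  sK <- scoreFeatures(fx$m, fx$y, method = "kruskal_wallis")$scores
  sU <- scoreFeatures(fx$m, fx$y, method = "auc")$scores
  for (j in c("weak", "noise1")) {
    refF <- summary(aov(fx$m[, j] ~ factor(fx$y)))[[1]][["F value"]][1]
    expect_equal(unname(sA[j]), refF, tolerance = 1e-9)
    refK <- unname(kruskal.test(fx$m[, j], factor(fx$y))$statistic)
    expect_equal(unname(sK[j]), refK, tolerance = 1e-9)
    refA <- as.numeric(suppressMessages(pROC::auc(fx$y, fx$m[, j])))
    expect_equal(unname(sU[j]), abs(refA - 0.5), tolerance = 1e-9)
  }
})

test_that("rank filters are invariant to strictly increasing transforms", {
  fx <- sepFixture(n = 50, seed = 21)
  m2 <- fx$m
  m2[, "weak"] <- exp(m2[, "weak"])          # monotone transform
  m2[, "noise1"] <- m2[, "noise1"]^3
  for (id in c("auc", "kruskal_wallis", "one_r")) {
    r1 <- scoreFeatures(fx$m, fx$y, method = id, seed = 5)$ranking
    r2 <- scoreFeatures(m2, fx$y, method = id, seed = 5)$ranking
    expect_identical(r1, r2)
  }
})

test_that("adding pure noise never reorders existing descriptors (deterministic filters)", {
  fx <- sepFixture(n = 70, seed = 13)
  extra <- withr::with_seed(99, matrix(rnorm(70 * 3), 70, 3,
                                       dimnames = list(rownames(fx$m),
                                                       paste0("xnoise", 1:3))))
  for (id in c("anova_f", "auc", "kruskal_wallis", "info_gain", "variance")) {
    r1 <- scoreFeatures(fx$m, fx$y, method = id)$ranking
    r2 <- scoreFeatures(cbind(fx$m, extra), fx$y, method = id)$ranking
    expect_identical(r1, intersect(r2, r1))
  }
})

test_that("relief with a single neighbor agrees with the nearest-hit/miss oracle", {
  withr::with_seed(17, {
    n <- 24
    y <- rep(c(0L, 1L), each = n / 2)
    m <- cbind(a = rnorm(n) + 1.5 * y, b = rnorm(n), c = rnorm(n))
    rownames(m) <- paste0("c", seq_len(n))
  })
  got <- diliqsar:::scoreRelief(m, y, k = 1L)
  ref <- reliefOracle(m, y)
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("stochastic scorers are reproducible under a seed", {
  fx <- sepFixture(n = 40, seed = 2)
  for (id in c("relief", "permutation_importance", "impurity_importance",
               "univariate_model_score")) {
    s1 <- scoreFeatures(fx$m, fx$y, method = id, seed = 42)$scores
    s2 <- scoreFeatures(fx$m, fx$y, method = id, seed = 42)$scores
    expect_identical(s1, s2)
  }
})

test_that("top-k selection applies the lexicographic tie rule", {
  sc <- structure(list(method = "manual",
                       scores = c(a = 3, b = 2, c = 2, d = 1),
                       ranking = c("a", "b", "c", "d"),
                       higherIsBetter = TRUE), class = "FeatureScores")
  expect_identical(selectTopK(sc, 2), c("a", "b"))
  expect_identical(selectTopK(sc, 1), "a")
  expect_identical(selectTopK(sc, 4), c("a", "b", "c", "d"))
  expect_error(selectTopK(sc, 0), "positive")
  expect_error(selectTopK(sc, 9), "exceeds")
  # the constructor itself orders ties lexicographically
  sc2 <- scoreFeatures(cbind(zz = c(0, 1, 0, 1), aa = c(0, 1, 0, 1),
                             mm = c(0, 1, 0, 1)) + 0,
                       c(0L, 1L, 0L, 1L), method = "variance")
  expect_identical(sc2$ranking, c("aa", "mm", "zz"))
})

test_that("top-5 frequency table counts methods and applies the inclusion rule", {
  mkScores <- function(rk) structure(list(method = "m", scores = NULL,
                                          ranking = rk, higherIsBetter = TRUE),
                                     class = "FeatureScores")
  pool <- paste0("d", 1:30)
  # Mp-like descriptor in the top 5 of 12 methods out of 17
  lst <- lapply(1:17, function(i) {
    head_ <- if (i <= 12) c("Mp", paste0("d", i, letters[1:4])) else
      paste0("d", i, letters[1:5])
    mkScores(c(head_, setdiff(pool, head_)))
  })
  tab <- topFeatureFrequency(lst)
  expect_identical(tab$count[tab$descriptor == "Mp"], 12L)
  expect_equal(tab$percentage[tab$descriptor == "Mp"], 70.59)
  # descriptors seen once are excluded by default, reported when minCount = 1
  expect_false(any(grepl("^d1a$", tab$descriptor)))
  tab1 <- topFeatureFrequency(lst, minCount = 1)
  expect_true("d13a" %in% tab1$descriptor)
  # single method: every top-5 descriptor at 100%
  tabS <- topFeatureFrequency(lst[1], minCount = 1)
  expect_identical(nrow(tabS), 5L)
  expect_true(all(tabS$percentage == 100))
  expect_error(topFeatureFrequency(list()), "at least one")
})

test_that("degenerate label input is refused", {
  fx <- sepFixture()
  expect_error(scoreFeatures(fx$m, rep(1L, nrow(fx$m)), method = "anova_f"),
               "both classes")
  expect_error(scoreFeatures(fx$m, fx$y, method = "no_such_method"))
})
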