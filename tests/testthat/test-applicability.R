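test_that("isolation forest isolates scattered points and is seeded", {
  withr::with_seed(5, {
    dense <- matrix(rnorm(50 * 2, sd = 0.05), 50, 2)    # one tight clump
    scatter <- matrix(runif(10 * 2, 3, 9), 10, 2)       # far-flung points
  })
  X <- rbind(dense, scatter)
  rownames(X) <- c(paste0("d", 1:50), paste0("s", 1:10))
  rep_ <- iforestScores(X, nTrees = 100, seed = 2)
  expect_true(all(rep_$score > 0 & rep_$score < 1))
  expect_gt(min(rep_$score[51:60]), max(rep_$score[1:50]))
  expect_identical(rep_$score, iforestScores(X, nTrees = 100, seed = 2)$score)
  expect_false(identical(rep_$score,
                         iforestScores(X, nTrees = 100, seed = 3)$score))
})

test_that("SOD matches the brute-force oracle and flags the quantile count", {
  # a cluster spread along x but tight along y, with one point displaced far
  # along the tight axis — the textbook case the subspace score must catch
  withr::with_seed(9, {
    X <- cbind(x = rnorm(20, sd = 3), y = rnorm(20, sd = 0.1))
    X[20, ] <- c(0, 10)
  })
  rownames(X) <- paste0("p", 1:20)
  rep_ <- sodOutliers(X, kNeighbors = 6, refSize = 5, frac = 0.05)
  ref <- sodOracle(X, kNeighbors = 6, refSize = 5, alpha = 0.8)
  expect_equal(unname(rep_$score), ref, tolerance = 1e-9)
  expect_identical(rep_$flagged, "p20")        # ceiling(0.05*20) = 1, the spike

  # exact-division and ceiling arithmetic of the flag count
  withr::with_seed(1, Y <- matrix(rnorm(100 * 3), 100, 3))
  expect_length(sodOutliers(Y, kNeighbors = 10, frac = 0.05)$flagged, 5)
  expect_error(sodOutliers(Y, frac = 1.5), "frac")
})

test_that("kNN-threshold AD reproduces the hand-computed 1-D example", {
  train <- matrix(c(0, 1, 2, 3, 4), ncol = 1,
                  dimnames = list(paste0("t", 0:4), "x"))
  # k = 2 thresholds: t0 (1+2)/2 = 1.5; t1,t2,t3 = 1; t4 = 1.5
  test <- matrix(c(2.4, 9), ncol = 1, dimnames = list(c("in", "out"), "x"))
  v <- adKnnThreshold(train, test, k = 2)
  expect_identical(v$in_domain, c(TRUE, FALSE))
  # 2.4 sits 0.4 from its nearest training point (threshold 1): slack -0.6
  expect_equal(v$score[1], -0.6)
  # 9 is 5 from t4 whose threshold is 1.5: slack 3.5
  expect_equal(v$score[2], 3.5)

  # a test point identical to a training point is always in-domain
  v0 <- adKnnThreshold(train, train[2, , drop = FALSE], k = 2)
  expect_true(v0$in_domain)
  expect_error(adKnnThreshold(train, test, k = 5), "smaller")
})

test_that("kNN-threshold deletion with fixed thresholds only shrinks the domain", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tr <- matrix(rnorm(30 * 3), 30, 3)
      te <- matrix(rnorm(10 * 3, sd = 1.4), 10, 3)
    })
    rownames(tr) <- paste0("t", 1:30); rownames(te) <- paste0("q", 1:10)
    k <- 4
    D <- diliqsar:::crossDist(tr, tr); diag(D) <- Inf
    thr <- apply(D, 1, function(d) mean(sort(d)[1:k]))
    before <- adKnnThreshold(tr, te, k = k, thresholds = thr)
    drop <- sample(30, 1)
    after <- adKnnThreshold(tr[-drop, ], te, k = k, thresholds = thr[-drop])
    expect_true(all(before$in_domain | !after$in_domain))
  }
})

test_that("INFLO matches brute force; uniform grids score about 1", {
  grid <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  rownames(grid) <- paste0("g", 1:49)
  v <- infloScores(grid, k = 4)
  # deep-interior points: their rook neighbors all have k-distance 1, so the
  # density ratio is exactly 1
  interior <- which(grid[, 1] %in% 3:5 & grid[, 2] %in% 3:5)
  expect_equal(v$score[interior], rep(1, length(interior)), tolerance = 1e-9)
  for (i in c(1, 25, 49))
    expect_equal(v$score[i], infloOracle(grid, grid[i, ], k = 4, selfIndex = i),
                 tolerance = 1e-9)

  # an isolated point 10x the grid spacing away is far out of domain
  far <- matrix(c(75, 75), 1, dimnames = list("far", NULL))
  vf <- infloScores(grid, far, k = 4)
  expect_gt(vf$score, 3)
  expect_false(vf$in_domain)
  expect_equal(vf$score, infloOracle(grid, c(75, 75), k = 4), tolerance = 1e-9)

  # mutually equidistant points (regular simplex): all scores exactly 1
  simplex <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(simplex) <- paste0("s", 1:3)
  expect_equal(infloScores(simplex, k = 2)$score, rep(1, 3), tolerance = 1e-12)
})

test_that("COF distinguishes isolativity from low density", {
  line <- cbind(x = seq(0, 9), y = rep(0, 10))
  rownames(line) <- paste0("l", 1:10)
  v <- cofScores(line, k = 3)
  # a point ON a sparse line still chains well: score near 1
  expect_true(all(abs(v$score[4:7] - 1) < 0.1))
  for (i in c(1, 5))
    expect_equal(v$score[i], cofOracle(line, line[i, ], k = 3, selfIndex = i),
                 tolerance = 1e-9)

  # an off-line point at the same nearest-neighbor distance scores higher
  onLine <- matrix(c(4.5, 0), 1, dimnames = list("on", NULL))
  offLine <- matrix(c(4.5, 2), 1, dimnames = list("off", NULL))
  sOn <- cofScores(line, onLine, k = 3)$score
  sOff <- cofScores(line, offLine, k = 3)$score
  expect_gt(sOff, sOn)
  expect_equal(sOff, cofOracle(line, c(4.5, 2), k = 3), tolerance = 1e-9)

  # mutually equidistant set: all chaining distances equal, scores 1
  simplex <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(simplex) <- paste0("s", 1:3)
  expect_equal(cofScores(simplex, k = 2)$score, rep(1, 3), tolerance = 1e-12)
})

test_that("AD scores are invariant under translation and rotation", {
  withr::with_seed(11, {
    tr <- matrix(rnorm(25 * 2), 25, 2)
    te <- matrix(rnorm(6 * 2, sd = 1.5), 6, 2)
  })
  rownames(tr) <- paste0("t", 1:25); rownames(te) <- paste0("q", 1:6)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(3, -5)
  trT <- sweep(tr %*% R, 2, shift, "+"); rownames(trT) <- rownames(tr)
  teT <- sweep(te %*% R, 2, shift, "+"); rownames(teT) <- rownames(te)
  expect_equal(adKnnThreshold(tr, te, k = 3)$score,
               adKnnThreshold(trT, teT, k = 3)$score, tolerance = 1e-9)
  expect_equal(infloScores(tr, te, k = 3)$score,
               infloScores(trT, teT, k = 3)$score, tolerance = 1e-9)
  expect_equal(cofScores(tr, te, k = 3)$score,
               cofScores(trT, teT, k = 3)$score, tolerance = 1e-9)
})

test_that("misclassification audit joins model errors with outlier flags", {
  labels <- c(1, 1, 1, 0, 0)
  preds <- cbind(m1 = c(0, 1, 0, 0, 1), m2 = c(0, 1, 0, 0, 0),
                 m3 = c(0, 0, 1, 0, 1))
  rownames(preds) <- paste0("c", 1:5)
  rep_ <- structure(list(method = "sod", score = NULL, flagged = c("c1", "c4"),
                         policy = "top"), class = "OutlierReport")
  audit <- misclassifiedAudit(preds, labels, list(rep_))
  # c1 wrong by all 3 models; c3 and c5 by 2 of 3; c2 and c4 by a minority
  expect_identical(audit$compound_id, c("c1", "c3", "c5"))
  expect_equal(audit$wrong_by, c(3, 2, 2))
  expect_identical(audit$outlier_sod, c(TRUE, FALSE, FALSE))
  expect_equal(attr(audit, "flaggedFraction"), 1 / 3)

  # no compound misclassified by a majority: empty, well-formed audit
  empty <- misclassifiedAudit(cbind(m1 = labels, m2 = labels), labels,
                              list(rep_))
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "flaggedFraction")))
})
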