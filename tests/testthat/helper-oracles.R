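# Independent brute-force oracles, written as plain double/triple loops over
# the definitions. They deliberately share no code with the package internals.

# Rescaled Gower dissimilarity: per-column |xi-xj|/range (continuous) or
# mismatch (binary), averaged over jointly observed columns, then divided by
# the global maximum.
gowerOracle <- function(values, kind) {
  n <- nrow(values); p <- ncol(values)
  rng <- numeric(p)
  for (j in seq_len(p)) rng[j] <- diff(range(values[, j], na.rm = TRUE))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (l in seq_len(n)) {
    s <- 0; w <- 0
    for (j in seq_len(p)) {
      xi <- values[i, j]; xl <- values[l, j]
      if (is.na(xi) || is.na(xl)) next
      s <- s + if (kind[j] == "continuous") abs(xi - xl) / rng[j]
               else as.numeric(xi != xl)
      w <- w + 1
    }
    D[i, l] <- s / w
  }
  diag(D) <- 0
  mx <- max(D)
  if (mx > 0) D <- D / mx
  dimnames(D) <- list(rownames(values), rownames(values))
  D
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# INFLO oracle for one query row against a training matrix.
infloOracle <- function(train, query, k, selfIndex = NA) {
  n <- nrow(train)
  dq <- vapply(seq_len(n), function(j) euclid(query, train[j, ]), 0)
  if (!is.na(selfIndex)) dq[selfIndex] <- Inf
  kdistQ <- sort(dq)[k]
  densQ <- 1 / max(kdistQ, 1e-12)
  kdistT <- numeric(n); densT <- numeric(n)
  for (i in seq_len(n)) {
    di <- vapply(seq_len(n), function(j)
      if (j == i) Inf else euclid(train[i, ], train[j, ]), 0)
    kdistT[i] <- sort(di)[k]
    densT[i] <- 1 / max(kdistT[i], 1e-12)
  }
  knn <- order(dq)[seq_len(k)]
  rnn <- which(dq <= kdistT + 1e-12 & is.finite(dq))
  infl <- union(knn, rnn)
  mean(densT[infl]) / densQ
}

# Average chaining distance of a query through its k-neighborhood (set-based
# nearest path, decreasing edge weights), and the COF score.
acDistOracle <- function(points, query, nbIdx) {
  r <- length(nbIdx)
  chain <- list(query)
  remaining <- nbIdx
  edges <- numeric(r)
  for (i in seq_len(r)) {
    best <- Inf; bestJ <- NA
    for (j in seq_along(remaining)) {
      for (g in chain) {
        d <- euclid(g, points[remaining[j], ])
        if (d < best) { best <- d; bestJ <- j }
      }
    }
    edges[i] <- best
    chain <- c(chain, list(points[remaining[bestJ], ]))
    remaining <- remaining[-bestJ]
  }
  sum(2 * (r + 1 - seq_len(r)) / (r * (r + 1)) * edges)
}

cofOracle <- function(train, query, k, selfIndex = NA) {
  n <- nrow(train)
  dq <- vapply(seq_len(n), function(j) euclid(query, train[j, ]), 0)
  if (!is.na(selfIndex)) dq[selfIndex] <- Inf
  nb <- order(dq)[seq_len(k)]
  acQ <- acDistOracle(train, query, nb)
  acNb <- vapply(nb, function(i) {
    di <- vapply(seq_len(n), function(j)
      if (j == i) Inf else euclid(train[i, ], train[j, ]), 0)
    acDistOracle(train, train[i, ], order(di)[seq_len(k)])
  }, 0)
  acQ / mean(acNb)
}

# SOD oracle: shared-nearest-neighbor reference set, axis-parallel subspace,
# normalized deviation.
sodOracle <- function(X, kNeighbors, refSize, alpha) {
  n <- nrow(X)
  nn <- vector("list", n)
  for (i in seq_len(n)) {
    di <- vapply(seq_len(n), function(j)
      if (j == i) Inf else euclid(X[i, ], X[j, ]), 0)
    nn[[i]] <- order(di)[seq_len(kNeighbors)]
  }
  score <- numeric(n)
  for (i in seq_len(n)) {
    snn <- vapply(seq_len(n), function(j)
      length(intersect(nn[[i]], nn[[j]])), 0L)
    snn[i] <- -1L
    ref <- order(-snn, seq_len(n))[seq_len(refSize)]
    mu <- colMeans(X[ref, , drop = FALSE])
    v <- apply(X[ref, , drop = FALSE], 2, var)
    rel <- which(v < alpha * mean(v))
    if (!length(rel)) rel <- which.min(v)
    score[i] <- sqrt(sum((X[i, rel] - mu[rel])^2) / length(rel))
  }
  score
}

# Relief with nearest hit/miss (k = 1): classic single-neighbor update with
# range-normalized differences and Manhattan neighbor distance.
reliefOracle <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) { r <- diff(range(v)); if (r == 0) 1 else r })
  Z <- sweep(sweep(X, 2, apply(X, 2, min), "-"), 2, rng, "/")
  w <- numeric(p)
  priors <- table(y) / n
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j)
      if (j == i) Inf else sum(abs(Z[i, ] - Z[j, ])), 0)
    hit <- which(y == y[i] & is.finite(d))
    hit <- hit[which.min(d[hit])]
    mis <- which(y != y[i])
    mis <- mis[which.min(d[mis])]
    pc <- priors[as.character(y[mis])] / (1 - priors[as.character(y[i])])
    w <- w - abs(Z[i, ] - Z[hit, ]) / n + as.numeric(pc) * abs(Z[i, ] - Z[mis, ]) / n
  }
  w
}

# Confusion arithmetic straight from the definitions.
metricsOracle <- function(tp, fp, tn, fn) {
  list(TPR = tp / (tp + fn), TNR = tn / (tn + fp),
       BA = (tp / (tp + fn) + tn / (tn + fp)) / 2,
       MMCE = (fp + fn) / (tp + fp + tn + fn),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# Build prediction/label vectors realizing the given confusion counts.
vectorsFromConfusion <- function(tp, fp, tn, fn) {
  list(pred = c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn)),
       labels = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)))
}
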