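mkset <- function(values) DescriptorSet(as.matrix(values))

test_that("quasi-constant filter implements the 1%-off-mode rule", {
  n <- 1000
  base <- rnorm(n)
  v5 <- rep(7, n); v5[1:5] <- 9      # 0.5% off the mode -> dropped
  v20 <- rep(7, n); v20[1:20] <- 9   # 2% off the mode -> kept
  x <- mkset(cbind(keep = base, const = rep(1, n), off5 = v5, off20 = v20))
  f <- dropQuasiConstant(x)
  rep_ <- preprocessReport(f)
  expect_setequal(rep_$dropped_quasi_constant, c("const", "off5"))
  expect_setequal(descriptorNames(f), c("keep", "off20"))
  expect_error(dropQuasiConstant(mkset(cbind(a = rep(1, 50)))), "nothing left")
})

test_that("mode of a continuous column is the most frequent value, ties to smallest", {
  # 3 appears twice, 8 appears twice: tie broken by the smaller value 3
  v <- c(3, 3, 8, 8, 5)
  expect_identical(diliqsar:::statMode(v), 3)
  expect_identical(diliqsar:::statMode(c(NA, 2, 2, 9)), 2)
})

test_that("auto-correlation filter keeps the earlier column and is deterministic", {
  set.seed(10)
  n <- 20
  a <- rnorm(n)
  mk_corr <- function(src, rho) {   # exact sample correlation by construction
    e <- resid(lm(rnorm(n) ~ src))
    rho * as.numeric(scale(src)) + sqrt(1 - rho^2) * as.numeric(scale(e))
  }
  x <- mkset(cbind(a = a, dup = a, r95 = mk_corr(a, 0.95),
                   r85 = mk_corr(a, 0.85), z = rnorm(n)))
  f <- dropAutocorrelated(x, rMax = 0.9)
  rep_ <- preprocessReport(f)
  expect_setequal(rep_$dropped_autocorrelated$dropped, c("dup", "r95"))
  expect_true(all(rep_$dropped_autocorrelated$partner == "a"))
  expect_setequal(descriptorNames(f), c("a", "r85", "z"))
})

test_that("filters are row-order stable; column permutation preserves kept count", {
  for (seed in 1:5) {
    x <- generateDescriptors(synthConfig(nCompounds = 120, nInformative = 4,
                                         nNoise = 8, nQuasiConstant = 3,
                                         nRedundant = 4, nBinary = 2,
                                         seed = seed))
    m <- descriptorMatrix(x)
    f1 <- dropAutocorrelated(dropQuasiConstant(x))
    perm <- withr::with_seed(seed, sample(nrow(m)))
    xr <- DescriptorSet(m[perm, ], kind = descriptorKind(x))
    f2 <- dropAutocorrelated(dropQuasiConstant(xr))
    expect_setequal(descriptorNames(f1), descriptorNames(f2))  # row order
    cperm <- withr::with_seed(seed + 100, sample(ncol(m)))
    xc <- DescriptorSet(m[, cperm], kind = descriptorKind(x)[cperm])
    f3 <- dropAutocorrelated(dropQuasiConstant(xc))
    expect_identical(length(descriptorNames(f3)), length(descriptorNames(f1)))
  }
})

test_that("normalize-and-cap z-scores, clips at the cap and is idempotent", {
  v <- c(10, 12, 14, 16, 40)          # 40 is far above the mean
  x <- mkset(cbind(d = v, e = rnorm(5)))
  nz <- normalizeCap(x, capSD = 2)
  m <- descriptorMatrix(nz)
  expect_equal(m[, "d"], pmin(2, pmax(-2, (v - mean(v)) / sd(v))),
               ignore_attr = TRUE)
  # a value whose z-score exceeds the cap lands exactly on +2; a value equal
  # to the column mean maps to 0
  y <- mkset(cbind(q = c(rnorm(99), 1e6)))
  my <- descriptorMatrix(normalizeCap(y))
  expect_identical(unname(my[100, "q"]), 2)
  expect_true(all(abs(my) <= 2))
  vq <- c(1, 2, 3, 4, 5)   # 3 is the mean
  m0 <- descriptorMatrix(normalizeCap(mkset(cbind(q = vq, r = rnorm(5)))))
  expect_identical(unname(m0[3, "q"]), 0)
  # idempotence: transforming already-capped data with its own fit
  fit2 <- normalizerParams(normalizeCap(nz))
  twice <- applyNormalizer(normalizeCap(nz), fit2)
  expect_equal(descriptorMatrix(applyNormalizer(normalizeCap(nz), fit2)),
               descriptorMatrix(twice), tolerance = 1e-12)
})

test_that("fitted transform carries training statistics to new tables", {
  tr <- generateDescriptors(synthConfig(nCompounds = 100, nInformative = 3,
                                        nNoise = 3, nQuasiConstant = 0,
                                        nRedundant = 0, nBinary = 1, seed = 2))
  trn <- normalizeCap(tr)
  fit <- normalizerParams(trn)
  # an extreme external table still lands inside [-2, 2] on continuous cells
  lib <- generateDescriptors(synthConfig(nCompounds = 50, nInformative = 3,
                                         nNoise = 3, nQuasiConstant = 0,
                                         nRedundant = 0, nBinary = 1, seed = 3))
  libm <- descriptorMatrix(lib)
  contCols <- descriptorKind(lib) == "continuous"
  libm[, contCols] <- libm[, contCols] * 100   # way outside the training range
  lib2 <- DescriptorSet(libm, kind = descriptorKind(lib))
  out <- applyNormalizer(lib2, fit)
  cont <- descriptorKind(out) == "continuous"
  expect_true(all(abs(descriptorMatrix(out)[, cont]) <= 2))
  expect_identical(descriptorNames(out), fit$descriptors)
  # binary columns untouched
  expect_identical(descriptorMatrix(out)[, !cont],
                   descriptorMatrix(lib2)[, fit$descriptors][, !cont])
  # missing fitted column -> error listing the name
  bad <- DescriptorSet(descriptorMatrix(lib2)[, -1],
                       kind = descriptorKind(lib)[-1])
  expect_error(applyNormalizer(bad, fit), fit$descriptors[1])
})

test_that("median imputation fills missing cells after filtering", {
  m <- cbind(a = c(1, 2, NA, 4, 100), b = c(0, 1, 1, NA, 0))
  rownames(m) <- paste0("c", 1:5)
  x <- DescriptorSet(m, kind = c("continuous", "binary"))
  f <- imputeMissing(x)
  mm <- descriptorMatrix(f)
  expect_identical(unname(mm[3, "a"]), 3)       # median of 1,2,4,100
  expect_identical(unname(mm[4, "b"]), 0)       # binary mode
  expect_identical(preprocessReport(f)$imputed_cells, 2L)
})

test_that("DILIrank-layout parsing collapses labels and applies exclusions", {
  tab <- data.frame(
    Compound.Name = c("drugA", "drugB", "drugC", "drugD", "bioE"),
    SMILES = c("C", "CC", "CCC", "CCCC", NA),
    vDILIConcern = c("Most-DILI-Concern", "Less-DILI-Concern",
                     "No-DILI-Concern", "Ambiguous DILI-concern",
                     "vLessConcern"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  meta <- readDilirank(path, exclusions = "bioE")
  expect_identical(meta$label, c(1L, 1L, 0L, NA_integer_, NA_integer_))
  expect_identical(meta$dili_category,
                   c("Most", "Less", "No", "Ambiguous", "Less"))
  expect_identical(meta$excluded, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(meta$exclusion_reason[4:5], c("ambiguous", "listed"))

  # unknown category errors naming the row; duplicates rejected
  tab2 <- tab; tab2$vDILIConcern[2] <- "Mystery"
  write.csv(tab2, path, row.names = FALSE)
  expect_error(readDilirank(path), "Mystery.*row 2")
  tab3 <- tab; tab3$Compound.Name[2] <- "drugA"
  write.csv(tab3, path, row.names = FALSE)
  expect_error(readDilirank(path), "duplicate")

  # empty file -> empty collection with a warning
  write.csv(tab[0, ], path, row.names = FALSE)
  expect_warning(out <- readDilirank(path), "empty")
  expect_identical(nrow(out), 0L)
})
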