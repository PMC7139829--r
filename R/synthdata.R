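#' Configuration for the synthetic descriptor-table generator
#'
#' Describes a synthetic modeling dataset with the statistical structure a
#' DILI descriptor table is assumed to have: class-separating (informative)
#' descriptors, pure-noise descriptors (a third of them heavy-tailed,
#' log-normal), quasi-constant columns, near-duplicate (redundant) columns,
#' binary descriptors, and a dose covariate associated with the positive
#' class. The default positive fraction 0.64 mirrors the 447/694
#' concern/no-concern composition of the curated DILIrank modeling set.
#'
#' @param nCompounds number of compounds (rows of the descriptor table).
#' @param nInformative number of class-separating continuous descriptors.
#' @param nNoise number of pure-noise descriptors.
#' @param nQuasiConstant number of columns with < 1% of values off the mode.
#' @param nRedundant number of near-duplicate columns; each is paired to a
#'   source column with sample correlation exactly `rho`.
#' @param nBinary number of 0/1 descriptors.
#' @param effectSize standardized mean shift between classes for informative
#'   descriptors (in SD units, before label noise).
#' @param positiveFraction proportion of compounds labeled DILI concern.
#' @param doseEffect additive shift of log maximum daily dose for the positive
#'   class (log-mg units; positive values mean toxic compounds get higher
#'   doses).
#' @param labelNoise probability of flipping an observed label.
#' @param rho target sample correlation of redundant columns to their source.
#' @param seed RNG seed; generation is bitwise-reproducible for a fixed seed.
#' @return a `SynthConfig` object (validated list).
#' @examples
#' cfg <- synthConfig(nCompounds = 100, seed = 1)
#' d <- generateDescriptors(cfg)
#' d
#' @export
synthConfig <- function(nCompounds = 694L,
                        nInformative = 20L,
                        nNoise = 60L,
                        nQuasiConstant = 5L,
                        nRedundant = 10L,
                        nBinary = 5L,
                        effectSize = 1.0,
                        positiveFraction = 0.64,
                        doseEffect = 0.5,
                        labelNoise = 0.0,
                        rho = 0.95,
                        seed = 1L) {
  cfg <- list(nCompounds = as.integer(nCompounds),
              nInformative = as.integer(nInformative),
              nNoise = as.integer(nNoise),
              nQuasiConstant = as.integer(nQuasiConstant),
              nRedundant = as.integer(nRedundant),
              nBinary = as.integer(nBinary),
              effectSize = effectSize,
              positiveFraction = positiveFraction,
              doseEffect = doseEffect,
              labelNoise = labelNoise,
              rho = rho,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("nCompounds", "nInformative", "nNoise",
                         "nQuasiConstant", "nRedundant", "nBinary")])
  if (any(counts < 0)) stopf("all counts must be >= 0")
  if (cfg$nCompounds < 1L) stopf("refusing to generate zero compounds")
  if (cfg$positiveFraction <= 0 || cfg$positiveFraction >= 1)
    stopf("positiveFraction must lie strictly between 0 and 1")
  if (cfg$labelNoise < 0 || cfg$labelNoise >= 0.5)
    stopf("labelNoise must lie in [0, 0.5)")
  nPos <- round(cfg$nCompounds * cfg$positiveFraction)
  if (nPos == 0L || nPos == cfg$nCompounds)
    stopf("positiveFraction %.3f produces an empty class at n = %d",
          cfg$positiveFraction, cfg$nCompounds)
  if (cfg$nRedundant > 0L && cfg$nInformative + cfg$nNoise == 0L)
    stopf("redundant columns need at least one informative or noise source column")
  structure(cfg, class = "SynthConfig")
}

#' @export
print.SynthConfig <- function(x, ...) {
  cat(sprintf(
    "SynthConfig: %d compounds; %d informative + %d noise + %d quasi-constant + %d redundant + %d binary descriptors\n",
    x$nCompounds, x$nInformative, x$nNoise, x$nQuasiConstant, x$nRedundant,
    x$nBinary))
  cat(sprintf("effect size %.2f SD, positive fraction %.2f, label noise %.2f, seed %d\n",
              x$effectSize, x$positiveFraction, x$labelNoise, x$seed))
  invisible(x)
}

#' Generate a synthetic descriptor table with labels
#'
#' Draws a binary-labeled descriptor matrix under `config`. Informative
#' columns are standard-normal with a class-conditional mean shift of
#' `effectSize` SD units; every third noise column is log-normal
#' (heavy-tailed, exercising the +/-2 SD capping step); quasi-constant columns
#' have strictly fewer than 1% of values off their modal value; each redundant
#' column is constructed to have sample correlation exactly `rho` with its
#' source column; binary descriptors are Bernoulli. Maximum daily dose is
#' log-normal with an additive class effect of `doseEffect` on the log scale;
#' treatment duration is log-normal and label-independent. Observed labels are
#' the true class flipped with probability `labelNoise`.
#'
#' @param config a [synthConfig()] object.
#' @return a [DescriptorSet-class]; `colData` carries `name`, `dili_category`
#'   (`Most`/`No`, synthetic), `label`, `true_label`, `max_daily_dose`,
#'   `duration_days`.
#' @export
generateDescriptors <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- config$nCompounds
  withSeed(config$seed, {
    nPos <- round(n * config$positiveFraction)
    trueLabel <- sample(rep(c(1L, 0L), c(nPos, n - nPos)))
    cols <- list(); kinds <- character()

    if (config$nInformative > 0L) {
      for (j in seq_len(config$nInformative)) {
        cols[[sprintf("inf_%03d", j)]] <-
          stats::rnorm(n) + config$effectSize * trueLabel
        kinds <- c(kinds, "continuous")
      }
    }
    if (config$nNoise > 0L) {
      for (j in seq_len(config$nNoise)) {
        cols[[sprintf("noise_%03d", j)]] <-
          if (j %% 3L == 0L) stats::rlnorm(n) else stats::rnorm(n)
        kinds <- c(kinds, "continuous")
      }
    }
    if (config$nQuasiConstant > 0L) {
      kOff <- floor(0.005 * n)  # 0.5% of values off the mode, < 1% always
      for (j in seq_len(config$nQuasiConstant)) {
        v <- rep(0, n)
        if (kOff > 0L) v[sample.int(n, kOff)] <- stats::rnorm(kOff, mean = 5)
        cols[[sprintf("qconst_%03d", j)]] <- v
        kinds <- c(kinds, "continuous")
      }
    }
    if (config$nRedundant > 0L) {
      sources <- names(cols)[kinds == "continuous" &
                             !startsWith(names(cols), "qconst")]
      for (j in seq_len(config$nRedundant)) {
        src <- cols[[sources[(j - 1L) %% length(sources) + 1L]]]
        e <- stats::rnorm(n)
        e <- stats::residuals(stats::lm.fit(cbind(1, src), e))  # orthogonal to src
        z1 <- as.numeric(scale(src)); z2 <- as.numeric(scale(e))
        cols[[sprintf("red_%03d", j)]] <-
          config$rho * z1 + sqrt(1 - config$rho^2) * z2
        kinds <- c(kinds, "continuous")
      }
    }
    if (config$nBinary > 0L) {
      for (j in seq_len(config$nBinary)) {
        cols[[sprintf("bin_%03d", j)]] <- stats::rbinom(n, 1L, 0.3)
        kinds <- c(kinds, "binary")
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- sprintf("cpd_%05d", seq_len(n))

    label <- trueLabel
    if (config$labelNoise > 0) {
      flip <- stats::runif(n) < config$labelNoise
      label[flip] <- 1L - label[flip]
    }
    dose <- stats::rlnorm(n, meanlog = log(100) + config$doseEffect * trueLabel,
                          sdlog = 1)
    duration <- stats::rlnorm(n, meanlog = log(30), sdlog = 0.8)
    meta <- data.frame(
      compound_id = rownames(values),
      name = rownames(values),
      dili_category = ifelse(label == 1L, "Most", "No"),
      label = label,
      true_label = trueLabel,
      excluded = FALSE,
      max_daily_dose = dose,
      duration_days = duration,
      row.names = rownames(values)
    )
    DescriptorSet(values, meta = meta, kind = kinds)
  })
}

#' Fixed 12-compound micro-fixture for unit tests and examples
#'
#' Returns the same hand-written 12 x 8 descriptor table on every call:
#' two informative columns, one constant column, one exact duplicate of the
#' first informative column, one binary column and three noise columns;
#' 7 of the 12 compounds carry the positive (DILI concern) label.
#'
#' @return a [DescriptorSet-class].
#' @export
makeMicroFixture <- function() {
  values <- cbind(
    inf1  = c(2.1, 1.8, 2.5, 1.9, 2.2, 2.8, 1.7, 0.2, -0.1, 0.4, -0.3, 0.1),
    inf2  = c(-1.0, -1.4, -0.8, -1.2, -0.9, -1.1, -1.3, 0.9, 1.2, 0.8, 1.1, 1.0),
    qconst = rep(3.5, 12),
    dup_inf1 = c(2.1, 1.8, 2.5, 1.9, 2.2, 2.8, 1.7, 0.2, -0.1, 0.4, -0.3, 0.1),
    bin1  = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 1),
    noise1 = c(0.5, -0.2, 1.3, -1.1, 0.7, 0.0, -0.6, 1.0, -0.9, 0.3, 0.8, -1.4),
    noise2 = c(-0.7, 1.5, 0.2, 0.9, -1.3, 0.4, 1.1, -0.5, 0.6, -1.0, 0.1, 1.2),
    noise3 = c(1.9, -0.4, -1.6, 0.3, 0.8, -1.2, 0.5, 1.4, -0.2, 0.7, -0.8, 0.0)
  )
  rownames(values) <- sprintf("cpd_%02d", 1:12)
  label <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  meta <- data.frame(
    compound_id = rownames(values),
    name = rownames(values),
    dili_category = ifelse(label == 1L, "Most", "No"),
    label = label,
    true_label = label,
    excluded = FALSE,
    max_daily_dose = c(120, 80, 300, 150, 95, 400, 60, 20, 35, 15, 25, 40),
    duration_days = c(30, 14, 90, 30, 7, 60, 21, 10, 30, 14, 7, 28),
    row.names = rownames(values)
  )
  DescriptorSet(values, meta = meta,
                kind = c("continuous", "continuous", "continuous", "continuous",
                         "binary", "continuous", "continuous", "continuous"))
}

#' Synthetic compound table in the DILIrank download layout
#'
#' Builds a synthetic stand-in for the FDA DILIrank list with the per-category
#' census used in the DILIrank modeling literature: 192 Most-DILI-concern,
#' 287 Less-DILI-concern, 312 No-DILI-concern and 254 Ambiguous DILI-concern
#' rows (791 labeled compounds once the ambiguous category is excluded), with
#' invented compound names and placeholder SMILES. Intended for exercising
#' [readDilirank()] and the label-collapsing rules without a network download;
#' the compounds are not real drugs.
#'
#' @param seed RNG seed controlling the row order.
#' @return a `data.frame` with columns `Compound.Name`, `SMILES`,
#'   `vDILIConcern`.
#' @export
syntheticDilirank <- function(seed = 1L) {
  census <- c("Most-DILI-Concern" = 192L, "Less-DILI-Concern" = 287L,
              "No-DILI-Concern" = 312L, "Ambiguous DILI-concern" = 254L)
  category <- rep(names(census), census)
  n <- length(category)
  withSeed(childSeed(seed, 97L), {
    ord <- sample.int(n)
    data.frame(
      Compound.Name = sprintf("synthdrug_%04d", seq_len(n)),
      SMILES = rep(c("CCO", "c1ccccc1", "CC(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C"),
                   length.out = n),
      vDILIConcern = category[ord],
      stringsAsFactors = FALSE
    )
  })
}
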