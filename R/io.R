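#' Read a compound table in the DILIrank download layout
#'
#' Parses a CSV in the layout of the FDA DILIrank list (compound name, SMILES,
#' DILI-concern category), normalizes the four concern categories, collapses
#' Most- and Less-DILI-concern into a single positive class (label 1) and
#' No-DILI-concern into the negative class (label 0). Ambiguous compounds are
#' always excluded and carry no label, as are compounds named in `exclusions`
#' (biologics, mixtures, simple inorganics — these judgment calls are supplied
#' as a list, not hard-coded).
#'
#' @param path CSV file path.
#' @param nameCol,categoryCol,smilesCol header names of the compound-name,
#'   concern-category and SMILES columns.
#' @param doseCol,durationCol optional header names for maximum daily dose and
#'   treatment duration.
#' @param exclusions character vector of compound names to exclude (reason
#'   recorded as `"listed"`).
#' @return a `data.frame` of compound metadata: `compound_id`, `name`,
#'   `smiles`, `dili_category` (`Most`/`Less`/`No`/`Ambiguous`), `label`
#'   (1 = DILI concern, `NA` when excluded), `excluded`, `exclusion_reason`,
#'   plus dose/duration when present.
#' @export
readDilirank <- function(path,
                         nameCol = "Compound.Name",
                         categoryCol = "vDILIConcern",
                         smilesCol = "SMILES",
                         doseCol = NULL,
                         durationCol = NULL,
                         exclusions = character()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(raw) == 0L) {
    warnf("empty compound table: %s", path)
    return(data.frame(compound_id = character(), name = character(),
                      smiles = character(), dili_category = character(),
                      label = integer(), excluded = logical(),
                      exclusion_reason = character()))
  }
  for (col in c(nameCol, categoryCol)) {
    if (!col %in% colnames(raw))
      stopf("column '%s' not found in %s", col, path)
  }
  name <- trimws(raw[[nameCol]])
  if (anyDuplicated(name))
    stopf("duplicate compound names: %s",
          paste(unique(name[duplicated(name)]), collapse = ", "))
  category <- normalizeCategory(raw[[categoryCol]])
  bad <- which(is.na(category))
  if (length(bad))
    stopf("unknown DILI-concern category '%s' at row %d",
          raw[[categoryCol]][bad[1L]], bad[1L])
  excluded <- category == "Ambiguous"
  reason <- ifelse(excluded, "ambiguous", NA_character_)
  listed <- name %in% exclusions
  reason[listed & !excluded] <- "listed"
  excluded <- excluded | listed
  label <- ifelse(excluded, NA_integer_,
                  ifelse(category %in% c("Most", "Less"), 1L, 0L))
  out <- data.frame(
    compound_id = name,
    name = name,
    smiles = if (smilesCol %in% colnames(raw)) raw[[smilesCol]] else NA_character_,
    dili_category = category,
    label = label,
    excluded = excluded,
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  if (!is.null(doseCol) && doseCol %in% colnames(raw))
    out$max_daily_dose <- as.numeric(raw[[doseCol]])
  if (!is.null(durationCol) && durationCol %in% colnames(raw))
    out$duration_days <- as.numeric(raw[[durationCol]])
  rownames(out) <- out$compound_id
  out
}

## Map the category spellings seen in DILIrank-layout files onto
## Most / Less / No / Ambiguous; NA for anything unrecognized.
normalizeCategory <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[grepl("^v?most", x)] <- "Most"
  out[grepl("^v?less", x)] <- "Less"
  out[grepl("^v?no[ -_]?dili|^no$", x)] <- "No"
  out[grepl("^ambiguous", x)] <- "Ambiguous"
  out
}

#' Read a descriptor CSV into a DescriptorSet
#'
#' The CSV is comma-separated UTF-8 with a header row; the first column holds
#' compound ids and every other column one named numeric descriptor. Columns
#' whose observed values are all in \{0, 1\} are typed binary.
#'
#' @param path descriptor CSV path.
#' @param meta optional compound metadata (e.g. from [readDilirank()]); rows
#'   are matched by compound id and compounds without metadata get `NA` labels.
#'   When `meta` marks compounds as excluded they are dropped.
#' @return a [DescriptorSet-class].
#' @export
readDescriptorTable <- function(path, meta = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) stopf("descriptor CSV needs an id column plus descriptors")
  ids <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (!is.null(meta)) {
    keep <- intersect(ids, rownames(meta)[!meta$excluded])
    values <- values[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  DescriptorSet(values, meta = meta)
}

#' Write a DescriptorSet (and its metadata) to CSV
#'
#' Values are written with full double precision (`%.17g`), so a write/read
#' round trip is lossless to 15+ significant digits.
#'
#' @param x a [DescriptorSet-class]
#' @param path descriptor CSV path; metadata goes to `metaPath` when given.
#' @param metaPath optional metadata CSV path.
#' @return `path`, invisibly.
#' @export
#' Write a pipeline report as JSON
#'
#' Serializes a report object (preprocessing report, diversity summary,
#' performance summaries, screening summary, ...) to pretty-printed JSON.
#'
#' @param x a list-like report object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

writeDescriptorTable <- function(x, path, metaPath = NULL) {
  m <- descriptorMatrix(x)
  df <- data.frame(compound_id = rownames(m), stringsAsFactors = FALSE)
  for (j in colnames(m)) df[[j]] <- sprintf("%.17g", m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metaPath))
    utils::write.csv(compoundMeta(x), metaPath, row.names = FALSE)
  invisible(path)
}
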