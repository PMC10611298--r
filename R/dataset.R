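# The 14-attribute UCI heart-disease schema and its CSV dialect
# (comma-separated, "?" for missing values, optional header).

HEART_COLUMNS <- c("age", "sex", "cp", "trestbps", "chol", "fbs",
                   "restecg", "thalach", "exang", "oldpeak", "slope",
                   "ca", "thal", "num")
HEART_CATEGORICAL <- c("sex", "cp", "fbs", "restecg", "exang", "slope",
                       "ca", "thal")
HEART_NUMERIC <- c("age", "trestbps", "chol", "thalach", "oldpeak")

#' The heart-disease table schema
#'
#' @return list with `columns` (the 14 attribute names, target `num`
#'   last), `categorical`, `numeric` and `target` fields.
#' @export
heart_schema <- function() {
  list(columns = HEART_COLUMNS, categorical = HEART_CATEGORICAL,
       numeric = HEART_NUMERIC, target = "num")
}

validate_heart <- function(ds) {
  if (!all(HEART_COLUMNS %in% names(ds))) {
    stop("dataset does not carry the 14-attribute heart schema")
  }
  num <- ds$num[!is.na(ds$num)]
  if (length(num) && (any(num < 0) || any(num > 4))) {
    stop("target 'num' must lie in 0..4")
  }
  invisible(ds)
}

#' Read a heart-disease table in the UCI CSV dialect
#'
#' Comma-separated, `?` marking missing cells, 14 columns in schema order.
#' A header line is auto-detected (any line starting with `age,` is
#' treated as a header).
#'
#' @param path file path.
#' @return data frame with the schema columns, missing cells as `NA`, and
#'   a `source` attribute.
#' @export
read_uci_csv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^age[,\t]", first)
  raw <- utils::read.csv(path, header = has_header, na.strings = "?",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) != length(HEART_COLUMNS)) {
    stop(sprintf("expected %d columns, found %d", length(HEART_COLUMNS),
                 ncol(raw)))
  }
  names(raw) <- HEART_COLUMNS
  for (cn in HEART_COLUMNS) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad)) {
        stop(sprintf("unparseable value in column '%s', row %d", cn,
                     bad[1]))
      }
      raw[[cn]] <- suppress
    }
  }
  attr(raw, "source") <- basename(path)
  validate_heart(raw)
  raw
}

#' Write a heart-disease table in the UCI CSV dialect
#'
#' Deterministic column order, `?` for missing cells, floats at six
#' significant digits (stable across write/read/write cycles).
#'
#' @param ds data frame with the schema columns.
#' @param path output path.
#' @param header write a header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_uci_csv <- function(ds, path, header = TRUE) {
  validate_heart(ds)
  ds <- ds[, HEART_COLUMNS, drop = FALSE]
  fmt <- function(v) {
    out <- ifelse(is.na(v), "?", formatC(v, format = "g", digits = 6))
    sub("^\\s+", "", out)
  }
  lines <- do.call(paste, c(lapply(ds, fmt), sep = ","))
  if (header) lines <- c(paste(HEART_COLUMNS, collapse = ","), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Binarize the disease target
#'
#' The multi-level `num` column (0 = absent, 1-4 = increasing severity)
#' becomes presence/absence: `disease = as.integer(num > 0)`.
#'
#' @param ds heart-schema data frame.
#' @return the data frame with a `disease` column appended.
#' @export
binarize_target <- function(ds) {
  validate_heart(ds)
  ds$disease <- as.integer(ds$num > 0)
  ds
}
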