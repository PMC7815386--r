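#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix with its wavenumber axis and
#' per-sample metadata. The canonical axis convention is strictly
#' *descending* wavenumbers (the usual FT-NIR instrument ordering,
#' 10,000 cm-1 down to 4,000 cm-1); inputs supplied on an ascending axis are
#' reversed, together with the data columns, on construction.
#'
#' @param absorbance numeric matrix, one row per spectrum, one column per
#'   wavenumber (absorbance units).
#' @param wavenumbers numeric vector of wavenumbers in cm-1, strictly
#'   monotonic, length `ncol(absorbance)`.
#' @param sample_id character vector of unique sample identifiers.
#' @param origin optional character vector of class labels (e.g. geographic
#'   origin) per sample.
#' @param replicate_group optional character vector grouping replicate scans
#'   of the same physical sample.
#' @return An object of class `spectra_set`: a list with elements
#'   `wavenumbers`, `absorbance`, `sample_id`, `origin`, `replicate_group`.
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_id = rownames(absorbance),
                        origin = NULL, replicate_group = NULL) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers))
    stop_invalid("absorbance has %d columns but %d wavenumbers were supplied",
                 ncol(absorbance), length(wavenumbers))
  if (!all(is.finite(wavenumbers)))
    stop_invalid("wavenumbers must be finite")
  d <- diff(wavenumbers)
  if (length(wavenumbers) > 1 && !(all(d > 0) || all(d < 0)))
    stop_invalid("wavenumbers must be strictly monotonic")
  if (length(wavenumbers) > 1 && all(d > 0)) {
    # canonicalize ascending input to descending order
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(absorbance)))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(absorbance))
    stop_invalid("sample_id length (%d) != number of spectra (%d)",
                 length(sample_id), nrow(absorbance))
  if (anyDuplicated(sample_id))
    stop_invalid("duplicate sample_id: %s",
                 paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (nrow(absorbance) > 0 && !all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop_invalid("non-finite absorbance at sample '%s', wavenumber %g",
                 sample_id[bad[1]], wavenumbers[bad[2]])
  }
  check_meta <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.character(x)
    if (length(x) != nrow(absorbance))
      stop_invalid("%s length != number of spectra", nm)
    x
  }
  rownames(absorbance) <- sample_id
  colnames(absorbance) <- NULL
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_id = sample_id,
                 origin = check_meta(origin, "origin"),
                 replicate_group = check_meta(replicate_group, "replicate_group")),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavenumbers (%.5g .. %.5g cm-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  if (!is.null(x$origin))
    cat("  origins:", paste(sprintf("%s=%d", names(table(x$origin)),
                                    table(x$origin)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

#' Read / write wide spectra CSV files
#'
#' The exchange format is a wide CSV: header `sample_id` followed by the
#' numeric wavenumbers, one row per spectrum, UTF-8, `,` separator, `.`
#' decimal. Files written by [write_spectra_csv()] use 6 significant digits,
#' so a write/read cycle is idempotent on the file contents. Ascending-axis
#' files are canonicalized to descending order on read.
#'
#' @param path file path.
#' @return [read_spectra_csv()] returns a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop_invalid("spectra CSV must start with a 'sample_id' column: %s", path)
  wn <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wn))
    stop_invalid("non-numeric wavenumber header column(s): %s",
                 paste(names(df)[-1][is.na(wn)], collapse = ", "))
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X))
    stop_invalid("non-numeric absorbance values in %s", path)
  spectra_set(X, wn, sample_id = df$sample_id)
}

#' @param spectra a [spectra_set()].
#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (nrow(spectra$absorbance) > 0 && !all(is.finite(spectra$absorbance)))
    stop_invalid("refusing to write non-finite absorbance values")
  header <- c("sample_id", formatC(spectra$wavenumbers, format = "g", digits = 10))
  lines <- paste(header, collapse = ",")
  if (nrow(spectra$absorbance) > 0) {
    body <- apply(spectra$absorbance, 1, function(row)
      paste(fmt_num(row), collapse = ","))
    lines <- c(lines, paste(spectra$sample_id, body, sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write reference tables
#'
#' A reference table holds, per sample, the origin class label and the
#' wet-chemistry (HPLC) concentration of each analyte in mg/g. The CSV
#' layout is `sample_id,origin,<analyte1>,<analyte2>,...`.
#'
#' @param path file path.
#' @param classes optional character vector of allowed origin labels.
#' @return a `data.frame` with columns `sample_id`, `origin`, and one
#'   numeric column per analyte.
#' @export
read_reference_csv <- function(path, classes = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_reference(df, classes = classes)
}

#' @param reference a reference `data.frame` as returned by
#'   [read_reference_csv()].
#' @rdname read_reference_csv
#' @export
write_reference_csv <- function(reference, path) {
  validate_reference(reference)
  write.csv(reference, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_reference <- function(df, classes = NULL) {
  if (!all(c("sample_id", "origin") %in% names(df)))
    stop_invalid("reference table needs 'sample_id' and 'origin' columns")
  analytes <- setdiff(names(df), c("sample_id", "origin"))
  if (length(analytes) == 0)
    stop_invalid("reference table has no analyte columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_invalid("duplicate sample_id in reference table")
  for (a in analytes) {
    v <- df[[a]]
    if (!is.numeric(v) || anyNA(v))
      stop_invalid("analyte column '%s' has missing or non-numeric values", a)
    if (any(v < 0))
      stop_invalid("negative concentration in analyte column '%s'", a)
  }
  if (!is.null(classes) && !all(df$origin %in% classes))
    stop_invalid("origin label(s) outside the configured class set: %s",
                 paste(setdiff(df$origin, classes), collapse = ", "))
  df
}

#' Align a spectra set with a reference table
#'
#' Reorders the reference table to the spectra-set row order so matrices and
#' response vectors can be used together. Every spectra `sample_id` must be
#' present in the reference table; reference row order is irrelevant.
#'
#' @param spectra a [spectra_set()].
#' @param reference a reference `data.frame`.
#' @return a list: `X` (absorbance matrix), `reference` (reordered rows),
#'   `labels` (origin per spectrum), `Y` (numeric matrix of analyte columns).
#' @export
align_spectra <- function(spectra, reference) {
  reference <- validate_reference(reference)
  idx <- match(spectra$sample_id, reference$sample_id)
  if (anyNA(idx))
    stop_invalid("sample_id(s) missing from reference table: %s",
                 paste(spectra$sample_id[is.na(idx)], collapse = ", "))
  ref <- reference[idx, , drop = FALSE]
  rownames(ref) <- NULL
  analytes <- setdiff(names(ref), c("sample_id", "origin"))
  Y <- as.matrix(ref[, analytes, drop = FALSE])
  rownames(Y) <- ref$sample_id
  list(X = spectra$absorbance, reference = ref, labels = ref$origin, Y = Y)
}
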