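# The feature-table container and its delimited / binary I/O.

#' Construct a feature table
#'
#' The substrate of selection and classification: a numeric sample-by-feature
#' matrix with one binary class label per row, optionally carrying the
#' ground-truth informative-column mask when the table is synthetic.
#'
#' @param values Numeric matrix, rows = samples, columns = features. All
#'   values must be finite.
#' @param labels Vector of class labels, one per row; coerced to factor.
#' @param feature_names Optional character vector of column names; defaults
#'   to existing column names or `feat_1 ... feat_D`.
#' @param informative Optional 0/1 integer vector marking ground-truth
#'   informative columns.
#' @param positive Optional label to treat as the positive (diseased) class;
#'   defaults downstream to the last factor level.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = NULL,
                          informative = NULL, positive = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("feature values must all be finite", call. = FALSE)
  }
  if (nrow(values) != length(labels)) {
    stop("`labels` must have one entry per row of `values`", call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) > 2L) {
    stop("labels must be binary (at most two classes)", call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) {
    feature_names <- paste0("feat_", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "), call. = FALSE)
  }
  colnames(values) <- feature_names
  if (!is.null(informative)) {
    stopifnot(length(informative) == ncol(values))
    informative <- as.integer(informative)
  }
  if (!is.null(positive) && !positive %in% levels(labels)) {
    stop("`positive` must be one of the label levels", call. = FALSE)
  }
  structure(
    list(values = values, labels = labels, feature_names = feature_names,
         informative = informative, positive = positive),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat("  classes:",
      paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n")
  if (!is.null(x$informative)) {
    cat(sprintf("  ground-truth informative columns: %d\n",
                sum(x$informative)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from disk
#'
#' Two on-disk dialects are supported. Delimited text: a header row of
#' feature names plus a final `label` column, one sample per row; floats are
#' written with shortest round-trip formatting so the text round trip is
#' exact. Binary: R serialization (`.rds`), bit-exact.
#'
#' @param path Input file. Format is inferred from the extension (`.rds` =
#'   binary, anything else = delimited) unless `format` says otherwise.
#' @param format `"auto"`, `"delim"`, or `"rds"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("auto", "delim", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "rds") "rds" else "delim"
  }
  if (format == "rds") {
    tab <- readRDS(path)
    if (!inherits(tab, "feature_table")) {
      stop("`", path, "` does not contain a feature table", call. = FALSE)
    }
    return(tab)
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"label" %in% names(dt)) {
    stop("missing `label` column in ", path, call. = FALSE)
  }
  labels <- dt[["label"]]
  feats <- dt[, setdiff(names(dt), "label"), drop = FALSE]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   bad, names(feats)[j], path), call. = FALSE)
    }
  }
  feature_table(as.matrix(feats), labels, feature_names = names(feats))
}

#' Write a feature table to disk
#'
#' @param table A [feature_table()].
#' @param path Output file; `.rds` selects the binary container, anything
#'   else the delimited dialect.
#' @param format `"auto"`, `"delim"`, or `"rds"`.
#' @return `path`, invisibly.
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path,
                                format = c("auto", "delim", "rds")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "rds") "rds" else "delim"
  }
  if (format == "rds") {
    saveRDS(table, path)
  } else {
    # %.17g guarantees the printed decimal parses back to the same double
    dt <- data.table::as.data.table(
      lapply(seq_len(ncol(table$values)),
             function(j) sprintf("%.17g", table$values[, j]))
    )
    data.table::setnames(dt, table$feature_names)
    dt[["label"]] <- as.character(table$labels)
    data.table::fwrite(dt, path, sep = ",", quote = FALSE)
  }
  invisible(path)
}
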