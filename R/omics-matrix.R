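#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric lines-by-features matrix carrying the omic
#' layer it came from and optional per-feature metadata (genomic coordinates,
#' cytosine context). It is the common currency passed between the QC
#' filters, the kernel builders and the mediation scan. Rows are samples:
#' for genotypes and methylation usually one row per line, for expression
#' one row per (line, treatment) sample.
#'
#' @param values numeric matrix, rows = lines/samples, columns = features.
#' @param omic_kind one of `"snp"`, `"methylation"`, `"expression"`.
#' @param line_ids row identifiers; defaults to `rownames(values)`.
#' @param feature_meta optional `data.frame` with one row per feature. A
#'   `feature_id` column is added from the matrix column names if absent;
#'   methylation metadata typically carries `chrom`, `start`, `end`,
#'   `context` (`CG`/`CHG`/`CHH`).
#' @return a numeric matrix of class `omics_matrix` with attributes
#'   `omic_kind` and `feature_meta`.
#' @examples
#' g <- matrix(c(0, 1, 2, 2, 0, 0), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), c("s1", "s2")))
#' om <- omics_matrix(g, "snp")
#' omic_kind(om)
#' @export
omics_matrix <- function(values, omic_kind = c("snp", "methylation", "expression"),
                         line_ids = rownames(values), feature_meta = NULL) {
  omic_kind <- match.arg(omic_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(line_ids)) {
    line_ids <- sprintf("L%03d", seq_len(nrow(values)))
  }
  if (length(line_ids) != nrow(values)) {
    stop("length(line_ids) must equal nrow(values)")
  }
  rownames(values) <- as.character(line_ids)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%d", seq_len(ncol(values)))
  }
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    if (!"feature_id" %in% names(feature_meta)) {
      feature_meta$feature_id <- colnames(values)
    }
    if (nrow(feature_meta) != ncol(values)) {
      stop("feature_meta must have one row per feature")
    }
  }
  structure(values, class = c("omics_matrix", "matrix", "array"),
            omic_kind = omic_kind, feature_meta = feature_meta)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
omic_kind <- function(x) attr(x, "omic_kind")

#' @rdname omics_matrix
#' @export
feature_meta <- function(x) attr(x, "feature_meta")

#' Validate omics matrix invariants
#'
#' Checks uniqueness of line and feature identifiers and the per-layer value
#' ranges: methylation proportions must lie in \[0, 1\] and TPM expression
#' values must be non-negative (missing cells are allowed everywhere).
#'
#' @param x an `omics_matrix`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_omics_matrix <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyDuplicated(rownames(x))) {
    stop("duplicate line ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  v <- x[!is.na(x)]
  kind <- omic_kind(x)
  if (kind == "methylation" && length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("methylation values must lie in [0, 1]")
  }
  if (kind == "expression" && length(v) && min(v) < 0) {
    stop("TPM expression values must be >= 0")
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d lines x %d features\n",
              omic_kind(x), nrow(x), ncol(x)))
  miss <- mean(is.na(x))
  cat(sprintf("  missing: %.1f%%", 100 * miss))
  fm <- feature_meta(x)
  if (!is.null(fm) && "context" %in% names(fm)) {
    tab <- table(fm$context)
    cat("  contexts: ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# Keep class/attributes on feature (column) subsetting used internally.
subset_features <- function(x, keep) {
  fm <- feature_meta(x)
  omics_matrix(unclass(x)[, keep, drop = FALSE], omic_kind(x),
               line_ids = rownames(x),
               feature_meta = if (!is.null(fm)) fm[keep, , drop = FALSE])
}

#' Read a lines-by-features matrix
#'
#' Reads a delimited (TSV/CSV, auto-detected) numeric matrix with row
#' identifiers in the first column, or feature identifiers first when
#' `transpose = TRUE`. `"NA"` and empty cells are read as missing; any other
#' non-numeric cell is an error that names its row and column.
#'
#' @param path file path.
#' @param omic_kind omic layer of the matrix, see [omics_matrix()].
#' @param transpose set `TRUE` when the file is features-by-lines.
#' @param missing_tokens character values treated as missing.
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, omic_kind, transpose = FALSE,
                        missing_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = NULL, data.table = FALSE)
  ids <- dt[[1L]]
  cells <- as.matrix(dt[, -1L, drop = FALSE])
  is_missing <- cells %in% missing_tokens
  dim(is_missing) <- dim(cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d ('%s'), column '%s'",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(cells))
  if (transpose) num <- t(num)
  out <- omics_matrix(num, omic_kind)
  validate_omics_matrix(out)
}

#' Write a matrix or table as annotated TSV
#'
#' All tabular outputs use TSV with a commented header line recording the
#' package version, so written artifacts are self-describing. Matrices are
#' written with row identifiers in a leading `id` column.
#'
#' @param x matrix or data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  hdr <- sprintf("# omicpred %s",
                 as.character(utils::packageVersion("omicpred")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
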