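#' Read a phenotype table
#'
#' Reads per-(line, treatment) trait observations: one row per field record
#' with a line identifier, a treatment label and one or more numeric trait
#' columns (grain yield in mg/ha, thousand kernel weight in g, protein in %
#' of dry matter, nitrogen uptake in g N/m2 in the motivating design).
#' Unparseable numeric cells become missing with a warning; duplicated
#' (line, treatment) rows and unknown treatment labels are hard errors.
#'
#' @param path file path; delimiter is auto-detected (TSV/CSV/whitespace).
#' @param line_col,treatment_col names of the identifier columns.
#' @param treatment_labels two-element character vector mapping the file's
#'   labels to `control` and `water_scarce`, in that order.
#' @param missing_tokens character values read as missing.
#' @return a `data.frame` of class `phenotype_table` with columns `line_id`,
#'   `treatment` (factor with levels `control`, `water_scarce`) and the
#'   numeric traits.
#' @export
read_phenotypes <- function(path, line_col = "line", treatment_col = "treatment",
                            treatment_labels = c("control", "water_scarce"),
                            missing_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = NULL, data.table = FALSE)
  if (!all(c(line_col, treatment_col) %in% names(dt))) {
    stop(sprintf("header must declare '%s' and '%s' columns", line_col, treatment_col))
  }
  trait_cols <- setdiff(names(dt), c(line_col, treatment_col))
  if (!length(trait_cols)) stop("no trait columns found")
  trt_raw <- dt[[treatment_col]]
  unknown <- setdiff(unique(trt_raw), treatment_labels)
  if (length(unknown)) {
    stop("unknown treatment label: ", paste(unknown, collapse = ", "))
  }
  treatment <- factor(c("control", "water_scarce")[match(trt_raw, treatment_labels)],
                      levels = c("control", "water_scarce"))
  key <- paste(dt[[line_col]], treatment)
  if (anyDuplicated(key)) {
    stop("duplicated (line, treatment) record: ", key[duplicated(key)][1])
  }
  out <- data.frame(line_id = dt[[line_col]], treatment = treatment,
                    stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    raw <- dt[[tc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !(raw %in% missing_tokens)
    if (any(bad)) {
      warning(sprintf("%d unparseable cell(s) in trait '%s' set to missing", sum(bad), tc))
    }
    out[[tc]] <- val
  }
  phenotype_table(out)
}

#' Construct / validate a phenotype table
#'
#' @param df data.frame with `line_id`, `treatment` and numeric trait columns.
#' @return `df` with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("line_id", "treatment") %in% names(df)))
  df$treatment <- factor(as.character(df$treatment),
                         levels = c("control", "water_scarce"))
  if (anyNA(df$treatment)) stop("treatment must be 'control' or 'water_scarce'")
  key <- paste(df$line_id, df$treatment)
  if (anyDuplicated(key)) {
    stop("duplicated (line, treatment) record: ", key[duplicated(key)][1])
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @export
print.phenotype_table <- function(x, ...) {
  traits <- setdiff(names(x), c("line_id", "treatment"))
  cat(sprintf("<phenotype_table> %d records, %d lines, traits: %s\n",
              nrow(x), length(unique(x$line_id)), paste(traits, collapse = ", ")))
  NextMethod()
}

#' List trait column names of a phenotype table
#' @param pheno a `phenotype_table`.
#' @export
trait_names <- function(pheno) setdiff(names(pheno), c("line_id", "treatment"))
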