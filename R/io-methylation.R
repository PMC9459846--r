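#' Read per-site, per-sample methylation counts
#'
#' Reads a BED-like long-format table of bisulfite counts with columns
#' `chrom`, `start`, `end`, `context`, `sample`, `methylated`, `total`
#' (tab-separated, 0-based half-open coordinates). Each row gives, for one
#' cytosine site in one sample, the number of reads calling the position
#' methylated and the total read count covering it.
#'
#' @param path file path.
#' @return a `data.frame` of class `methylation_counts` in file order.
#' @export
read_methylation_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom", "start", "end", "context", "sample", "methylated", "total")
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (!all(cols %in% names(dt))) {
    stop("methylation file must have columns: ", paste(cols, collapse = ", "))
  }
  dt <- dt[, cols]
  dt$start <- as.integer(dt$start)
  dt$end <- as.integer(dt$end)
  dt$methylated <- as.integer(dt$methylated)
  dt$total <- as.integer(dt$total)
  bad_ctx <- !dt$context %in% c("CG", "CHG", "CHH")
  if (any(bad_ctx)) {
    stop(sprintf("unknown methylation context '%s' at line %d",
                 dt$context[which(bad_ctx)[1]], which(bad_ctx)[1] + 1L))
  }
  over <- dt$methylated > dt$total
  if (any(over)) {
    stop(sprintf("methylated reads exceed total reads at line %d (%d > %d)",
                 which(over)[1] + 1L, dt$methylated[which(over)[1]],
                 dt$total[which(over)[1]]))
  }
  if (any(dt$methylated < 0 | dt$total < 0)) stop("negative read counts")
  class(dt) <- c("methylation_counts", "data.frame")
  dt
}

#' Write methylation counts in the long BED-like dialect
#'
#' @param counts a `methylation_counts` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation_bed <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
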