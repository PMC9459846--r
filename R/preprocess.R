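#' Filter report
#'
#' Bookkeeping object returned by the QC filters: feature counts in and out
#' plus per-rule removal counts (rules applied sequentially, so counts sum
#' to `n_in - n_out`).
#'
#' @param omic_kind omic layer the filter ran on.
#' @param n_in,n_out feature counts before/after.
#' @param removals named integer vector of per-rule removal counts.
#' @return list of class `filter_report`.
#' @export
filter_report <- function(omic_kind, n_in, n_out, removals) {
  stopifnot(n_out + sum(removals) == n_in)
  structure(list(omic_kind = omic_kind, n_features_in = n_in,
                 n_features_out = n_out, removals = removals),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d -> %d features\n", x$omic_kind,
              x$n_features_in, x$n_features_out))
  for (r in names(x$removals)) cat(sprintf("  %-12s -%d\n", r, x$removals[[r]]))
  invisible(x)
}

#' Filter SNP dosage matrices
#'
#' Applies the marker QC used before kernel construction, in fixed order:
#' (1) drop SNPs with more than `max_missing` missing calls, (2) drop
#' monomorphic SNPs (zero variance among observed calls; required because
#' centered-scaled kernels are undefined for constant columns), (3) prune
#' SNPs in high linkage disequilibrium, dropping the later member of any
#' pair with squared Pearson correlation above `ld_r2`.
#'
#' LD is computed on mean-imputed dosages by a greedy left-to-right scan in
#' input column order: each candidate is compared against already-retained
#' SNPs within a sliding window of `window` retained-or-seen positions;
#' `window = 0` compares against all retained SNPs (all-pairs prune). The
#' scan is deterministic and order-stable.
#'
#' @param geno an [omics_matrix()] of kind `snp` (0/1/2 dosages).
#' @param max_missing maximum tolerated missing fraction per SNP (default 0.20).
#' @param ld_r2 squared-correlation pruning threshold (default 0.9).
#' @param window window size in SNPs for the LD scan; 0 = all pairs.
#' @return `list(matrix = , report = )` with the filtered [omics_matrix()]
#'   and a [filter_report()].
#' @export
filter_snps <- function(geno, max_missing = 0.20, ld_r2 = 0.9, window = 50) {
  stopifnot(inherits(geno, "omics_matrix"), omic_kind(geno) == "snp")
  n_in <- ncol(geno)
  miss_frac <- colMeans(is.na(geno))
  keep1 <- miss_frac <= max_missing
  n_miss <- sum(!keep1)
  g1 <- subset_features(geno, keep1)

  v <- apply(unclass(g1), 2, stats::var, na.rm = TRUE)
  keep2 <- !is.na(v) & v > 0
  n_mono <- sum(!keep2)
  g2 <- subset_features(g1, keep2)

  # greedy windowed LD prune on mean-imputed dosages
  X <- unclass(g2)
  if (ncol(X) > 0) {
    X <- apply(X, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      col
    })
    Xs <- scale(X)  # unit columns -> r = crossprod / (n-1)
    p <- ncol(Xs)
    n1 <- nrow(Xs) - 1
    keep_idx <- integer(0)
    for (j in seq_len(p)) {
      if (length(keep_idx)) {
        cand <- if (window > 0) keep_idx[j - keep_idx <= window] else keep_idx
        if (length(cand)) {
          r <- crossprod(Xs[, cand, drop = FALSE], Xs[, j]) / n1
          if (any(r^2 > ld_r2)) next
        }
      }
      keep_idx <- c(keep_idx, j)
    }
    keep3 <- logical(p)
    keep3[keep_idx] <- TRUE
  } else {
    keep3 <- logical(0)
  }
  n_ld <- sum(!keep3)
  g3 <- subset_features(g2, keep3)
  if (ncol(g3) == 0) stop("no SNPs left after filtering")

  list(matrix = g3,
       report = filter_report("snp", n_in, ncol(g3),
                              c(missingness = n_miss, monomorphic = n_mono,
                                ld = n_ld)))
}

#' Compute methylation levels with coverage and presence filters
#'
#' Converts per-site read counts into a samples-by-sites matrix of
#' methylation levels (methylated reads / total reads). Cells with fewer
#' than `min_coverage` total reads are set missing, and sites observed
#' (non-missing) in less than `min_presence` of the samples are dropped.
#'
#' @param counts a `methylation_counts` table from [read_methylation_bed()].
#' @param min_coverage minimum read depth per cell (default 5).
#' @param min_presence minimum fraction of samples with a retained call per
#'   site (default 0.80).
#' @return an [omics_matrix()] of kind `methylation` (values in \[0, 1\])
#'   with site coordinates and context in `feature_meta`.
#' @export
methylation_levels <- function(counts, min_coverage = 5, min_presence = 0.80) {
  stopifnot(inherits(counts, "methylation_counts"), nrow(counts) > 0)
  site <- paste0(counts$chrom, ":", counts$start, "-", counts$end)
  samples <- sort(unique(counts$sample))
  sites <- unique(site)
  lvl <- matrix(NA_real_, length(samples), length(sites),
                dimnames = list(samples, sites))
  ok <- counts$total >= min_coverage
  idx <- cbind(match(counts$sample[ok], samples), match(site[ok], sites))
  lvl[idx] <- counts$methylated[ok] / counts$total[ok]
  presence <- colMeans(!is.na(lvl))
  keep <- presence >= min_presence
  lvl <- lvl[, keep, drop = FALSE]
  first <- counts[!duplicated(site), c("chrom", "start", "end", "context")]
  rownames(first) <- sites
  meta <- first[colnames(lvl), , drop = FALSE]
  meta <- data.frame(feature_id = colnames(lvl), meta, row.names = NULL)
  validate_omics_matrix(omics_matrix(lvl, "methylation", feature_meta = meta))
}

#' Split a methylation matrix by cytosine context
#'
#' Partitions sites into the three plant methylation contexts CG, CHG and
#' CHH; the three outputs are disjoint and jointly cover the input. A
#' context with no sites yields a 0-feature matrix.
#'
#' @param meth an [omics_matrix()] of kind `methylation` whose
#'   `feature_meta` has a `context` column.
#' @return named list of three [omics_matrix()] objects (`CG`, `CHG`, `CHH`).
#' @export
split_contexts <- function(meth) {
  stopifnot(inherits(meth, "omics_matrix"), omic_kind(meth) == "methylation")
  fm <- feature_meta(meth)
  if (is.null(fm) || !"context" %in% names(fm) || anyNA(fm$context)) {
    stop("every methylation feature must have a context")
  }
  out <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx) {
    subset_features(meth, fm$context == ctx)
  })
  out
}

#' Drop low-information methylation sites
#'
#' Removes sites dominated by zero methylation levels or by missing calls:
#' a site is kept iff its zero fraction (among observed cells) is at most
#' `max_zero_fraction` and its missing fraction is at most `max_missing`.
#'
#' @param meth an [omics_matrix()] of kind `methylation`.
#' @param max_zero_fraction maximum fraction of exact-zero levels (default 0.9).
#' @param max_missing maximum fraction of missing cells (default 0.2).
#' @return `list(matrix = , report = )`.
#' @export
filter_low_information_methylation <- function(meth, max_zero_fraction = 0.9,
                                               max_missing = 0.2) {
  stopifnot(inherits(meth, "omics_matrix"), omic_kind(meth) == "methylation")
  X <- unclass(meth)
  miss <- colMeans(is.na(X))
  nobs <- colSums(!is.na(X))
  zero <- colSums(X == 0, na.rm = TRUE) / pmax(nobs, 1L)
  drop_missing <- miss > max_missing
  drop_zero <- !drop_missing & zero > max_zero_fraction
  keep <- !(drop_missing | drop_zero)
  list(matrix = subset_features(meth, keep),
       report = filter_report("methylation", ncol(meth), sum(keep),
                              c(missing = sum(drop_missing),
                                zero = sum(drop_zero))))
}

#' Filter low-expression transcripts
#'
#' Excludes transcripts whose median TPM across samples is zero and whose
#' mean TPM is below 1 (both statistics over non-missing cells); with
#' `connective = "or"` either condition alone excludes.
#'
#' @param expr an [omics_matrix()] of kind `expression` (TPM values).
#' @param connective `"and"` (default) or `"or"`.
#' @return `list(matrix = , report = )`.
#' @export
filter_expression <- function(expr, connective = c("and", "or")) {
  stopifnot(inherits(expr, "omics_matrix"), omic_kind(expr) == "expression")
  connective <- match.arg(connective)
  X <- unclass(expr)
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  avg <- colMeans(X, na.rm = TRUE)
  excl <- if (connective == "and") (med == 0) & (avg < 1) else (med == 0) | (avg < 1)
  excl[is.na(excl)] <- TRUE
  list(matrix = subset_features(expr, !excl),
       report = filter_report("expression", ncol(expr), sum(!excl),
                              c(low_expression = sum(excl))))
}
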