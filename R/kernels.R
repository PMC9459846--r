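#' Center and scale an omics matrix
#'
#' Column-standardizes a lines-by-features matrix for kernel construction:
#' missing cells are imputed with the column mean (equivalently 0 after
#' centering), each column is centered to mean 0 and scaled to unit sample
#' standard deviation (n - 1 denominator). Zero-variance columns cannot be
#' scaled and are dropped with a message.
#'
#' @param X an [omics_matrix()] or plain numeric matrix with at least 2 rows.
#' @return plain numeric matrix of standardized retained columns, with an
#'   attribute `n_dropped` giving the zero-variance column count.
#' @export
center_scale <- function(X) {
  X <- unclass(as.matrix(X))
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("center_scale needs at least 2 lines")
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, colMeans(X), "-")
  s <- sqrt(colSums(X^2) / (nrow(X) - 1))
  keep <- is.finite(s) & s > 0
  if (!any(keep)) stop("all columns have zero variance")
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " zero-variance column(s) dropped")
  W <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
  attr(W, "n_dropped") <- n_dropped
  W
}

#' Build a similarity (relationship) kernel from an omics matrix
#'
#' Computes the VanRaden-style similarity matrix K = W W' / p, where W is
#' the centered-scaled omics matrix from [center_scale()] and p the number
#' of retained features. Dividing by p makes the mean diagonal equal 1 for
#' unit-variance columns, so K is on the scale of an additive genomic
#' relationship matrix. For noisy high-dimensional layers (expression), W
#' may optionally be replaced by its truncated principal-component
#' reconstruction before forming K: components are retained until they
#' explain at least `pca_var` of the total variance (`pca_var = 1`, the
#' default, reproduces the exact kernel).
#'
#' If the smallest eigenvalue falls below -1e-8 the kernel is repaired by
#' clipping negative eigenvalues at zero (logged); K is always returned
#' symmetric.
#'
#' @param X an [omics_matrix()] (rows = lines or samples).
#' @param pca_var variance fraction for PCA truncation of W, in (0, 1\].
#' @return a matrix of class `similarity_matrix` with attributes
#'   `source_omic` and `n_features_used`; dimnames are the row ids of `X`.
#' @export
similarity <- function(X, pca_var = 1) {
  stopifnot(pca_var > 0, pca_var <= 1)
  ids <- rownames(as.matrix(X))
  src <- if (inherits(X, "omics_matrix")) omic_kind(X) else "unknown"
  W <- center_scale(X)
  p <- ncol(W)
  if (pca_var < 1) {
    sv <- svd(W)
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    k <- which(cum >= pca_var)[1]
    W <- sv$u[, 1:k, drop = FALSE] %*% (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
  }
  K <- tcrossprod(W) / p
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    message("similarity: clipping ", sum(ev$values < 0),
            " negative eigenvalue(s) at 0")
    vals <- pmax(ev$values, 0)
    K <- ev$vectors %*% (vals * t(ev$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(ids, ids)
  structure(K, class = c("similarity_matrix", "matrix", "array"),
            source_omic = src, n_features_used = p)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d from %s (%d features); mean diag %.4f\n",
              nrow(x), ncol(x), attr(x, "source_omic"),
              attr(x, "n_features_used"), mean(diag(x))))
  invisible(x)
}
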