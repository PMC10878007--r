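#' Autoscale a feature matrix
#'
#' Mean-centers every column and divides it by its standard deviation, the
#' normalization applied to GC fatty-acid profiles before PCA. Columns with
#' zero variance carry no information after scaling and are dropped with a
#' warning.
#'
#' @param m numeric matrix or data frame (rows = samples, columns = named
#'   features).
#' @return Autoscaled matrix with attributes `center` and `scale`.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  stopifnot(is.numeric(m))
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (all(zero))
    stop("autoscale: every column has zero variance", call. = FALSE)
  if (any(zero)) {
    warning("autoscale: dropping ", sum(zero), " zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
    m <- m[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  ctr <- colMeans(m)
  out <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}

#' Principal component analysis by singular value decomposition
#'
#' Mean-centers the matrix (no rescaling — autoscale beforehand if desired)
#' and computes a deterministic SVD-based PCA. Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so
#' results are reproducible across runs and platforms.
#'
#' @param m numeric matrix (rows = samples); column names become loading
#'   names.
#' @param n_components number of components to keep; `NULL` keeps all.
#'   Requests beyond `min(nrow - 1, ncol)` are clipped with a warning.
#' @return An object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components, orthonormal),
#'   `explained_variance_fraction`, `center` and `sdev`.
#' @export
pca_fit <- function(m, n_components = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 1, !anyNA(m))
  maxk <- min(nrow(m) - 1L, ncol(m))
  k <- n_components %||% maxk
  if (k > maxk) {
    warning("pca_fit: n_components clipped from ", k, " to ", maxk,
            call. = FALSE)
    k <- maxk
  }
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc, nu = maxk, nv = maxk)
  ev <- sv$d[seq_len(maxk)]^2
  expl <- ev / sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(maxk)], maxk)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(maxk)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  cn <- paste0("PC", seq_len(k))
  scores <- scores[, seq_len(k), drop = FALSE]
  loadings <- loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- cn; colnames(loadings) <- cn
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = expl[seq_len(k)],
                 center = ctr, sdev = sv$d[seq_len(maxk)] / sqrt(nrow(m) - 1)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, ",
      ncol(x$scores), " components; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Grouped Pearson correlation
#'
#' Pearson correlation between two paired per-sample quantities (typically
#' the FTIR L/P ratio and the GC total lipid content), overall or within the
#' groups a metadata column defines. Groups with fewer than two complete
#' pairs, or zero variance in either variable, get an undefined (`NA`)
#' coefficient with an explanatory flag rather than being dropped.
#'
#' @param df data frame holding both variables (and the grouping column).
#' @param x,y names of the two numeric columns.
#' @param group name of the grouping column, or `NULL` for the whole dataset.
#' @return Data frame `grouping`, `group`, `n`, `r`, `flag`.
#' @export
pearson_by_group <- function(df, x, y, group = NULL) {
  stopifnot(is.data.frame(df), x %in% names(df), y %in% names(df))
  one <- function(sub, label) {
    ok <- stats::complete.cases(sub[[x]], sub[[y]])
    n <- sum(ok)
    if (n < 2)
      return(data.frame(grouping = group %||% "all", group = label, n = n,
                        r = NA_real_, flag = "n < 2"))
    xs <- sub[[x]][ok]; ys <- sub[[y]][ok]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
      return(data.frame(grouping = group %||% "all", group = label, n = n,
                        r = NA_real_, flag = "zero variance"))
    data.frame(grouping = group %||% "all", group = label, n = n,
               r = stats::cor(xs, ys), flag = "")
  }
  if (is.null(group)) return(one(df, "all"))
  stopifnot(group %in% names(df))
  out <- do.call(rbind, lapply(split(df, df[[group]]), function(sub)
    one(sub, as.character(sub[[group]][1]))))
  rownames(out) <- NULL
  out
}
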