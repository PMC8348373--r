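# Multivariate QC: group-level relative-abundance profiles, PCA of group
# profiles and Pearson correlation utilities.

#' Group-level relative-abundance profiles
#'
#' Per feature: replicate-averaged abundance per group, converted into the
#' feature's percentage share across the six groups (shares sum to 100).
#' Features missing in all replicates of any group are excluded (count
#' reported via `message`).
#'
#' @param qm A [quant_matrix()].
#' @param design Validated `GroupDesign`.
#' @return Numeric matrix features x groups of percentage shares, with
#'   attribute `excluded` (number of dropped features).
#' @export
group_profiles <- function(qm, design) {
  design <- validate_design(design)
  groups <- unique(design$group)
  v <- qm$values
  gm <- sapply(groups, function(g) {
    cols <- design_samples(design, g)
    rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
  })
  gm[is.nan(gm)] <- NA_real_
  keep <- rowSums(is.na(gm)) == 0
  if (any(!keep))
    message(sum(!keep), " feature(s) excluded from group profiles: ",
            "unobserved in at least one group")
  gm <- gm[keep, , drop = FALSE]
  prof <- 100 * gm / rowSums(gm)
  attr(prof, "excluded") <- sum(!keep)
  prof
}

#' PCA of group profiles
#'
#' Decomposes the group x feature share matrix (feature columns centered,
#' no scaling) by singular values and returns the first two components'
#' group scores and variance fractions. Component signs are fixed so the
#' loading of largest magnitude is positive, making scores reproducible.
#'
#' @param profile Feature x group matrix from [group_profiles()].
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (groups x components), `var_explained`
#'   (fractions of total variance) and `loadings`.
#' @export
pca_scores <- function(profile, n_components = 2) {
  if (nrow(profile) < 3)
    stop("dimension error: need >= 3 features for PCA")
  if (ncol(profile) < 2)
    stop("dimension error: need >= 2 groups for PCA")
  x <- t(profile)                       # groups x features
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       loadings = loadings)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with the validation the QC figures rely on: equal
#' lengths of at least 3 and non-zero variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("pearson error: unequal lengths")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("pearson error: need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson error: zero variance — correlation undefined")
  stats::cor(x, y)
}
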