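#' Standardise-then-SVD principal component basis
#'
#' Fits the PCA basis shared by shape space (flattened momenta) and field
#' space (stacked pressure/velocity fields): each column is standardised
#' (mean removed, scaled to unit variance; constant columns are flagged and
#' given SD 1 so they never contribute), then the standardised matrix is
#' decomposed by SVD. The number of retained modes is either the smallest
#' prefix reaching a cumulative variance target (0.99 for shapes and
#' pressure) or a fixed mode count (55 for velocity).
#'
#' @param M n x d data matrix (n subjects, d coefficients).
#' @param var_target cumulative variance fraction to reach (used when
#'   `fixed_k` is `NULL`).
#' @param fixed_k retain exactly this many modes (capped at the rank).
#' @return An object of class `pca_basis`: `column_mean`, `column_sd`,
#'   `constant_columns`, `components` (k x d, orthonormal rows),
#'   `singular_values`, `variance_fraction`, `n_train`, `mode_rule`.
#' @export
fit_pca <- function(M, var_target = 0.99, fixed_k = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 rows to fit a PCA basis")
  if (anyNA(M) || any(!is.finite(M))) stop("non-finite entries in M")
  mu <- colMeans(M)
  sd_ <- apply(M, 2L, stats::sd)
  constant <- sd_ <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  sd_use <- ifelse(constant, 1, sd_)
  Z <- sweep(sweep(M, 2L, mu), 2L, sd_use, `/`)
  Z[, constant] <- 0
  sv <- svd(Z)
  pos <- sv$d > max(sv$d[1L], 1e-30) * 1e-12
  if (!any(pos)) {
    # rank-0 (all columns constant): a single inert mode keeps the
    # contracts alive; scores are zero and reconstruction is the mean
    e1 <- rep(0, ncol(M))
    e1[1L] <- 1
    return(structure(list(
      column_mean = mu, column_sd = sd_use,
      constant_columns = which(constant),
      components = matrix(e1, 1L), singular_values = 0,
      variance_fraction = 1, all_singular_values = 0,
      n_train = nrow(M),
      mode_rule = if (is.null(fixed_k)) sprintf("var:%g", var_target)
                  else "k:1"), class = "pca_basis"))
  }
  d_all <- sv$d[pos]
  varfrac_all <- d_all^2 / sum(d_all^2)
  k <- if (!is.null(fixed_k)) {
    if (fixed_k < 1L) stop("fixed_k must be >= 1")
    min(as.integer(fixed_k), length(d_all))
  } else {
    if (var_target <= 0 || var_target > 1) stop("var_target must be in (0,1]")
    which(cumsum(varfrac_all) >= var_target - 1e-12)[1L]
  }
  structure(list(
    column_mean = mu,
    column_sd = sd_use,
    constant_columns = which(constant),
    components = t(sv$v[, seq_len(k), drop = FALSE]),
    singular_values = d_all[seq_len(k)],
    variance_fraction = varfrac_all[seq_len(k)],
    all_singular_values = d_all,
    n_train = nrow(M),
    mode_rule = if (is.null(fixed_k)) sprintf("var:%g", var_target)
                else sprintf("k:%d", k)
  ), class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf(
    "pca_basis: %d modes over %d coefficients (%s, %.1f%% variance, n=%d)\n",
    nrow(x$components), ncol(x$components), x$mode_rule,
    100 * sum(x$variance_fraction), x$n_train))
  invisible(x)
}

#' Project rows onto a PCA basis
#'
#' Standardises the rows with the training mean/SD and multiplies by the
#' transposed components, giving the mode weights (the `US` projection of the
#' training matrix).
#'
#' @param basis a [fit_pca()] basis.
#' @param rows n x d matrix (or a single length-d vector).
#' @return n x k score matrix.
#' @export
pca_project <- function(basis, rows) {
  rows <- row_matrix(rows, ncol(basis$components))
  Z <- sweep(sweep(rows, 2L, basis$column_mean), 2L, basis$column_sd, `/`)
  if (length(basis$constant_columns)) Z[, basis$constant_columns] <- 0
  Z %*% t(basis$components)
}

#' Reconstruct rows from PCA scores
#'
#' Multiplies scores by the components and reverses the standardisation
#' (the `L = X S V^T` reconstruction with de-standardisation).
#'
#' @param basis a [fit_pca()] basis.
#' @param scores n x k score matrix (or a single length-k vector).
#' @return n x d matrix of reconstructed rows.
#' @export
pca_reconstruct <- function(basis, scores) {
  scores <- row_matrix(scores, nrow(basis$components))
  Z <- scores %*% basis$components
  sweep(sweep(Z, 2L, basis$column_sd, `*`), 2L, basis$column_mean, `+`)
}

row_matrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop("dimension mismatch: expected length ", d)
    matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d) stop("dimension mismatch: expected ", d, " columns")
    x
  }
}

#' Sample synthetic subjects in PCA score space
#'
#' Draws each mode independently from a Gaussian fitted to the training
#' weights of that mode, rejection-resampled until every draw lies within
#' `truncation_sd` standard deviations of the mode mean (the paper samples
#' within 2 SD). Rejection, not clipping, so no mass piles up at the
#' boundary.
#'
#' @param basis a [fit_pca()] basis (used for dimension checks).
#' @param scores_train n x k training score matrix.
#' @param n number of synthetic subjects to draw.
#' @param truncation_sd truncation half-width in training SDs (> 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return n x k matrix of synthetic scores.
#' @export
sample_synthetic <- function(basis, scores_train, n, truncation_sd = 2,
                             seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (truncation_sd <= 0) stop("truncation_sd must be positive")
  scores_train <- as.matrix(scores_train)
  if (ncol(scores_train) != nrow(basis$components)) {
    stop("training scores do not match the basis mode count")
  }
  m <- colMeans(scores_train)
  s <- apply(scores_train, 2L, stats::sd)
  with_seed(seed, {
    out <- matrix(0, n, ncol(scores_train))
    for (j in seq_len(ncol(out))) {
      if (s[j] == 0) { out[, j] <- m[j]; next }
      x <- stats::rnorm(n, m[j], s[j])
      bad <- abs(x - m[j]) > truncation_sd * s[j]
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), m[j], s[j])
        bad <- abs(x - m[j]) > truncation_sd * s[j]
      }
      out[, j] <- x
    }
    out
  })
}
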