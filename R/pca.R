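#' Fit a principal component analysis model
#'
#' Columns are standardized to zero mean and unit sample (divide by n - 1)
#' variance, so the analysed covariance matrix `t(Y) %*% Y / (n - 1)` is the
#' correlation matrix of the training data. Eigenpairs are sorted by
#' decreasing eigenvalue and each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive. When `n - 1 < p` the eigenpairs are
#' obtained through the thin SVD of the standardized data matrix (identical
#' result, avoids forming a p x p matrix); only the `k = min(n, p)`
#' identifiable components are stored.
#'
#' Zero-variance columns are standardized to all-zeros (with a warning) and
#' carry no loading weight.
#'
#' @param X numeric matrix, n samples x p features.
#' @param m number of components retained for projection and contribution
#'   weights (default 32, the canonical choice); `1 <= m <= k`.
#' @return object of class `pca_model`: `means`, `sds`, `eigenvalues`
#'   (length k), `eigenvectors` (p x k, orthonormal columns), `m`, `n_train`,
#'   `feature_names`.
#' @export
fit_pca <- function(X, m = 32L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("insufficient data: PCA needs at least 2 samples", call. = FALSE)
  if (m < 1L || m > p) stop("dimension error: m must be in [1, p]", call. = FALSE)
  means <- colMeans(X)
  sds <- sqrt(apply(X, 2L, stats::var))
  zero <- sds < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature column(s) standardized to zeros")
    sds[zero] <- Inf  # (x - mean)/Inf -> 0
  }
  Y <- sweep(sweep(X, 2L, means, "-"), 2L, sds, "/")
  if (n - 1L >= p) {
    ed <- eigen(crossprod(Y) / (n - 1), symmetric = TRUE)
    values <- ed$values
    vectors <- ed$vectors
  } else {
    sv <- svd(Y, nu = 0L)
    values <- sv$d^2 / (n - 1)
    vectors <- sv$v
  }
  values <- pmax(values, 0)
  # deterministic sign: largest-|.| loading positive
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  k <- ncol(vectors)
  if (m > k) {
    stop("dimension error: m = ", m, " exceeds the ", k,
         " identifiable components (min(n, p))", call. = FALSE)
  }
  structure(list(means = means, sds = sds, eigenvalues = values,
                 eigenvectors = vectors, m = as.integer(m),
                 n_train = n, feature_names = colnames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> p=", length(x$means), ", k=", length(x$eigenvalues),
      ", m=", x$m, ", n_train=", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Project feature vectors onto the retained principal components
#'
#' Standardizes with the model's stored means and variances, then returns the
#' first `m` principal-component coordinates `t(E[, 1:m]) %*% y`.
#'
#' @param model a fitted [fit_pca] model.
#' @param x numeric vector of length p, or an n x p matrix (rows projected
#'   independently).
#' @param m number of components (default: the model's `m`).
#' @return numeric vector of length m, or an n x m score matrix.
#' @export
project <- function(model, x, m = model$m) {
  stopifnot(inherits(model, "pca_model"), m >= 1L,
            m <= ncol(model$eigenvectors))
  p <- length(model$means)
  if (is.matrix(x)) {
    if (ncol(x) != p) stop("length mismatch: expected ", p, " features", call. = FALSE)
    Y <- sweep(sweep(x, 2L, model$means, "-"), 2L, model$sds, "/")
    return(Y %*% model$eigenvectors[, seq_len(m), drop = FALSE])
  }
  if (length(x) != p) stop("length mismatch: expected ", p, " features", call. = FALSE)
  y <- (x - model$means) / model$sds
  as.vector(crossprod(model$eigenvectors[, seq_len(m), drop = FALSE], y))
}

#' Per-feature contribution weights
#'
#' The weight of feature j is the sum of its squared loadings over the m
#' retained eigenvectors, `w_j = sum_{i=1..m} E_{ij}^2`. By column
#' orthonormality the weights sum to m; with m = k = p every weight is 1.
#'
#' @inheritParams project
#' @return object of class `contribution_weights`: numeric vector `weights`
#'   (length p, named when the model kept feature names) plus `m`.
#' @export
contribution_weights <- function(model, m = model$m) {
  stopifnot(inherits(model, "pca_model"), m >= 1L,
            m <= ncol(model$eigenvectors))
  w <- rowSums(model$eigenvectors[, seq_len(m), drop = FALSE]^2)
  names(w) <- model$feature_names
  structure(list(weights = w, m = as.integer(m)),
            class = "contribution_weights")
}

#' @export
print.contribution_weights <- function(x, ...) {
  cat("<contribution_weights> p=", length(x$weights), ", m=", x$m,
      ", sum=", format(sum(x$weights)), "\n", sep = "")
  invisible(x)
}

#' Average contribution weight per feature block
#'
#' Aggregates [contribution_weights] over the canonical feature blocks (AAC,
#' DC, AD, GD, SD, PseAAC) -- the quantity used to rank descriptor groups by
#' influence.
#'
#' @param cw a `contribution_weights` object for a model fitted on full
#'   1497-feature vectors.
#' @return named numeric vector of 6 block means.
#' @export
block_contributions <- function(cw) {
  stopifnot(inherits(cw, "contribution_weights"),
            length(cw$weights) == 1497L)
  fb <- feature_blocks()
  out <- vapply(seq_len(nrow(fb)), function(i)
    mean(cw$weights[fb$start[i]:fb$end[i]]), numeric(1L))
  stats::setNames(out, fb$block)
}

#' Select the number of retained components by jackknife accuracy
#'
#' Sweeps m over `m_range`, computing the jackknife overall accuracy for each
#' value, and returns the smallest m attaining the maximum (parsimony
#' tie-break). The sweep shares one jackknife pass: per fold the PCA is fitted
#' once at `max(m_range)` and predictions are recomputed per truncation, which
#' is equivalent to calling [jackknife_evaluate] per m.
#'
#' @param X numeric feature matrix (n x p).
#' @param labels class label per row.
#' @param m_range integer vector of candidate m values.
#' @param pca_scope `"per_fold"` (refit PCA without the held-out sample; no
#'   leakage) or `"global"` (fit once on all data).
#' @param rng_seed integer seed driving the tie-break randomness.
#' @return list with `best_m`, `oacc_curve` (named numeric vector, percent),
#'   and `flagged_singletons`.
#' @export
select_m <- function(X, labels, m_range = 1:32,
                     pca_scope = c("per_fold", "global"), rng_seed = 1L) {
  pca_scope <- match.arg(pca_scope)
  m_range <- sort(unique(as.integer(m_range)))
  res <- jackknife_core(as.matrix(X), as.character(labels), m_range,
                        pca_scope, rng_seed)
  oacc <- vapply(res$predictions, function(pred)
    100 * mean(pred == labels), numeric(1L))
  names(oacc) <- as.character(m_range)
  best <- m_range[which.max(oacc)]  # which.max returns first (smallest) max
  list(best_m = best, oacc_curve = oacc,
       flagged_singletons = res$flagged_singletons)
}
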