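# Shared leave-one-out engine. For each fold the PCA is fitted (or reused,
# for pca_scope = "global") at max(ms) components and the held-out sample is
# classified once per requested m. Returns the prediction vectors per m.
jackknife_core <- function(X, labels, ms, pca_scope, rng_seed) {
  n <- nrow(X)
  if (n < 2L) stop("evaluation error: need at least 2 samples", call. = FALSE)
  stopifnot(length(labels) == n)
  m_max <- max(ms)
  tot <- table(labels)
  flagged <- names(tot)[tot == 1L]

  preds <- lapply(ms, function(m) character(n))
  names(preds) <- as.character(ms)

  # one summary warning instead of one per fold
  n_const <- sum(apply(X, 2L, stats::var) < 1e-24)
  if (n_const > 0L) {
    warning(n_const, " near-constant feature column(s); they carry no weight",
            call. = FALSE)
  }

  if (pca_scope == "global") {
    m_fit <- min(m_max, n, ncol(X))
    pca <- suppressWarnings(fit_pca(X, m_fit))
    S <- project(pca, X, m = m_fit)
  }
  for (i in seq_len(n)) {
    if (pca_scope == "per_fold") {
      if (n - 1L < 2L) {
        # a single training point cannot support a PCA fit; classify on the
        # raw feature vectors instead
        m_fit <- ncol(X)
        Z <- X[-i, , drop = FALSE]
        q <- X[i, ]
      } else {
        m_fit <- min(m_max, n - 1L, ncol(X))
        pca <- suppressWarnings(fit_pca(X[-i, , drop = FALSE], m_fit))
        Z <- project(pca, X[-i, , drop = FALSE], m = m_fit)
        q <- project(pca, X[i, ], m = m_fit)
      }
    } else {
      Z <- S[-i, , drop = FALSE]
      q <- S[i, ]
    }
    seed_i <- derive_seed(rng_seed, i)
    for (ms_j in seq_along(ms)) {
      m <- min(ms[ms_j], m_fit)
      ts <- training_set(Z[, seq_len(m), drop = FALSE], labels[-i])
      preds[[ms_j]][i] <- predict_class(q[seq_len(m)], ts, seed_i)$label
    }
  }
  list(predictions = preds, flagged_singletons = flagged)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Singles out each sample in turn, trains on the remaining n - 1 (refitting
#' the PCA inside the fold by default, so no information from the held-out
#' sample leaks into the projection), classifies the held-out sample by
#' intimate sorting, and accumulates per-class accuracy
#' `ACC(i) = C(i) / Tot(i)` and overall accuracy
#' `OACC = sum(C) / sum(Tot)`, both reported in percent.
#'
#' Classes with a single member are evaluated (and necessarily misclassified,
#' since their only exemplar is held out) and flagged in the report rather
#' than dropped.
#'
#' @param X numeric feature matrix (n x p).
#' @param labels class label per row.
#' @param m number of retained principal components (default 32; capped at
#'   the fold's identifiable components).
#' @param pca_scope `"per_fold"` (default, leakage-free) or `"global"` (PCA
#'   fitted once on the full data before the folds).
#' @param rng_seed integer seed; fold tie-break seeds are derived from it so
#'   results are independent of execution order.
#' @return object of class `jackknife_report`: `per_class` data.frame
#'   (`class`, `Tot`, `C`, `ACC`), `overall` list (`Tot`, `C`, `OACC`),
#'   `confusion` matrix (rows = true class), `settings`,
#'   `flagged_singletons`.
#' @export
jackknife_evaluate <- function(X, labels, m = 32L,
                               pca_scope = c("per_fold", "global"),
                               rng_seed = 1L) {
  pca_scope <- match.arg(pca_scope)
  X <- as.matrix(X)
  labels <- as.character(labels)
  res <- jackknife_core(X, labels, as.integer(m), pca_scope, rng_seed)
  pred <- res$predictions[[1L]]

  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(pred, classes))
  per_class <- data.frame(
    class = classes,
    Tot = as.integer(table(factor(labels, classes))),
    C = vapply(classes, function(k) sum(labels == k & pred == k), integer(1L)),
    row.names = NULL)
  per_class$ACC <- 100 * per_class$C / per_class$Tot
  overall <- list(Tot = nrow(X), C = sum(per_class$C),
                  OACC = 100 * sum(per_class$C) / nrow(X))
  structure(list(per_class = per_class, overall = overall,
                 confusion = unclass(confusion),
                 settings = list(m = as.integer(m), pca_scope = pca_scope,
                                 rng_seed = as.integer(rng_seed)),
                 flagged_singletons = res$flagged_singletons),
            class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat("Jackknife evaluation (m=", x$settings$m, ", pca_scope=",
      x$settings$pca_scope, ")\n", sep = "")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Overall: %d/%d  OACC = %.2f%%\n",
              x$overall$C, x$overall$Tot, x$overall$OACC))
  if (length(x$flagged_singletons)) {
    cat("Flagged singleton classes (cannot be predicted correctly):",
        paste(x$flagged_singletons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a jackknife report as TSV
#'
#' One row per class (`class`, `Tot`, `C`, `ACC`) plus an `Overall` row; reads
#' back losslessly with [read.delim].
#'
#' @param report a `jackknife_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "jackknife_report"))
  df <- rbind(report$per_class,
              data.frame(class = "Overall", Tot = report$overall$Tot,
                         C = report$overall$C, ACC = report$overall$OACC))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
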