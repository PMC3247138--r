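#' Cosine similarity between two vectors
#'
#' `Phi(p, q) = (p . q) / (||p|| ||q||)`, in \[-1, 1\]; `Phi(p, p) = 1` for any
#' nonzero p. Zero-norm inputs are rejected (the similarity is undefined
#' there).
#'
#' @param p,q numeric vectors of equal length.
#' @return similarity score in \[-1, 1\].
#' @export
cosine_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("dimension mismatch", call. = FALSE)
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) {
    stop("undefined similarity: zero-norm vector", call. = FALSE)
  }
  sum(p * q) / (np * nq)
}

#' Construct a training set of projected vectors
#'
#' @param vectors numeric matrix, one training vector per row.
#' @param labels class label per row.
#' @param level_tag optional hierarchy-level annotation.
#' @return object of class `training_set`.
#' @export
training_set <- function(vectors, labels, level_tag = NA_integer_) {
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  stopifnot(nrow(vectors) >= 1L, nrow(vectors) == length(labels))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("training set contains a zero-norm vector", call. = FALSE)
  structure(list(vectors = vectors, labels = labels, norms = norms,
                 level_tag = level_tag),
            class = "training_set")
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Knuth multiplicative hash, kept within 32-bit integer range
derive_seed <- function(rng_seed, index) {
  as.integer((as.double(rng_seed) * 2654435761 + as.double(index)) %% 2147483647)
}

#' Intimate-sorting (nearest-prototype) classification
#'
#' Assigns the query the label of the training vector with the highest cosine
#' similarity. Scores within 1e-12 of the maximum are treated as tied; a tie
#' is resolved by a uniform draw from the tied set using the seeded generator,
#' so identical (query, training set, seed) triples always give the same
#' answer.
#'
#' @param query numeric vector (same dimension as the training vectors).
#' @param train a [training_set].
#' @param rng_seed integer seed for the tie-break.
#' @return list with `label` and `best_score`.
#' @export
predict_class <- function(query, train, rng_seed = 1L) {
  stopifnot(inherits(train, "training_set"))
  if (length(query) != ncol(train$vectors)) {
    stop("dimension mismatch between query and training vectors", call. = FALSE)
  }
  nq <- sqrt(sum(query^2))
  if (nq == 0) stop("undefined similarity: zero-norm query", call. = FALSE)
  sims <- as.vector(train$vectors %*% query) / (train$norms * nq)
  top <- max(sims)
  tied <- which(sims >= top - 1e-12)
  pick <- if (length(tied) == 1L) tied else
    with_local_seed(rng_seed, tied[sample.int(length(tied), 1L)])
  list(label = train$labels[pick], best_score = sims[pick])
}

# ---- hierarchical cascade ------------------------------------------------

build_hierarchy_node <- function(X, labs, level, m, max_level) {
  lab_now <- labs[[paste0("level", level)]]
  keep <- !is.na(lab_now) & nzchar(lab_now)
  X <- X[keep, , drop = FALSE]
  labs <- labs[keep, , drop = FALSE]
  lab_now <- lab_now[keep]
  if (nrow(X) < 2L) {
    stop("configuration error: hierarchy node at level ", level,
         " has fewer than 2 labeled training sequences", call. = FALSE)
  }
  m_eff <- min(m, nrow(X), ncol(X))
  pca <- fit_pca(X, m_eff)
  ts <- training_set(project(pca, X), lab_now, level_tag = level)
  children <- list()
  if (level < max_level) {
    nxt <- labs[[paste0("level", level + 1L)]]
    for (val in unique(lab_now)) {
      sub <- lab_now == val & !is.na(nxt) & nzchar(nxt)
      if (sum(sub) >= 2L) {
        children[[val]] <- build_hierarchy_node(
          X[lab_now == val, , drop = FALSE],
          labs[lab_now == val, , drop = FALSE], level + 1L, m, max_level)
      }
    }
  }
  list(level = level, pca = pca, train = ts, children = children)
}

#' Train the five-level hierarchical classifier
#'
#' Builds a tree of per-node classifiers: the root (level 1) is trained on all
#' labeled sequences; for every level-k label that carries deeper annotations,
#' a child node is trained on that label's subset with its level-(k+1) labels.
#' Each node owns its own PCA model (fitted on its subset, m capped at the
#' node's identifiable components) and projected training set, mirroring a
#' cascade of independently trained classifiers.
#'
#' @param X numeric feature matrix (rownames = sequence ids), typically from
#'   [extract_features_matrix].
#' @param labels label table: data.frame with column `id` and columns
#'   `level1` ... `level5` (trailing levels may be empty strings for branches
#'   that terminate early), as read by [read_labels].
#' @param m retained components per node (default 32).
#' @return object of class `hierarchy_model`.
#' @export
train_hierarchy <- function(X, labels, m = 32L) {
  stopifnot(is.data.frame(labels), "id" %in% names(labels))
  lv <- grep("^level[0-9]+$", names(labels), value = TRUE)
  if (length(lv) < 1L) stop("label table has no level columns", call. = FALSE)
  max_level <- min(5L, length(lv))
  idx <- match(rownames(X), labels$id)
  if (anyNA(idx)) {
    stop("feature matrix contains ids absent from the label table: ",
         paste(utils::head(rownames(X)[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  }
  labs <- labels[idx, , drop = FALSE]
  root <- build_hierarchy_node(X, labs, 1L, m, max_level)
  structure(list(root = root, m = as.integer(m), p = ncol(X)),
            class = "hierarchy_model")
}

#' @export
print.hierarchy_model <- function(x, ...) {
  count_nodes <- function(node) 1L + sum(vapply(node$children, count_nodes,
                                                integer(1L)))
  cat("<hierarchy_model> p=", x$p, ", m=", x$m, ", nodes=",
      count_nodes(x$root), "\n", sep = "")
  invisible(x)
}

#' Classify a sequence down the hierarchical cascade
#'
#' Extracts the feature vector once, then walks the tree: at each node the
#' vector is projected with that node's PCA model and classified by intimate
#' sorting; if a child classifier exists for the predicted label the walk
#' descends, otherwise it stops (e.g. immediately after a level-1 non-target
#' prediction, or at a branch with no deeper levels).
#'
#' @param seq a [protein_sequence], or a precomputed numeric feature vector of
#'   length p.
#' @param model a [train_hierarchy] model.
#' @param rng_seed integer seed; per-level tie-break seeds are derived from
#'   it.
#' @return data.frame with columns `level`, `label`, `score` (one row per
#'   visited level).
#' @export
predict_hierarchy <- function(seq, model, rng_seed = 1L) {
  stopifnot(inherits(model, "hierarchy_model"))
  x <- if (inherits(seq, "protein_sequence")) extract_features(seq) else seq
  if (length(x) != model$p) {
    stop("dimension mismatch: expected ", model$p, " features", call. = FALSE)
  }
  node <- model$root
  out <- list()
  repeat {
    if (is.null(node$pca)) stop("configuration error: node without a fitted model",
                                call. = FALSE)
    z <- project(node$pca, as.numeric(x))
    pred <- predict_class(z, node$train, derive_seed(rng_seed, node$level))
    out[[length(out) + 1L]] <- data.frame(level = node$level,
                                          label = pred$label,
                                          score = pred$best_score)
    child <- node$children[[pred$label]]
    if (is.null(child)) break
    node <- child
  }
  do.call(rbind, out)
}
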