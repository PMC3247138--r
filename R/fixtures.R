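#' Specification for the synthetic labeled-sequence generator
#'
#' Describes a desk-scale hierarchical multi-class dataset: a ragged class
#' tree, per-class residue-composition profiles, and an optional planted
#' lag-1 autocorrelation signal. Defaults describe the strong-bias regime
#' used throughout the test suite: 30 sequences per class, lengths 100-400,
#' and a composition bias of 0.5 concentrated on 4 class-specific dominant
#' residues (disjoint across up to 5 terminal classes).
#'
#' The class tree is built from `n_classes = c(k1, k2, ...)`: level 1 has k1
#' classes of which only the first descends (mirroring a target/non-target
#' first level); at deeper levels every class except the last descends,
#' leaving ragged branches that terminate early.
#'
#' @param n_classes integer vector: class counts per level (length = depth).
#' @param sequences_per_class sequences generated for each terminal class.
#' @param length_range integer interval for sequence lengths; lower bound
#'   must be >= 31.
#' @param composition_bias in \[0, 1\]: mixing weight of the class-specific
#'   dominant-residue profile against the uniform background (0 = all classes
#'   identical, chance-level dataset).
#' @param autocorr_bias in \[0, 1): probability that a residue copies its
#'   predecessor, planting class-independent lag-1 autocorrelation.
#' @param seed integer; the generator is fully determined by it.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes = c(2L, 4L), sequences_per_class = 30L,
                         length_range = c(100L, 400L),
                         composition_bias = 0.5, autocorr_bias = 0,
                         seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (length(n_classes) < 1L || any(n_classes < 1L)) {
    stop("invalid fixture spec: n_classes must be positive", call. = FALSE)
  }
  if (sequences_per_class < 1L) {
    stop("invalid fixture spec: sequences_per_class must be positive", call. = FALSE)
  }
  if (length(length_range) != 2L || length_range[1] < 31L ||
      length_range[2] < length_range[1]) {
    stop("invalid fixture spec: length_range lower bound must be >= 31", call. = FALSE)
  }
  if (composition_bias < 0 || composition_bias > 1 ||
      autocorr_bias < 0 || autocorr_bias >= 1) {
    stop("invalid fixture spec: biases must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_classes = n_classes,
                 sequences_per_class = as.integer(sequences_per_class),
                 length_range = as.integer(length_range),
                 composition_bias = composition_bias,
                 autocorr_bias = autocorr_bias, seed = as.integer(seed)),
            class = "fixture_spec")
}

# enumerate terminal classes and their level-label paths
fixture_tree <- function(n_classes) {
  depth <- length(n_classes)
  paths <- list()
  walk <- function(path, level) {
    if (level > depth) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    k <- n_classes[level]
    for (j in seq_len(k)) {
      label <- if (level == 1L) paste0("C", j) else
        paste0(path[length(path)], ".", j)
      child_path <- c(path, label)
      descends <- if (level == 1L) j == 1L else j < k
      if (descends && level < depth) {
        walk(child_path, level + 1L)
      } else {
        paths[[length(paths) + 1L]] <<- child_path
      }
    }
    invisible()
  }
  walk(character(0L), 1L)
  paths
}

#' Generate a seeded synthetic labeled dataset
#'
#' Draws sequences from class-specific residue distributions (uniform
#' background mixed with a dominant-residue spike per terminal class),
#' optionally smears in lag-1 repeats, and assigns hierarchical labels
#' consistent with the routing tree of the spec. Byte-identical output for
#' identical spec + seed.
#'
#' @param spec a [fixture_spec].
#' @return list with `sequences` (list of [protein_sequence]) and `labels`
#'   (data.frame: `id`, `level1` ... up to the tree depth; empty string where
#'   a branch terminates early).
#' @examples
#' fx <- generate_fixtures(fixture_spec(n_classes = 4, sequences_per_class = 5))
#' fx$labels[1:3, ]
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  paths <- fixture_tree(spec$n_classes)
  depth <- length(spec$n_classes)
  n_term <- length(paths)
  b <- spec$composition_bias

  with_local_seed(spec$seed, {
    seqs <- list()
    labs <- list()
    for (t in seq_len(n_term)) {
      dom <- ((t - 1L) * 4L + 0:3) %% 20L + 1L
      profile <- rep((1 - b) / 20, 20L)
      profile[dom] <- profile[dom] + b / 4
      for (r in seq_len(spec$sequences_per_class)) {
        lens <- seq(spec$length_range[1], spec$length_range[2])
        L <- lens[sample.int(length(lens), 1L)]
        idx <- sample.int(20L, L, replace = TRUE, prob = profile)
        if (spec$autocorr_bias > 0 && L > 1L) {
          copy <- stats::runif(L - 1L) < spec$autocorr_bias
          for (i in which(copy)) idx[i + 1L] <- idx[i]
        }
        id <- sprintf("fx_t%02d_s%03d", t, r)
        seqs[[length(seqs) + 1L]] <- protein_sequence(
          id, paste(AMINO_ACIDS[idx], collapse = ""))
        row <- c(paths[[t]], rep("", depth - length(paths[[t]])))
        labs[[length(labs) + 1L]] <-
          as.data.frame(as.list(stats::setNames(c(id, row),
                                                c("id", paste0("level", seq_len(depth))))))
      }
    }
    list(sequences = seqs, labels = do.call(rbind, labs))
  })
}
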