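#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This order fixes the layout of
#' every composition-type feature block.
#'
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.constants_cache <- new.env(parent = emptyenv())

constants_file <- function(name) {
  path <- system.file("extdata", "constants", name, package = "featkit")
  if (!nzchar(path)) {
    stop("featkit constants-integrity error: missing embedded table '", name, "'",
         call. = FALSE)
  }
  path
}

#' Standardize a 20-value amino-acid property scale
#'
#' Centers by the mean over the 20 amino acids and divides by the population
#' (divide-by-20) standard deviation, so the standardized scale has mean 0 and
#' population standard deviation 1.
#'
#' @param values numeric vector of 20 property values, named by amino acid.
#' @return numeric vector of 20 standardized values.
#' @export
standardize_property <- function(values) {
  if (length(values) != 20L) {
    stop("featkit constants-integrity error: property scale must have 20 values",
         call. = FALSE)
  }
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    stop("featkit constants-integrity error: constant property scale", call. = FALSE)
  }
  (values - mu) / sigma
}

read_distance_matrix <- function(name, matrix_id) {
  raw <- utils::read.delim(constants_file(name), row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), AMINO_ACIDS) || !identical(colnames(m), AMINO_ACIDS)) {
    stop("featkit constants-integrity error: distance matrix '", matrix_id,
         "' must be indexed by the 20 amino acids", call. = FALSE)
  }
  if (any(m < 0) || any(diag(m) != 0) || !isSymmetric(unname(m))) {
    stop("featkit constants-integrity error: distance matrix '", matrix_id,
         "' must be symmetric, nonnegative, with zero diagonal", call. = FALSE)
  }
  structure(list(matrix_id = matrix_id, values = m), class = "aa_distance")
}

#' Load the embedded physicochemical constants
#'
#' Reads the frozen plain-text tables shipped with the package and returns the
#' full constant set: 18 amino-acid property tables (the first 8 numeric scales
#' drive the autocorrelation descriptors; scales 9-11 -- hydrophobicity,
#' hydrophilicity and side-chain mass -- drive the pseudo amino acid
#' composition; 12-14 are the numeric scales behind three of the grouping
#' schemes; 15-18 are categorical), 2 amino-acid distance matrices
#' (Grantham chemical distance and a documented synthetic reconstruction of
#' the Schneider-Wrede physicochemical distance), and 7 three-way grouping
#' schemes used by the composition/transition/distribution descriptors.
#'
#' Numeric scales carry `standardized_values`: mean 0, population (divide by
#' 20) standard deviation 1. All tables are validated on load; any
#' inconsistency aborts with a constants-integrity error. Results are cached
#' per session.
#'
#' @return list with elements `properties` (list of 18 `property_table`),
#'   `distances` (list of 2 `aa_distance`), `groupings` (list of 7
#'   `grouping_scheme`).
#' @examples
#' k <- load_constants()
#' length(k$properties)          # 18
#' k$distances$grantham$values["L", "I"]
#' @export
load_constants <- function() {
  if (!is.null(.constants_cache$constants)) {
    return(.constants_cache$constants)
  }
  ptab <- utils::read.delim(constants_file("aa_properties.tsv"),
                            check.names = FALSE)
  if (!all(AMINO_ACIDS %in% names(ptab)) || nrow(ptab) != 14L) {
    stop("featkit constants-integrity error: aa_properties.tsv malformed",
         call. = FALSE)
  }
  properties <- vector("list", 18L)
  for (r in seq_len(nrow(ptab))) {
    id <- ptab$property_id[r]
    raw <- as.numeric(ptab[r, AMINO_ACIDS])
    names(raw) <- AMINO_ACIDS
    if (anyNA(raw)) {
      stop("featkit constants-integrity error: property ", id, " has missing values",
           call. = FALSE)
    }
    properties[[id]] <- structure(
      list(property_id = id, name = ptab$name[r], raw_values = raw,
           standardized_values = standardize_property(raw),
           source_tag = ptab$source_tag[r]),
      class = "property_table")
  }

  gtab <- utils::read.delim(constants_file("aa_groupings.tsv"),
                            check.names = FALSE)
  groupings <- list()
  for (id in sort(unique(gtab$property_id))) {
    rows <- gtab[gtab$property_id == id, ]
    groups <- lapply(rows$members, function(s) strsplit(s, "")[[1]])
    names(groups) <- rows$label
    all_members <- unlist(groups)
    if (length(all_members) != 20L || !setequal(all_members, AMINO_ACIDS) ||
        anyDuplicated(all_members) || length(groups) != 3L) {
      stop("featkit constants-integrity error: grouping scheme ", id,
           " is not a 3-way partition of the amino-acid alphabet", call. = FALSE)
    }
    scheme <- structure(
      list(property_id = id, name = rows$name[1], groups = groups),
      class = "grouping_scheme")
    groupings[[length(groupings) + 1L]] <- scheme
    # categorical properties 15-18 exist only through their grouping
    if (id >= 15L && is.null(properties[[id]])) {
      lab <- character(20L)
      names(lab) <- AMINO_ACIDS
      for (g in names(groups)) lab[groups[[g]]] <- g
      properties[[id]] <- structure(
        list(property_id = id, name = rows$name[1], raw_values = lab,
             standardized_values = NULL,
             source_tag = "Dubchak et al. 3-group assignment"),
        class = "property_table")
    }
  }
  if (length(groupings) != 7L || any(vapply(properties, is.null, logical(1)))) {
    stop("featkit constants-integrity error: expected 18 property tables and 7 grouping schemes",
         call. = FALSE)
  }

  distances <- list(
    grantham = read_distance_matrix("dist_grantham.tsv", "grantham"),
    schneider_wrede = read_distance_matrix("dist_schneider_wrede_synthetic.tsv",
                                           "schneider_wrede"))
  if (max(distances$grantham$values) > 215 ||
      max(distances$schneider_wrede$values) > 1) {
    stop("featkit constants-integrity error: distance values out of documented range",
         call. = FALSE)
  }

  out <- list(properties = properties, distances = distances,
              groupings = groupings)
  .constants_cache$constants <- out
  out
}

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table ", x$property_id, ": ", x$name, ">\n", sep = "")
  cat("  source: ", x$source_tag, "\n", sep = "")
  print(x$raw_values)
  invisible(x)
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat("<grouping_scheme ", x$property_id, ": ", x$name, ">\n", sep = "")
  for (g in names(x$groups)) {
    cat("  ", g, ": ", paste(x$groups[[g]], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.aa_distance <- function(x, ...) {
  cat("<aa_distance ", x$matrix_id, "> 20x20, max ", max(x$values), "\n", sep = "")
  invisible(x)
}
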