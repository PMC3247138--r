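#' Read a FASTA file of protein sequences
#'
#' Parses multi-record, line-wrapped FASTA. Record ids are the first
#' whitespace-delimited token of the header; input order is preserved and
#' each record is validated through [protein_sequence] (so the sanitization
#' policy applies). Malformed input -- sequence data before the first header,
#' or an empty record -- raises a parse error naming the offending line.
#'
#' @param path readable FASTA file.
#' @param sanitize passed to [protein_sequence].
#' @return list of [protein_sequence] objects.
#' @export
read_fasta <- function(path, sanitize = c("strict", "drop")) {
  sanitize <- match.arg(sanitize)
  lines <- readLines(path)
  out <- list()
  id <- NULL
  chunks <- character(0L)
  header_line <- 0L
  flush <- function() {
    if (is.null(id)) return(invisible())
    if (!length(chunks) || !nzchar(paste(chunks, collapse = ""))) {
      stop("FASTA parse error at line ", header_line,
           ": record '", id, "' has an empty sequence", call. = FALSE)
    }
    out[[length(out) + 1L]] <<- protein_sequence(
      id, paste(chunks, collapse = ""), sanitize = sanitize)
    invisible()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      id <- strsplit(sub("^>", "", line), "[[:space:]]+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", i, ": empty header", call. = FALSE)
      }
      header_line <- i
      chunks <- character(0L)
    } else {
      if (is.null(id)) {
        stop("FASTA parse error at line ", i,
             ": sequence data before the first header", call. = FALSE)
      }
      chunks <- c(chunks, line)
    }
  }
  if (is.null(id)) stop("FASTA parse error at line 1: no records found", call. = FALSE)
  flush()
  out
}

#' Write protein sequences as FASTA
#'
#' @param seqs list of [protein_sequence] objects.
#' @param path output file.
#' @param width residues per wrapped line.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, s$length)),
               con)
  }
  invisible(path)
}

#' Read a hierarchical label table
#'
#' TSV with columns `id`, `level1` ... `level5` (trailing level columns may
#' be absent; empty cells mark branches that terminate early). Validates id
#' uniqueness and tree consistency: a label at level k must have a single
#' parent label at level k - 1.
#'
#' @param path TSV file.
#' @return data.frame of characters.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(df)) stop("label table must have an 'id' column", call. = FALSE)
  if (anyDuplicated(df$id)) {
    stop("label table has duplicate ids: ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 3L), collapse = ", "),
         call. = FALSE)
  }
  lv <- grep("^level[0-9]+$", names(df), value = TRUE)
  if (!length(lv)) stop("label table has no level columns", call. = FALSE)
  lv <- lv[order(as.integer(sub("level", "", lv)))]
  for (k in seq_along(lv)[-1]) {
    child <- df[[lv[k]]]
    parent <- df[[lv[k - 1L]]]
    use <- nzchar(child)
    if (any(use & !nzchar(parent))) {
      stop("label table inconsistency: ", lv[k],
           " assigned without a ", lv[k - 1L], " label", call. = FALSE)
    }
    tab <- unique(data.frame(child = child[use], parent = parent[use]))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup)) {
      stop("label table inconsistency: label(s) ",
           paste(unique(dup), collapse = ", "), " at ", lv[k],
           " have more than one parent", call. = FALSE)
    }
  }
  df
}

#' Write a hierarchical label table
#'
#' @param labels data.frame as produced by [generate_fixtures] or
#'   [read_labels].
#' @param path output TSV.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as TSV
#'
#' Rows are sequences (first column `id`), columns the 1497 block-qualified
#' feature names.
#'
#' @param X feature matrix from [extract_features_matrix].
#' @param path output TSV.
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Serialize / restore a trained hierarchy model
#'
#' Single-file versioned archive (RDS) holding the classifier tree with each
#' node's PCA model, projected training set and routing table.
#'
#' @param model a `hierarchy_model`.
#' @param path archive path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hierarchy_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION,
               package_version = as.character(utils::packageVersion("featkit")),
               model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns the `hierarchy_model`.
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model archive version", call. = FALSE)
  }
  obj$model
}
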