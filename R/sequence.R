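#' Construct a validated protein sequence
#'
#' Uppercases the input and validates it against the 20 standard one-letter
#' amino-acid codes. Sequences shorter than 31 residues are rejected: every
#' lag- and rank-indexed descriptor runs over lags 1..30, and 31 is the
#' smallest length for which all of those sums are nonempty.
#'
#' @param id sequence identifier.
#' @param residues character scalar of one-letter residue codes.
#' @param sanitize `"strict"` (default) rejects nonstandard codes
#'   (B, Z, X, U, O, J, gaps, ...) with an error; `"drop"` removes them.
#' @return object of class `protein_sequence` with fields `id`, `residues`,
#'   `length`.
#' @examples
#' protein_sequence("toy", strrep("ACDEFGHIKLMNPQRSTVWY", 2))
#' @export
protein_sequence <- function(id, residues, sanitize = c("strict", "drop")) {
  sanitize <- match.arg(sanitize)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[[:space:]]", "", residues))
  chars <- strsplit(res, "")[[1]]
  bad <- !(chars %in% AMINO_ACIDS)
  if (any(bad)) {
    if (sanitize == "strict") {
      stop("sequence '", id, "' contains nonstandard residue code(s): ",
           paste(unique(chars[bad]), collapse = ", "),
           " (use sanitize = \"drop\" to remove them)", call. = FALSE)
    }
    chars <- chars[!bad]
  }
  if (length(chars) < 31L) {
    stop("sequence '", id, "' is too short (", length(chars),
         " residues after sanitization; minimum is 31)", call. = FALSE)
  }
  structure(list(id = id, residues = paste(chars, collapse = ""),
                 length = length(chars)),
            class = "protein_sequence")
}

# integer encoding 1..20 in AMINO_ACIDS order
seq_index <- function(seq) {
  match(strsplit(seq$residues, "")[[1]], AMINO_ACIDS)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence ", x$id, "> L=", x$length, "\n", sep = "")
  if (x$length > 60) {
    cat(substr(x$residues, 1, 57), "...\n", sep = "")
  } else {
    cat(x$residues, "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.character.protein_sequence <- function(x, ...) x$residues
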