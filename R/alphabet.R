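#' The 20-letter standard amino-acid alphabet
#'
#' One-letter codes of the 20 proteinogenic amino acids accepted throughout the
#' package. Ambiguity and non-standard codes (B, J, O, U, X, Z) are rejected by
#' all sequence-validating functions.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Split a sequence into residues, erroring with the 1-based position of the
# first character outside the standard alphabet.
validate_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single non-NA character string", call. = FALSE)
  }
  if (nchar(sequence) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(chars)
}

#' Construct a validated protein record
#'
#' @param id Text identifier of the protein.
#' @param sequence One-letter amino-acid string; every character must belong to
#'   the 20-letter standard alphabet.
#' @return An object of class `protein_record` with fields `id` and `sequence`.
#' @export
#' @examples
#' protein_record("myosin_fragment", "MKAVLQWR")
protein_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("id must be a single non-empty string", call. = FALSE)
  }
  validate_sequence(sequence, sprintf("protein '%s'", id))
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  cat(strwrap(x$sequence, width = 60), sep = "\n")
  invisible(x)
}

# Coerce a character sequence (optionally named) or protein_record.
as_protein <- function(x, default_id = "protein") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x)) && nzchar(names(x))) names(x) else default_id
    return(protein_record(id, unname(x)))
  }
  stop("expected a protein_record or a single character sequence", call. = FALSE)
}
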