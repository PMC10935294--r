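#' The 5-z-scale amino-acid descriptor table
#'
#' Five principal-component scores per residue summarizing physicochemical
#' properties: z1 lipophilicity, z2 steric/spatial arrangement, z3 charge,
#' z4 and z5 electronic properties (electronegativity, heat of formation,
#' electrophilicity, hardness). Shipped as a versioned CSV data file and
#' loaded once per session.
#'
#' @return Data frame with one row per residue (rownames = one-letter code)
#'   and columns `residue`, `aa3`, `z1`..`z5`.
#' @export
#' @examples
#' zscale_table()["A", c("z1", "z2", "z3", "z4", "z5")]
zscale_table <- function() {
  if (is.null(.acescreen_cache$zscale)) {
    path <- system.file("extdata", "zscales.csv", package = "acescreen",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$residue),
              all(is.finite(as.matrix(tab[, c("z1", "z2", "z3", "z4", "z5")]))))
    rownames(tab) <- tab$residue
    .acescreen_cache$zscale <- tab
  }
  .acescreen_cache$zscale
}

#' Encode one residue as its 5-z-scale descriptor vector
#'
#' @param aa Single one-letter residue code.
#' @return Named numeric vector `(z1, z2, z3, z4, z5)`.
#' @export
#' @examples
#' encode_residue("A")
encode_residue <- function(aa) {
  if (!is.character(aa) || length(aa) != 1L || is.na(aa) || nchar(aa) != 1L) {
    stop("aa must be a single one-letter residue code", call. = FALSE)
  }
  tab <- zscale_table()
  if (!aa %in% rownames(tab)) {
    stop(sprintf("unknown residue '%s': not in the 20-letter standard alphabet", aa),
         call. = FALSE)
  }
  unlist(tab[aa, c("z1", "z2", "z3", "z4", "z5")])
}

#' Encode a peptide as a concatenated z-scale descriptor vector
#'
#' Position-major layout: residue 1's z1..z5, then residue 2's, and so on,
#' giving a vector of length 5n for an n-residue peptide.
#'
#' @param sequence Peptide sequence (length >= 1, standard alphabet).
#' @return Named numeric vector of length `5 * nchar(sequence)`.
#' @export
#' @examples
#' encode_peptide("YNL")[1]   # Tyr z1
encode_peptide <- function(sequence) {
  chars <- validate_sequence(sequence, "peptide")
  tab <- zscale_table()
  m <- as.matrix(tab[chars, c("z1", "z2", "z3", "z4", "z5"), drop = FALSE])
  v <- as.vector(t(m))
  names(v) <- paste0("p", rep(seq_along(chars), each = 5L), ".",
                     rep(c("z1", "z2", "z3", "z4", "z5"), length(chars)))
  v
}

#' Encode a set of equal-length peptides as a descriptor matrix
#'
#' @param sequences Character vector of peptides, all the same length.
#' @return Numeric matrix, one row per peptide, `5n` columns.
#' @export
encode_peptides <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("sequences must be a non-empty character vector", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all peptides must have the same length to share a descriptor space",
         call. = FALSE)
  }
  X <- t(vapply(sequences, encode_peptide, numeric(5L * lens[1L])))
  rownames(X) <- sequences
  X
}

#' Write the packaged z-scale table back to CSV
#'
#' Re-serializes [zscale_table()] in the packaged file's own column order and
#' formatting, for round-trip verification and for export.
#'
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_zscale_table <- function(path) {
  tab <- zscale_table()
  utils::write.csv(tab[, c("residue", "aa3", "z1", "z2", "z3", "z4", "z5")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
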