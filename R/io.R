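#' Load enzyme cleavage rules from a YAML file
#'
#' The file maps enzyme names to `p1`, `p1prime_exclusions` and `p2` residue
#' lists (see [cleavage_rule()] for semantics). Rules are data, not code, so
#' specificities can be edited to match any BIOPEP release.
#'
#' @param path YAML file; defaults to the packaged rule file with trypsin,
#'   papain and pepsin (pH 2) in their conventional formulations.
#' @return Named list of `cleavage_rule` objects.
#' @export
#' @examples
#' names(enzyme_rules())
read_enzyme_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("enzyme rule file must be a named mapping of enzymes", call. = FALSE)
  }
  # Bare Y / N in hand-edited files arrive as YAML 1.1 booleans; map them back.
  unbool <- function(x) {
    vapply(x, function(e) {
      if (isTRUE(e)) "Y" else if (isFALSE(e)) "N" else as.character(e)
    }, character(1))
  }
  rules <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    cleavage_rule(nm,
                  p1 = unbool(entry$p1 %||% character()),
                  p1prime_exclusions = unbool(entry$p1prime_exclusions %||% character()),
                  p2 = unbool(entry$p2 %||% character()))
  })
  stats::setNames(rules, names(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write enzyme cleavage rules to a YAML file
#'
#' Inverse of [read_enzyme_rules()]; a written file re-reads to rules equal to
#' the originals.
#'
#' @param rules Named list of `cleavage_rule` objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_enzyme_rules <- function(rules, path) {
  rules <- as_rule_list(rules)
  nms <- vapply(rules, function(r) r$enzyme_name, character(1))
  out <- stats::setNames(lapply(rules, function(r) {
    list(p1 = as.list(r$p1),
         p1prime_exclusions = as.list(r$p1prime_exclusions),
         p2 = as.list(r$p2))
  }), nms)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname read_enzyme_rules
#' @export
enzyme_rules <- function(path = system.file("extdata", "enzymes.yaml",
                                            package = "acescreen", mustWork = TRUE)) {
  read_enzyme_rules(path)
}

#' Read protein records from a FASTA file
#'
#' Accepts single- and multi-record amino-acid FASTA. Sequences are validated
#' against the 20-letter standard alphabet.
#'
#' @param path FASTA file path.
#' @return List of [protein_record()] objects, named by record id.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  recs <- lapply(names(seqs), function(nm) {
    protein_record(nm, toupper(as.character(seqs[[nm]])))
  })
  stats::setNames(recs, names(seqs))
}

#' Write released peptides to a TSV file
#'
#' Writes the standard fragment table (`parent_id`, `start`, `end`, `length`,
#' `sequence`) as tab-separated text.
#'
#' @param peptides Data frame as produced by [digest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_tsv <- function(peptides, path) {
  cols <- c("parent_id", "start", "end", "length", "sequence")
  missing <- setdiff(cols, names(peptides))
  if (length(missing) > 0L) {
    stop("peptide table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(peptides[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a peptide list from TSV/CSV
#'
#' Reads an observed-peptide list (for example a trimmed MS search-engine
#' export) containing at least a `sequence` column; the delimiter is inferred
#' from the extension (`.csv` vs tab-separated otherwise).
#'
#' @param path Input path.
#' @return Data frame with at least a `sequence` column.
#' @export
read_peptide_list <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df)) {
    stop("peptide list must contain a 'sequence' column", call. = FALSE)
  }
  df
}
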