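# Candidate funnel: intersect in-silico released peptides with an observed
# (MS-identified) list, keep lengths with trained models, predict IC50, and
# select candidates under a threshold.

as_peptide_table <- function(peptides) {
  if (is.character(peptides)) {
    return(data.frame(parent_id = NA_character_, start = NA_integer_,
                      end = NA_integer_, length = nchar(peptides),
                      sequence = peptides, stringsAsFactors = FALSE))
  }
  if (is.data.frame(peptides) && "sequence" %in% names(peptides)) {
    if (!"length" %in% names(peptides)) peptides$length <- nchar(peptides$sequence)
    return(peptides)
  }
  stop("peptides must be a character vector or a data frame with a 'sequence' column",
       call. = FALSE)
}

#' Match in-silico released peptides against an observed list
#'
#' Exact sequence-equality intersection of digestion fragments with an observed
#' (for example MS-identified) peptide list. Isoleucine and leucine are
#' distinct by default — their z-scale descriptors differ, so predictions do —
#' but `il_equivalent = TRUE` folds I to L on both sides, since mass
#' spectrometry cannot distinguish the two. Duplicate fragments are collapsed
#' to one row per sequence; the first occurrence's parent coordinates are
#' retained as provenance plus an `n_copies` count.
#'
#' @param released Fragment data frame from [digest()] (or character vector).
#' @param observed Character vector of observed sequences, or a data frame
#'   with a `sequence` column.
#' @param il_equivalent Treat I and L as interchangeable when matching.
#' @return Subset of `released`, one row per matched sequence, with `n_copies`.
#' @export
match_peptides <- function(released, observed, il_equivalent = FALSE) {
  rel <- as_peptide_table(released)
  if (is.data.frame(observed)) observed <- observed$sequence
  if (length(observed) == 0L || nrow(rel) == 0L) {
    stop("released and observed peptide lists must both be non-empty", call. = FALSE)
  }
  fold <- if (il_equivalent) function(s) gsub("I", "L", s, fixed = TRUE) else identity
  hit <- fold(rel$sequence) %in% fold(observed)
  matched <- rel[hit, , drop = FALSE]
  if (nrow(matched) == 0L) {
    out <- matched
    out$n_copies <- integer(0)
    return(out)
  }
  copies <- table(matched$sequence)
  first <- !duplicated(matched$sequence)
  out <- matched[first, , drop = FALSE]
  out$n_copies <- as.integer(copies[out$sequence])
  rownames(out) <- NULL
  out
}

#' Keep peptides whose length has a trained QSAR model
#'
#' @param peptides Fragment data frame or character vector.
#' @param allowed Residue counts with trained models (default `c(3, 6, 7, 8)`).
#' @return Subset, input order preserved.
#' @export
filter_by_length <- function(peptides, allowed = c(3L, 6L, 7L, 8L)) {
  tab <- as_peptide_table(peptides)
  out <- tab[tab$length %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Monoisotopic residue masses (Da); peptide mass adds one water.
MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MONOISOTOPIC <- 18.010565

#' Monoisotopic mass of a peptide
#'
#' Sum of standard monoisotopic residue masses plus one water.
#'
#' @param sequence Peptide sequence(s).
#' @return Numeric mass in Da, vectorized over `sequence`.
#' @export
#' @examples
#' peptide_mass("YNL")
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- validate_sequence(s, "peptide")
    sum(MONOISOTOPIC_RESIDUE_MASS[chars]) + WATER_MONOISOTOPIC
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter peptides by monoisotopic mass
#'
#' In-silico proxy for ultrafiltration: keeps peptides at or below a mass
#' cutoff (default 3 kDa, the fraction typically carrying the strongest
#' ACE-inhibitory activity). A sequence-mass gate only approximates a
#' membrane separation, which is a wet-lab process.
#'
#' @param peptides Fragment data frame or character vector.
#' @param max_mass_da Mass cutoff in Da (default 3000).
#' @return Subset, input order preserved.
#' @export
filter_by_mass <- function(peptides, max_mass_da = 3000) {
  tab <- as_peptide_table(peptides)
  keep <- peptide_mass(tab$sequence) <= max_mass_da
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate peptides under an IC50 threshold
#'
#' Sorts predictions by ascending predicted IC50, flags those strictly below
#' `threshold_uM`, and tabulates counts under each reporting threshold and per
#' length class.
#'
#' @param predictions Data frame with columns `peptide` and `predicted_ic50_uM`
#'   (as from [predict.pls_model()] or [table1_fixture()]).
#' @param threshold_uM Selection threshold in micromolar (default 10).
#' @param report_thresholds Thresholds tabulated in the report (default
#'   `c(10, 100)`).
#' @return An object of class `screening_report`: `candidates` (sorted, with
#'   `selected` flag), `threshold_uM`, `counts` (named by threshold) and
#'   `counts_by_length`.
#' @export
#' @examples
#' rep <- select_candidates(table1_fixture(), threshold_uM = 10)
#' rep$counts
select_candidates <- function(predictions, threshold_uM = 10,
                              report_thresholds = c(10, 100)) {
  if (!is.data.frame(predictions) ||
      !all(c("peptide", "predicted_ic50_uM") %in% names(predictions))) {
    stop("predictions must have columns 'peptide' and 'predicted_ic50_uM'",
         call. = FALSE)
  }
  if (nrow(predictions) == 0L) stop("predictions must be non-empty", call. = FALSE)
  if (!is.numeric(threshold_uM) || length(threshold_uM) != 1L || threshold_uM < 0) {
    stop("threshold_uM must be a single non-negative number", call. = FALSE)
  }
  cand <- predictions[order(predictions$predicted_ic50_uM, predictions$peptide), ,
                      drop = FALSE]
  rownames(cand) <- NULL
  cand$length <- nchar(cand$peptide)
  cand$selected <- cand$predicted_ic50_uM < threshold_uM
  counts <- vapply(report_thresholds,
                   function(th) sum(cand$predicted_ic50_uM < th), integer(1))
  names(counts) <- paste0("<", report_thresholds, "uM")
  structure(list(candidates = cand, threshold_uM = threshold_uM,
                 counts = counts,
                 counts_by_length = table(cand$length)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d candidates, %d selected (IC50 < %g uM)\n",
              nrow(x$candidates), sum(x$candidates$selected), x$threshold_uM))
  for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  print(utils::head(x$candidates[, c("peptide", "length", "predicted_ic50_uM",
                                     "selected")], 10L))
  invisible(x)
}

#' Write a screening report as TSV plus JSON summary
#'
#' The TSV holds the sorted candidate table (stable column order: peptide,
#' length, predicted_ic50_uM, selected, then any provenance columns); the JSON
#' holds thresholds and counts.
#'
#' @param report A `screening_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of the written paths.
#' @export
write_screening_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!inherits(report, "screening_report")) {
    stop("report must be a screening_report", call. = FALSE)
  }
  if (!is.null(tsv_path)) {
    lead <- c("peptide", "length", "predicted_ic50_uM", "selected")
    rest <- setdiff(names(report$candidates), lead)
    utils::write.table(report$candidates[, c(lead, rest)], tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(threshold_uM = report$threshold_uM,
                              counts = as.list(report$counts),
                              counts_by_length = as.list(report$counts_by_length),
                              n_candidates = nrow(report$candidates),
                              n_selected = sum(report$candidates$selected)),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Packaged fixture of 21 screened peptides with QSAR-predicted IC50
#'
#' The 21 peptides released by combined in-silico hydrolysis of the large
#' yellow croaker myosin heavy chain that were also observed in the <3 kDa
#' hydrolysate, with their model-predicted IC50 values (micromolar): 3
#' tripeptides, 5 hexapeptides, 5 heptapeptides and 8 octapeptides by direct
#' length count. One octapeptide (LYDQHLGK) also circulates under a 7-residue
#' spelling (LYDHLGK) in the assay tables; the fixture keeps the 8-residue
#' form verbatim and carries the alternate in its `note` column.
#'
#' @return Data frame with columns `peptide`, `predicted_ic50_uM`, `length`,
#'   `note`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_predicted_ic50.csv",
                      package = "acescreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged fixture of assayed IC50 before/after simulated digestion
#'
#' Mean and SD (n = 3) of measured IC50 for the six synthesized candidate
#' peptides before and after simulated gastrointestinal digestion.
#'
#' @return Data frame with columns `peptide`, `ic50_pre_uM`, `sd_pre`,
#'   `ic50_post_uM`, `sd_post`, `n_replicates`.
#' @export
digestion_ic50_fixture <- function() {
  path <- system.file("extdata", "table2_digestion_ic50.csv",
                      package = "acescreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full screening funnel
#'
#' digest -> match against observed list -> keep modelled lengths -> predict
#' IC50 with the per-length models -> select under the threshold.
#'
#' @param protein A [protein_record()] or sequence.
#' @param rules Cleavage rules for the hydrolysis.
#' @param observed Observed peptide list (character or data frame).
#' @param models Named list of `pls_model`s, names = length classes
#'   (e.g. `list("6" = model6)`).
#' @param threshold_uM Selection threshold (default 10).
#' @param il_equivalent Passed to [match_peptides()].
#' @param max_mass_da Optional monoisotopic mass gate before matching
#'   (`NULL` disables).
#' @return A `screening_report`; candidates carry digestion provenance columns.
#' @export
screen_peptides <- function(protein, rules, observed, models,
                            threshold_uM = 10, il_equivalent = FALSE,
                            max_mass_da = NULL) {
  released <- digest(protein, rules)
  if (!is.null(max_mass_da)) released <- filter_by_mass(released, max_mass_da)
  matched <- match_peptides(released, observed, il_equivalent = il_equivalent)
  lengths_avail <- as.integer(names(models))
  if (anyNA(lengths_avail)) stop("models must be named by length class", call. = FALSE)
  pool <- filter_by_length(matched, allowed = lengths_avail)
  if (nrow(pool) == 0L) stop("no matched peptide has a trained model", call. = FALSE)
  preds <- do.call(rbind, lapply(split(pool, pool$length), function(chunk) {
    model <- models[[as.character(chunk$length[1L])]]
    cbind(predict(model, chunk$sequence),
          chunk[, c("parent_id", "start", "end"), drop = FALSE])
  }))
  rownames(preds) <- NULL
  select_candidates(preds, threshold_uM = threshold_uM)
}
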