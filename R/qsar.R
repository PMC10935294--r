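#' Assemble a QSAR training dataset
#'
#' Validates a table of (peptide, IC50) training pairs for one length class.
#' All peptides must share the same residue count; IC50 values must be
#' positive and below the 15 mM (15,000 uM) admission bound — rows at or above
#' the bound are dropped with a message, mirroring the admission filter applied
#' when training compilations are assembled.
#'
#' @param peptide Character vector of equal-length peptide sequences.
#' @param ic50_uM Positive IC50 values in micromolar.
#' @return A data frame of class `qsar_dataset` with attribute `length_class`
#'   (the shared residue count) and `n_rejected` (rows dropped by the
#'   admission filter).
#' @export
qsar_dataset <- function(peptide, ic50_uM) {
  if (length(peptide) != length(ic50_uM)) {
    stop("peptide and ic50_uM must have the same length", call. = FALSE)
  }
  invisible(lapply(peptide, validate_sequence, what = "training peptide"))
  lens <- nchar(peptide)
  if (length(unique(lens)) != 1L) {
    stop("all training peptides must share one length class", call. = FALSE)
  }
  ic50_uM <- as.numeric(ic50_uM)
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("all IC50 values must be finite and positive", call. = FALSE)
  }
  admit <- ic50_uM < 15000
  n_rejected <- sum(!admit)
  if (n_rejected > 0L) {
    message(sprintf("admission filter: dropped %d record(s) with IC50 >= 15 mM",
                    n_rejected))
  }
  out <- data.frame(peptide = peptide[admit], ic50_uM = ic50_uM[admit],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no records pass the admission filter", call. = FALSE)
  attr(out, "length_class") <- lens[1L]
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("qsar_dataset", "data.frame")
  out
}

#' Fit a length-stratified QSAR model from a training dataset
#'
#' Encodes the peptides with [encode_peptide()], log10-transforms IC50, and
#' fits a two-component PLS regression ([fit_pls()]). Optional t,u-score
#' outlier exclusion ([exclude_outliers()]) prunes and refits.
#'
#' @param dataset A [qsar_dataset()].
#' @param n_components Latent components (default 2).
#' @param exclude Run t,u-score outlier exclusion after the initial fit.
#' @param threshold_sd,max_rounds Passed to [exclude_outliers()].
#' @return A `pls_model` whose `length_class` matches the dataset.
#' @export
#' @examples
#' sim <- gen_qsar_dataset(seed = 1, n = 40, length = 3, sigma = 0.1)
#' m <- fit_qsar(sim$data)
#' m$r2
fit_qsar <- function(dataset, n_components = 2L, exclude = FALSE,
                     threshold_sd = 2.5, max_rounds = 5L) {
  if (!inherits(dataset, "qsar_dataset")) {
    stop("dataset must be a qsar_dataset", call. = FALSE)
  }
  X <- encode_peptides(dataset$peptide)
  y <- log10(dataset$ic50_uM)
  model <- fit_pls(X, y, n_components = n_components)
  if (exclude) {
    model <- exclude_outliers(model, X, y, threshold_sd = threshold_sd,
                              max_rounds = max_rounds)$model
  }
  model$length_class <- attr(dataset, "length_class")
  model
}

#' Read a QSAR training table from CSV
#'
#' Expects columns `peptide` and `ic50_uM`.
#'
#' @param path CSV path.
#' @return A [qsar_dataset()].
#' @export
read_qsar_training <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "ic50_uM") %in% names(df))) {
    stop("training CSV must have columns 'peptide' and 'ic50_uM'", call. = FALSE)
  }
  qsar_dataset(df$peptide, df$ic50_uM)
}
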