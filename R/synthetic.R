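# Synthetic-data generators with known ground truth. Every generator is
# deterministic under its seed (withr::with_seed, so the caller's RNG state is
# never touched) and returns the truth alongside the data.

random_peptide <- function(length, exclude = character()) {
  paste(sample(setdiff(aa_alphabet(), exclude), length, replace = TRUE),
        collapse = "")
}

# Internal + boundary cleavability check for a planted peptide: simulate the
# peptide in context (separator before, non-proline residue after) and demand
# cuts exactly at its two boundary bonds.
check_plantable <- function(peptide, separator, rules) {
  chars <- validate_sequence(peptide, "planted peptide")
  ctx <- paste0(separator, peptide, "A")
  sites <- cleavage_sites(ctx, rules)
  len <- length(chars)
  internal <- intersect(sites, seq(2L, len, by = 1L))  # ctx bonds 2..len are internal
  if (length(internal) > 0L) {
    stop(sprintf("planted peptide '%s' has an internal cleavage site after residue %d",
                 peptide, internal[1L] - 1L), call. = FALSE)
  }
  if (!(1L %in% sites)) {
    stop(sprintf("planted peptide '%s' cannot be released: no cut after separator '%s' (does it start with a blocked residue?)",
                 peptide, separator), call. = FALSE)
  }
  if (!((len + 1L) %in% sites)) {
    stop(sprintf("planted peptide '%s' cannot be released: the rules never cut after its C-terminal residue",
                 peptide), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic protein with planted cleavage products
#'
#' Builds a random protein whose digestion under the given rules releases
#' every planted peptide, recording their true coordinates. Planted peptides
#' are separated from random background segments by a separator residue that
#' the rules cut after (lysine for the default trypsin-containing rule set).
#' A planted peptide with an internal cleavage site, or one the rules cannot
#' release at either boundary, raises an error naming the offending bond.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param length Approximate total protein length (background is scaled to
#'   reach it; a floor of 3 residues per background segment applies).
#' @param planted Character vector of peptides the digest must release.
#' @param separator_residue Residue inserted before each planted peptide
#'   (must be cut after by the rules; default `"K"`).
#' @param rules Cleavage rules the construction targets. The default is
#'   trypsin alone, under which any peptide free of internal K/R (except
#'   before proline) and ending in K or R is plantable — the classical
#'   tryptic-peptide layout. Broader rule sets (for example adding the
#'   packaged P2-hydrophobic papain rule) shrink the plantable space
#'   considerably, since most sequences then carry internal sites.
#' @param id Protein identifier.
#' @return List with `protein` (a [protein_record()]) and `truth` (data frame
#'   `peptide`, `start`, `end`).
#' @export
#' @examples
#' gp <- gen_protein(seed = 1, planted = c("NWPWMK", "FYEPFM"))
#' gp$truth
gen_protein <- function(seed, length = 240L, planted = character(),
                        separator_residue = "K",
                        rules = enzyme_rules()["trypsin"],
                        id = sprintf("synthetic_protein_%d", seed)) {
  rules <- as_rule_list(rules)
  stopifnot(is.character(separator_residue), nchar(separator_residue) == 1L,
            separator_residue %in% aa_alphabet())
  withr::with_seed(as.integer(seed), {
    for (p in planted) check_plantable(p, separator_residue, rules)
    n_seg <- length(planted) + 1L
    budget <- max(length - sum(nchar(planted)) - length(planted), 3L * n_seg)
    seg_len <- pmax(3L, diff(round(seq(0, budget, length.out = n_seg + 1L))))
    # background segments never start with proline, so a cut before them sticks
    bg <- vapply(seg_len, function(l) {
      paste0(random_peptide(1L, exclude = "P"), random_peptide(l - 1L))
    }, character(1))

    parts <- character(0)
    truth <- data.frame(peptide = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    pos <- 0L
    for (k in seq_along(planted)) {
      parts <- c(parts, bg[k], separator_residue, planted[k])
      pos <- pos + nchar(bg[k]) + 1L
      truth <- rbind(truth, data.frame(peptide = planted[k],
                                       start = pos + 1L,
                                       end = pos + nchar(planted[k]),
                                       stringsAsFactors = FALSE))
      pos <- pos + nchar(planted[k])
    }
    parts <- c(parts, bg[n_seg])
    protein <- protein_record(id, paste(parts, collapse = ""))

    frags <- digest(protein, rules)
    for (k in seq_len(nrow(truth))) {
      hit <- frags$start == truth$start[k] & frags$end == truth$end[k] &
        frags$sequence == truth$peptide[k]
      if (!any(hit)) {
        stop(sprintf("construction failed: planted peptide '%s' not released at [%d, %d]",
                     truth$peptide[k], truth$start[k], truth$end[k]),
             call. = FALSE)
      }
    }
    list(protein = protein, truth = truth)
  })
}

#' Generate a synthetic QSAR training set with known coefficients
#'
#' Draws peptides uniformly over the 20-letter alphabet and simulates
#' `log10(IC50) = intercept + x . beta + N(0, sigma^2)` on their z-scale
#' descriptors. Records whose IC50 would breach the 15 mM admission bound are
#' resampled so the returned set is fully admitted. Defaults place IC50
#' roughly in the 0.5-500 uM range typical of ACE-inhibitory peptide
#' compilations.
#'
#' @param seed Integer seed.
#' @param n Number of training peptides (>= 10).
#' @param length Peptide length (residues).
#' @param beta True coefficient vector of length `5 * length`; `NULL` draws
#'   one from N(0, 0.1) under the same seed.
#' @param intercept True intercept on the log10 scale (default 1.5, i.e.
#'   ~32 uM median IC50).
#' @param sigma Gaussian noise SD on log10 IC50 (>= 0).
#' @return List with `data` (a [qsar_dataset()]), `X` (descriptor matrix),
#'   `log10_ic50`, and the truth `beta`, `intercept`, `sigma`.
#' @export
gen_qsar_dataset <- function(seed, n = 100L, length = 6L, beta = NULL,
                             intercept = 1.5, sigma = 0.2) {
  if (n < 10L) stop("n must be at least 10", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    if (is.null(beta)) beta <- stats::rnorm(5L * length, 0, 0.1)
    if (length(beta) != 5L * length) {
      stop("beta must have length 5 * peptide length", call. = FALSE)
    }
    draw <- function(k) {
      peps <- vapply(seq_len(k), function(i) random_peptide(length), character(1))
      X <- encode_peptides(peps)
      y <- drop(intercept + X %*% beta) + stats::rnorm(k, 0, sigma)
      list(peps = peps, X = X, y = y)
    }
    d <- draw(n)
    for (iter in seq_len(100L)) {
      over <- which(10^d$y >= 15000)
      if (length(over) == 0L) break
      redo <- draw(length(over))
      d$peps[over] <- redo$peps
      d$X[over, ] <- redo$X
      d$y[over] <- redo$y
    }
    rownames(d$X) <- d$peps
    d$y <- unname(d$y)
    list(data = qsar_dataset(d$peps, 10^d$y),
         X = d$X, log10_ic50 = d$y,
         beta = beta, intercept = intercept, sigma = sigma)
  })
}

#' Generate Michaelis-Menten inhibition series with known mechanism
#'
#' Simulates velocities from the rate law of the chosen mechanism at each
#' (inhibitor, substrate) combination, with optional multiplicative Gaussian
#' noise:
#' \itemize{
#'   \item competitive: `v = Vmax S / (Km (1 + I/Ki) + S)`
#'   \item non-competitive: `v = Vmax S / ((Km + S)(1 + I/Ki))`
#'   \item uncompetitive: `v = Vmax S / (Km + S (1 + I/Ki))`
#'   \item mixed: `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))`
#' }
#' Defaults use the standard assay grids: substrate 0.5/1/2/4/5 mM and
#' inhibitor 0/0.2/0.5 (mg/mL; the module is unit-agnostic).
#'
#' @param seed Integer seed (only used when `sigma > 0`).
#' @param mode One of `"competitive"`, `"noncompetitive"`, `"uncompetitive"`,
#'   `"mixed"`.
#' @param vmax,km True control parameters (defaults 2 and 1 mM).
#' @param ki Inhibition constant in inhibitor units (default 0.2).
#' @param alpha Mixed-mode asymmetry factor (default 2; `alpha = 1` reduces
#'   mixed to non-competitive).
#' @param inhibitor_concs,substrate_concs Assay grids.
#' @param sigma Multiplicative noise SD (default 0).
#' @return List with `data` (data frame `inhibitor_conc`, `substrate_mM`,
#'   `velocity`) and `truth` (mode, parameters, and per-level apparent
#'   Km/Vmax).
#' @export
gen_kinetics <- function(seed, mode = c("competitive", "noncompetitive",
                                        "uncompetitive", "mixed"),
                         vmax = 2, km = 1, ki = 0.2, alpha = 2,
                         inhibitor_concs = c(0, 0.2, 0.5),
                         substrate_concs = c(0.5, 1, 2, 4, 5),
                         sigma = 0) {
  mode <- match.arg(mode)
  stopifnot(vmax > 0, km > 0, ki > 0, alpha > 0, sigma >= 0,
            all(substrate_concs > 0), all(inhibitor_concs >= 0))
  rate <- function(S, I) {
    switch(mode,
           competitive = vmax * S / (km * (1 + I / ki) + S),
           noncompetitive = vmax * S / ((km + S) * (1 + I / ki)),
           uncompetitive = vmax * S / (km + S * (1 + I / ki)),
           mixed = vmax * S / (km * (1 + I / ki) + S * (1 + I / (alpha * ki))))
  }
  apparent <- function(I) {
    switch(mode,
           competitive = c(km = km * (1 + I / ki), vmax = vmax),
           noncompetitive = c(km = km, vmax = vmax / (1 + I / ki)),
           uncompetitive = c(km = km / (1 + I / ki), vmax = vmax / (1 + I / ki)),
           mixed = c(km = km * (1 + I / ki) / (1 + I / (alpha * ki)),
                     vmax = vmax / (1 + I / (alpha * ki))))
  }
  grid <- expand.grid(substrate_mM = substrate_concs,
                      inhibitor_conc = inhibitor_concs)
  v <- rate(grid$substrate_mM, grid$inhibitor_conc)
  if (sigma > 0) {
    v <- withr::with_seed(as.integer(seed),
                          v * (1 + stats::rnorm(length(v), 0, sigma)))
  }
  app <- do.call(rbind, lapply(inhibitor_concs, function(I) {
    a <- apparent(I)
    data.frame(inhibitor_conc = I, km_apparent = unname(a["km"]),
               vmax_apparent = unname(a["vmax"]))
  }))
  list(data = data.frame(inhibitor_conc = grid$inhibitor_conc,
                         substrate_mM = grid$substrate_mM, velocity = v),
       truth = list(mode = mode, vmax = vmax, km = km, ki = ki, alpha = alpha,
                    sigma = sigma, apparent = app))
}

#' Generate dose-response points from a log-logistic curve
#'
#' `inhibition = 100 / (1 + (ic50 / c)^hill)` plus additive Gaussian noise in
#' percentage points, clamped to the tolerated -10..110% band. The default
#' concentration grid spans 0.1x to 10x the IC50, so the 50% level is always
#' bracketed.
#'
#' @param seed Integer seed (used when `sigma > 0`).
#' @param ic50 True IC50 (> 0; default 5).
#' @param hill Hill slope (default 1).
#' @param concentrations Concentration grid; `NULL` uses
#'   `ic50 * c(0.1, 0.3, 0.6, 1, 2, 5, 10)`.
#' @param sigma Noise SD in percentage points (default 0).
#' @return List with `data` (data frame `concentration`, `inhibition_pct`)
#'   and `truth` (`ic50`, `hill`, `sigma`).
#' @export
gen_dose_response <- function(seed, ic50 = 5, hill = 1, concentrations = NULL,
                              sigma = 0) {
  if (ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (is.null(concentrations)) {
    concentrations <- ic50 * c(0.1, 0.3, 0.6, 1, 2, 5, 10)
  }
  inh <- 100 / (1 + (ic50 / concentrations)^hill)
  if (sigma > 0) {
    inh <- withr::with_seed(as.integer(seed),
                            inh + stats::rnorm(length(inh), 0, sigma))
    inh <- pmin(pmax(inh, -9.99), 109.99)
  }
  list(data = data.frame(concentration = concentrations, inhibition_pct = inh),
       truth = list(ic50 = ic50, hill = hill, sigma = sigma))
}

#' Write a synthetic scenario to disk in the pipeline's file dialects
#'
#' Convenience front-end for the generators: writes the scenario's CSV/TSV
#' files plus a `truth.json`, in the same formats the pipeline reads.
#'
#' @param scenario One of `"protein"`, `"qsar"`, `"kinetics"`,
#'   `"dose_response"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param ... Passed to the underlying generator.
#' @return Invisible character vector of written paths.
#' @export
simulate_scenario <- function(scenario = c("protein", "qsar", "kinetics",
                                           "dose_response"),
                              seed, dir, ...) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  truth <- NULL
  if (scenario == "protein") {
    g <- gen_protein(seed, ...)
    fa <- file.path(dir, "protein.fasta")
    writeLines(c(paste0(">", g$protein$id), g$protein$sequence), fa)
    tsv <- file.path(dir, "planted_peptides.tsv")
    utils::write.table(g$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(fa, tsv)
    truth <- list(planted = g$truth)
  } else if (scenario == "qsar") {
    g <- gen_qsar_dataset(seed, ...)
    csv <- file.path(dir, "qsar_training.csv")
    utils::write.csv(g$data, csv, row.names = FALSE)
    paths <- csv
    truth <- list(beta = g$beta, intercept = g$intercept, sigma = g$sigma)
  } else if (scenario == "kinetics") {
    g <- gen_kinetics(seed, ...)
    csv <- file.path(dir, "kinetics.csv")
    utils::write.csv(g$data, csv, row.names = FALSE)
    paths <- csv
    truth <- g$truth
  } else {
    g <- gen_dose_response(seed, ...)
    csv <- file.path(dir, "dose_response.csv")
    utils::write.csv(g$data, csv, row.names = FALSE)
    paths <- csv
    truth <- g$truth
  }
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, tj))
}
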