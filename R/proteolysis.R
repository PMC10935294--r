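#' Define a protease cleavage rule
#'
#' A declarative Keil-style description of where an enzyme cuts. The peptide
#' bond after residue i (the "scissile bond" between positions i and i+1) is
#' cut when all of the following hold:
#' \itemize{
#'   \item P1: residue i belongs to `p1` (an empty `p1` places no constraint);
#'   \item P1': residue i+1 is \emph{not} in `p1prime_exclusions`;
#'   \item P2: if `p2` is non-empty, residue i-1 belongs to `p2` (so a bond
#'     after position 1 can never satisfy a P2 constraint).
#' }
#'
#' @param enzyme_name Text name of the protease.
#' @param p1 Residues allowed immediately N-terminal to the scissile bond.
#' @param p1prime_exclusions Residues that block cleavage when immediately
#'   C-terminal to the bond (classically proline).
#' @param p2 Optional residues required two positions N-terminal of the bond;
#'   empty means no constraint. At least one of `p1` / `p2` must be non-empty.
#' @return An object of class `cleavage_rule`.
#' @seealso [enzyme_rules()] for the packaged trypsin / papain / pepsin rules.
#' @export
#' @examples
#' trypsin <- cleavage_rule("trypsin", p1 = c("K", "R"),
#'                          p1prime_exclusions = "P")
cleavage_rule <- function(enzyme_name, p1 = character(),
                          p1prime_exclusions = character(),
                          p2 = character()) {
  if (!is.character(enzyme_name) || length(enzyme_name) != 1L || !nzchar(enzyme_name)) {
    stop("enzyme_name must be a single non-empty string", call. = FALSE)
  }
  p1 <- as.character(p1); p1p <- as.character(p1prime_exclusions); p2 <- as.character(p2)
  for (set in list(p1 = p1, p1prime_exclusions = p1p, p2 = p2)) {
    bad <- setdiff(set, aa_alphabet())
    if (length(bad) > 0L) {
      stop(sprintf("residue class contains non-standard residues: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(p1) == 0L && length(p2) == 0L) {
    stop("at least one of p1 / p2 must be non-empty", call. = FALSE)
  }
  structure(list(enzyme_name = enzyme_name, p1 = sort(unique(p1)),
                 p1prime_exclusions = sort(unique(p1p)), p2 = sort(unique(p2))),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = "") else "-"
  cat(sprintf("<cleavage_rule> %s: P2 in [%s], P1 in [%s], P1' not in [%s]\n",
              x$enzyme_name, fmt(x$p2),
              if (length(x$p1)) paste(x$p1, collapse = "") else "any",
              fmt(x$p1prime_exclusions)))
  invisible(x)
}

# Bond indices cut by a single rule, given the residue vector.
rule_cut_sites <- function(chars, rule) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  ok <- rep(TRUE, n - 1L)
  if (length(rule$p1) > 0L) ok <- ok & (chars[i] %in% rule$p1)
  if (length(rule$p1prime_exclusions) > 0L) {
    ok <- ok & !(chars[i + 1L] %in% rule$p1prime_exclusions)
  }
  if (length(rule$p2) > 0L) {
    p2ok <- c(FALSE, chars[seq_len(n - 2L)] %in% rule$p2)  # bond 1 has no P2
    ok <- ok & p2ok
  }
  which(ok)
}

as_rule_list <- function(rules) {
  if (inherits(rules, "cleavage_rule")) return(list(rules))
  if (is.list(rules) && length(rules) > 0L &&
      all(vapply(rules, inherits, logical(1), "cleavage_rule"))) {
    return(rules)
  }
  stop("rules must be a cleavage_rule or a non-empty list of cleavage_rule objects",
       call. = FALSE)
}

#' Locate cleavage sites on a protein
#'
#' Computes the union, over all supplied rules, of the bond indices at which at
#' least one enzyme cuts — the simultaneous multi-enzyme behaviour of combined
#' hydrolysis. Bond index i denotes the bond between residues i and i+1
#' (1-based).
#'
#' @param protein A [protein_record()] or a single character sequence.
#' @param rules A `cleavage_rule` or list of them.
#' @return Sorted integer vector of cut bond indices.
#' @export
#' @examples
#' tr <- enzyme_rules()[["trypsin"]]
#' cleavage_sites("AKGR", tr)   # cut after K only: R is C-terminal
cleavage_sites <- function(protein, rules) {
  pr <- as_protein(protein)
  rules <- as_rule_list(rules)
  chars <- strsplit(pr$sequence, "", fixed = TRUE)[[1L]]
  sites <- lapply(rules, function(r) rule_cut_sites(chars, r))
  sort(unique(unlist(sites)))
}

fragments_from_sites <- function(pr, sites) {
  n <- nchar(pr$sequence)
  bounds <- c(0L, as.integer(sites), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  data.frame(parent_id = pr$id, start = starts, end = ends,
             length = ends - starts + 1L,
             sequence = substring(pr$sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Digest a protein into peptide fragments
#'
#' Releases the maximal substrings between consecutive cut bonds, in N-to-C
#' order, with 1-based inclusive parent coordinates. Concatenating the
#' fragment sequences in order reproduces the protein exactly.
#'
#' By default all enzymes act simultaneously (union of cut sites, matching
#' BIOPEP-style combined "Enzyme action"). With `sequential = TRUE` the rules
#' are applied one after another, each enzyme re-digesting the fragments left
#' by the previous one; for context-free rules both modes coincide, but a P2
#' constraint can straddle a fresh N-terminus and then the modes differ.
#'
#' @inheritParams cleavage_sites
#' @param sequential Apply rules one enzyme at a time instead of jointly.
#' @return A data frame of fragments with columns `parent_id`, `start`, `end`,
#'   `length`, `sequence`.
#' @export
#' @examples
#' tr <- enzyme_rules()[["trypsin"]]
#' digest("AKGR", tr)
digest <- function(protein, rules, sequential = FALSE) {
  pr <- as_protein(protein)
  rules <- as_rule_list(rules)
  if (!sequential) {
    return(fragments_from_sites(pr, cleavage_sites(pr, rules)))
  }
  frags <- fragments_from_sites(pr, integer(0))
  for (rule in rules) {
    pieces <- lapply(seq_len(nrow(frags)), function(k) {
      sub <- fragments_from_sites(
        protein_record(pr$id, frags$sequence[k]),
        cleavage_sites(frags$sequence[k], list(rule)))
      sub$start <- sub$start + frags$start[k] - 1L
      sub$end <- sub$end + frags$start[k] - 1L
      sub
    })
    frags <- do.call(rbind, pieces)
  }
  rownames(frags) <- NULL
  frags
}

#' Default gastrointestinal digestion stages
#'
#' An ordered two-stage scheme emulating simulated gastrointestinal digestion:
#' a gastric pepsin stage (pH 2 specificity: cuts after F/L/W/Y unless proline
#' follows) followed by an intestinal trypsin stage. Both rules come from the
#' packaged enzyme file and can be overridden.
#'
#' @param rules Named list of cleavage rules to draw the stages from.
#' @return List of two rule lists, one per stage.
#' @export
gastrointestinal_stages <- function(rules = enzyme_rules()) {
  list(list(rules[["pepsin_ph2"]]), list(rules[["trypsin"]]))
}

#' Simulated gastrointestinal digestion of a peptide
#'
#' Applies each stage's digestion sequentially to all current fragments and
#' reports whether the input peptide survives intact — the in-silico
#' counterpart of a pepsin-then-trypsin stability assay.
#'
#' @param peptide A single peptide sequence (or [protein_record()]).
#' @param stages Ordered list of stages, each a `cleavage_rule` or list of
#'   rules; default [gastrointestinal_stages()]. An empty list is the identity.
#' @return List with `fragments` (data frame as from [digest()]) and
#'   `survived` (`TRUE` iff the peptide emerges uncut).
#' @export
#' @examples
#' gi_digest("NWPWMK")$survived   # pepsin cuts after the second W
gi_digest <- function(peptide, stages = gastrointestinal_stages()) {
  pr <- as_protein(peptide, default_id = "peptide")
  frags <- fragments_from_sites(pr, integer(0))
  for (stage in stages) {
    stage_rules <- as_rule_list(stage)
    pieces <- lapply(seq_len(nrow(frags)), function(k) {
      sub <- fragments_from_sites(
        protein_record(pr$id, frags$sequence[k]),
        cleavage_sites(frags$sequence[k], stage_rules))
      sub$start <- sub$start + frags$start[k] - 1L
      sub$end <- sub$end + frags$start[k] - 1L
      sub
    })
    frags <- do.call(rbind, pieces)
    rownames(frags) <- NULL
  }
  list(fragments = frags,
       survived = nrow(frags) == 1L && frags$sequence[1L] == pr$sequence)
}
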