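test_that("the packaged screened-peptide fixture reproduces the funnel counts", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 21L)
  expect_equal(as.vector(table(fx$length)[c("3", "6", "7", "8")]),
               c(3L, 5L, 5L, 8L))
  rep10 <- select_candidates(fx, threshold_uM = 10)
  expect_equal(sum(rep10$candidates$selected), 6L)
  rep100 <- select_candidates(fx, threshold_uM = 100)
  expect_equal(sum(rep100$candidates$selected), 16L)
  expect_equal(unname(rep10$counts), c(6L, 16L))
  # sorted ascending; most potent candidate first
  expect_equal(rep10$candidates$peptide[1], "IPYADFK")
  expect_true(!is.unsorted(rep10$candidates$predicted_ic50_uM))
  # threshold 0 selects nothing
  expect_equal(sum(select_candidates(fx, threshold_uM = 0)$candidates$selected), 0L)
})

test_that("matching is exact intersection with provenance and collapse of duplicates", {
  released <- digest("AAKGGKAAK", enzyme_rules()[["trypsin"]])
  expect_equal(released$sequence, c("AAK", "GGK", "AAK"))
  m <- match_peptides(released, c("AAK", "ZZZ was not valid anyway", "GGK"))
  expect_setequal(m$sequence, c("AAK", "GGK"))
  expect_equal(m$n_copies[m$sequence == "AAK"], 2L)
  expect_equal(m$start[m$sequence == "AAK"], 1L)  # first occurrence kept
  # identical lists retain everything; disjoint lists match nothing
  expect_equal(nrow(match_peptides(released, released$sequence)), 2L)
  expect_equal(nrow(match_peptides(released, "WWW")), 0L)
  expect_error(match_peptides(released, character(0)), "non-empty")
})

test_that("I/L equivalence mode folds isoleucine into leucine on both sides", {
  expect_equal(nrow(match_peptides("AIK", "ALK")), 0L)
  expect_equal(nrow(match_peptides("AIK", "ALK", il_equivalent = TRUE)), 1L)
})

test_that("planted peptides are matched through the digest against a decoy list", {
  gp <- gen_protein(seed = 21, planted = c("NWPWMK", "INEMLDTK"))
  released <- digest(gp$protein, enzyme_rules()["trypsin"])
  m <- match_peptides(released, c("NWPWMK", "QQQQQQ"))
  expect_equal(m$sequence, "NWPWMK")
  expect_equal(m$start, gp$truth$start[gp$truth$peptide == "NWPWMK"])
})

test_that("length filtering keeps only modelled classes in order", {
  peps <- c("AAA", "AAAAA", "AAAAAA", "AAAAAAA", "AAAAAAAA", "AAAA")
  kept <- filter_by_length(peps)
  expect_equal(kept$sequence, c("AAA", "AAAAAA", "AAAAAAA", "AAAAAAAA"))
  expect_equal(nrow(filter_by_length("AAAAA")), 0L)
  expect_equal(nrow(filter_by_length(table1_fixture()$peptide)), 21L)
})

test_that("monoisotopic masses match an independent computation", {
  # YNL: 163.06333 + 114.04293 + 113.08406 + water = 408.200885
  expect_equal(peptide_mass("YNL"), 408.200885, tolerance = 1e-6)
  expect_equal(peptide_mass("G"), 57.02146 + 18.010565, tolerance = 1e-6)
  big <- paste(rep("W", 20), collapse = "")
  kept <- filter_by_mass(c("YNL", big), max_mass_da = 3000)
  expect_equal(kept$sequence, "YNL")
})

test_that("the screening funnel is monotone and deterministic end to end", {
  gp <- gen_protein(seed = 22, length = 400,
                    planted = c("NWPWMK", "INEMLDTK", "SIHEIEK"))
  released <- digest(gp$protein, enzyme_rules()["trypsin"])
  observed <- c(gp$truth$peptide, "DECOYPEP")
  m <- match_peptides(released, observed)
  f <- filter_by_length(m)
  expect_lte(nrow(m), nrow(released))
  expect_lte(nrow(f), nrow(m))
  # byte-identical reports for identical inputs
  fx <- table1_fixture()
  r1 <- select_candidates(fx)
  r2 <- select_candidates(fx)
  expect_identical(r1, r2)
})

test_that("screening reports serialize to TSV and JSON", {
  rep <- select_candidates(table1_fixture())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_screening_report(rep, tsv_path = tsv, json_path = js)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 21L)
  expect_equal(back$peptide[1], "IPYADFK")
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$counts$`<10uM`, 6L)
  expect_equal(summ$counts$`<100uM`, 16L)
})

test_that("the full pipeline screens a planted low-IC50 peptide to the top", {
  # train a model on synthetic data, then screen a protein carrying one
  # peptide engineered (via the generating beta) to be potent and one decoy
  g <- gen_qsar_dataset(seed = 23, n = 120, length = 6, sigma = 0.1)
  model <- fit_qsar(g$data, n_components = 10)
  set.seed(24)
  pool <- replicate(300, random_tryptic_peptide(6))
  eta <- drop(encode_peptides(pool) %*% g$beta)  # truth, not the fitted model
  low <- pool[which.min(eta)]
  high <- pool[which.max(eta)]
  gp <- gen_protein(seed = 25, planted = c(low, high))
  rep <- screen_peptides(gp$protein, enzyme_rules()["trypsin"],
                         observed = c(low, high),
                         models = list("6" = model),
                         threshold_uM = 1e6)
  expect_equal(rep$candidates$peptide[1], low)
})
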