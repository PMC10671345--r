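test_that("cysteine positions are 0-based and concatenative", {
  expect_identical(cysteine_positions("ACCA"), c(1L, 2L))
  expect_identical(cysteine_positions("AAAA"), integer())
  set.seed(9)
  for (i in 1:10) {
    x <- random_protein(sample(5:40, 1)); y <- random_protein(sample(5:40, 1))
    expect_identical(cysteine_positions(paste0(x, y)),
                     c(cysteine_positions(x), cysteine_positions(y) + nchar(x)))
  }
})

test_that("signal peptide heuristic follows its declared rule", {
  ## M + 8 hydrophobic + polar stretch + A at offset 16
  p <- paste0("M", "LLLLLLLL", "KKKKKK", "T", "A", "DEDEDEDEDEDE")
  sp <- predict_signal_peptide(p)
  expect_true(sp$present)
  expect_equal(sp$cleavage, 16L)
  expect_identical(mature_protein(p), "DEDEDEDEDEDE")

  expect_false(predict_signal_peptide(
    paste0("MDDEE", random_protein(40)))$present)      # polar N-terminus
  expect_false(predict_signal_peptide(
    paste0("K", "LLLLLLLL", "KKKKKKTA", random_protein(20)))$present)  # no M
  ## cleavage residue must sit in [15, 35]
  expect_false(predict_signal_peptide(
    paste0("M", "LLLLLLLL", paste(rep("K", 40), collapse = "")))$present)
})

test_that("scaffold conformance counts mature-protein cysteines", {
  six_c <- paste0(paste(rep("ADKE", 10), collapse = ""),
                  paste(rep("CAD", 6), collapse = ""))
  expect_true(check_scaffold(six_c, "hirudin")$conforms)
  five_c <- sub("C", "A", six_c)
  chk <- check_scaffold(five_c, "hirudin")
  expect_false(chk$conforms)
  expect_equal(chk$expected, 6L)
  expect_equal(chk$observed, 5L)
  ## families without a declared count always conform
  expect_true(check_scaffold(random_protein(80), "eglin")$conforms)
  expect_true(check_scaffold(random_protein(80), "lefaxin")$conforms)
  expect_error(check_scaffold(six_c, "not-a-family"), "unknown family")
})

test_that("scaffold counting is invariant under signal-peptide removal", {
  set.seed(77)
  for (i in 1:10) {
    mem <- generate_family_member("hirudin", divergence = 0.1)
    expect_true(predict_signal_peptide(mem$protein)$present)
    expect_true(check_scaffold(mem$protein, "hirudin")$conforms)
    expect_true(check_scaffold(mem$mature, "hirudin")$conforms)
  }
})

make_unit <- function(len, ncys) {
  r <- sample(setdiff(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], "C"),
              len, replace = TRUE)
  r[round(seq(2, len - 1, length.out = ncys))] <- "C"
  paste(r, collapse = "")
}

test_that("planted tandem repeats are segmented exactly", {
  set.seed(55)
  unit6 <- make_unit(30, 6)
  linker <- paste(rep("E", 5), collapse = "")
  two <- paste0(unit6, linker, unit6)
  reps <- detect_tandem_repeats(two)
  expect_equal(nrow(reps), 2L)
  expect_true(all(reps$n_cysteines == 6L))

  unit12 <- make_unit(60, 12)
  five <- paste(rep(unit12, 5), collapse = "")
  reps5 <- detect_tandem_repeats(five)
  expect_equal(nrow(reps5), 5L)
  expect_true(all(reps5$n_cysteines == 12L))
})

test_that("random proteins contain no tandem repeats", {
  set.seed(1)
  p <- random_protein(100)
  expect_equal(nrow(detect_tandem_repeats(p)), 0L)
})

test_that("unit-count recovery holds across seeds and unit multiplicities", {
  for (sd in 1:20) {
    set.seed(sd)
    for (r in c(2L, 3L, 5L)) {
      unit <- make_unit(sample(25:40, 1), 6)
      arr <- paste(rep(unit, r), collapse = "")
      reps <- detect_tandem_repeats(arr)
      expect_equal(nrow(reps), r)
      expect_equal(length(unique(reps$n_cysteines)), 1L)
    }
  }
})

test_that("feature reports serialize to TSV and JSON", {
  set.seed(3)
  mem <- generate_family_member("LDTI", divergence = 0.05)
  rep1 <- protein_features(mem$protein, "LDTI")
  expect_equal(rep1$scaffold$observed, 12L)
  expect_equal(nrow(rep1$repeats), 2L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_feature_reports(list(ldti1 = rep1), tsv)
  write_feature_reports(list(ldti1 = rep1), jsn)
  tab <- read.delim(tsv)
  expect_equal(tab$cysteine_count, 12L)
  expect_equal(jsonlite::read_json(jsn)[[1]]$n_repeat_units, 2L)
})
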