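test_that("local alignment matches hand-checkable cases", {
  a <- local_align("AAAA", "AAAA")
  expect_equal(a$score, 16)
  expect_equal(a$n_similar, 4L)
  expect_equal(a$alignment_length, 4L)
  expect_equal(a$n_gap_columns, 0L)

  wf <- local_align("W", "F")   # BLOSUM62 W/F = 1 > 0
  expect_equal(wf$score, 1)
  expect_equal(wf$alignment_length, 1L)
  expect_equal(wf$n_similar, 1L)

  ## no positive-scoring pair: empty alignment, score 0
  wp <- local_align("W", "P")
  expect_equal(wp$score, 0)
  expect_equal(wp$alignment_length, 0L)
})

test_that("global alignment matches hand-checkable cases and rejects empty input", {
  expect_equal(global_align("AAA", "AAA")$score, 12)
  expect_error(global_align("A", ""), "non-empty")
  expect_error(local_align("", "A"), "non-empty")
  ## MKV/MV: M/M + gap(1) + V/V = 5 - 10.5 + 4
  expect_equal(global_align("MKV", "MV")$score, -1.5)
  expect_equal(global_align("MKV", "MV")$score,
               oracle_align("MKV", "MV", local = FALSE))
})

test_that("the classic two-peptide example agrees with the DP oracle", {
  aln <- local_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(aln$score, oracle_align("HEAGAWGHEE", "PAWHEAE", local = TRUE))
  expect_equal(aln$score, 17.5)      # AWGHE / AW-HE under EMBOSS defaults
  expect_equal(aln$n_similar, 4L)
  expect_equal(aln$n_gap_columns, 1L)
  expect_equal(similarity_index(aln), 100)
  g <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(g$score, oracle_align("HEAGAWGHEE", "PAWHEAE", local = FALSE))
})

test_that("the DP oracle itself matches exhaustive alignment enumeration", {
  set.seed(3)
  ab <- c("A", "W")
  pool <- c(ab, as.vector(outer(ab, ab, paste0)),
            as.vector(outer(as.vector(outer(ab, ab, paste0)), ab, paste0)))
  pairs <- expand.grid(a = pool, b = pool, stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 40), ]
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    expect_equal(oracle_align(a, b, local = FALSE), enum_global_score(a, b))
    expect_equal(oracle_align(a, b, local = TRUE), enum_local_score(a, b))
  }
})

test_that("similarity index follows its defining formula", {
  aln <- structure(list(score = 1, alignment_length = 10L, n_gap_columns = 2L,
                        n_similar = 6L), class = "protein_alignment")
  expect_equal(similarity_index(aln), 75)
  aln$n_gap_columns <- 10L
  expect_error(similarity_index(aln), "undefined")
})

test_that("local self-alignment of any protein scores similarity 100", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_protein(sample(10:120, 1))
    expect_equal(similarity_index(local_align(p, p)), 100)
  }
})

test_that("scores are symmetric and indices bounded", {
  set.seed(8)
  for (i in 1:50) {
    a <- random_protein(sample(3:40, 1)); b <- random_protein(sample(3:40, 1))
    la <- local_align(a, b); lb <- local_align(b, a)
    expect_equal(la$score, lb$score)
    ga <- global_align(a, b); gb <- global_align(b, a)
    expect_equal(ga$score, gb$score)
    if (la$alignment_length - la$n_gap_columns > 0) {
      si <- similarity_index(la)
      expect_gte(si, 0); expect_lte(si, 100)
      expect_equal(si, similarity_index(lb))
    }
  }
})

test_that("appending identical residues never decreases the local score", {
  set.seed(13)
  for (i in 1:30) {
    a <- random_protein(sample(3:25, 1)); b <- random_protein(sample(3:25, 1))
    s0 <- local_align(a, b)$score
    tailseq <- random_protein(sample(1:10, 1))
    s1 <- local_align(paste0(a, tailseq), paste0(b, tailseq))$score
    expect_gte(s1, s0)
  }
})

test_that("the packaged BLOSUM62 is symmetric with the canonical diagonal", {
  m <- blosum62()
  expect_true(isSymmetric(unname(m)))
  expect_equal(m["A", "A"], 4)
  expect_equal(m["W", "W"], 11)
  expect_equal(m["C", "C"], 9)
  expect_equal(m["W", "F"], 1)
})
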