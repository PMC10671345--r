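scan_config <- mine_config()

test_that("sixframe_scan finds planted archetype segments on both strands", {
  reg <- family_registry()
  segment <- substring(reg$archetype[reg$family == "hirudin"], 1, 60)
  set.seed(2)
  planted_nt <- back_translate(segment)
  g_plus <- c(chr1 = paste0(random_dna(4000), planted_nt, random_dna(4000)))
  loci <- sixframe_scan(g_plus, archetype_proteins(reg), scan_config)
  expect_equal(nrow(loci), 1L)
  expect_identical(loci$strand, "+")
  expect_identical(loci$best_archetype, "hirudin")
  expect_lte(abs(loci$start - 4001L), 30L)
  expect_lte(abs(loci$end - (4000L + nchar(planted_nt))), 30L)

  g_minus <- c(chr1 = paste0(random_dna(4000), reverse_complement(planted_nt),
                             random_dna(4000)))
  loci <- sixframe_scan(g_minus, archetype_proteins(reg), scan_config)
  expect_equal(nrow(loci), 1L)
  expect_identical(loci$strand, "-")
  expect_identical(loci$best_archetype, "hirudin")
})

test_that("an unplanted random genome yields no loci", {
  set.seed(1)
  g <- c(chr1 = random_dna(10000))
  loci <- sixframe_scan(g, archetype_proteins(), scan_config)
  expect_equal(nrow(loci), 0L)
})

test_that("splice_map recovers planted intron structure exactly", {
  set.seed(31)
  cds <- paste0("ATG", random_dna(297))
  e1 <- substring(cds, 1, 150); e2 <- substring(cds, 151, 300)
  intron <- paste0("GT", random_dna(96), "AG")
  genome <- c(chr1 = paste0(random_dna(500), e1, intron, e2, random_dna(500)))
  m <- splice_map(cds, genome, "chr1", 1, nchar(genome), "+",
                  config = scan_config)
  expect_s3_class(m, "gene_model")
  expect_equal(m$exons$start, c(501L, 501L + 150L + 100L))
  expect_equal(m$exons$end, c(650L, 900L))
  expect_identical(m$cds, cds)
  expect_equal(as.integer(m$attributes[["n_mismatch"]]), 0L)

  ## contiguous CDS -> single exon
  genome2 <- c(chr1 = paste0(random_dna(300), cds, random_dna(300)))
  m2 <- splice_map(cds, genome2, "chr1", 1, nchar(genome2), "+",
                   config = scan_config)
  expect_equal(nrow(m2$exons), 1L)
  expect_equal(unlist(m2$exons), c(start = 301L, end = 600L))

  ## one substitution: same structure, one mismatch reported
  cds_mut <- cds
  substring(cds_mut, 80, 80) <- setdiff(c("A", "C", "G", "T"),
                                        substring(cds, 80, 80))[1]
  m3 <- splice_map(cds_mut, genome, "chr1", 1, nchar(genome), "+",
                   config = scan_config)
  expect_equal(m3$exons, m$exons)
  expect_equal(as.integer(m3$attributes[["n_mismatch"]]), 1L)
})

test_that("splice_map maps minus-strand genes and fails below coverage", {
  set.seed(33)
  cds <- paste0("ATG", random_dna(237))
  e1 <- substring(cds, 1, 120); e2 <- substring(cds, 121, 240)
  intron <- paste0("GT", random_dna(80), "AG")
  gene <- paste0(e1, intron, e2)
  genome <- c(chr1 = paste0(random_dna(400), reverse_complement(gene),
                            random_dna(400)))
  m <- splice_map(cds, genome, "chr1", 1, nchar(genome), "-",
                  config = scan_config)
  expect_s3_class(m, "gene_model")
  expect_identical(m$cds, cds)
  expect_equal(nrow(m$exons), 2L)

  ## a region shorter than the coverage requirement is a mapping failure
  expect_null(splice_map(cds, genome, "chr1", 1, 100, "-",
                         config = scan_config))
})

toy_model <- function(id, start, end, tier = "evidence", score = NA_real_,
                      strand = "+", exons = NULL) {
  if (is.null(exons)) exons <- data.frame(start = start, end = end)
  gene_model(id, "chr1", strand, exons, source_tier = tier, score = score)
}

test_that("merge_models deduplicates by footprint Jaccard with tier priority", {
  a <- toy_model("a", 1, 300); b <- toy_model("b", 1000, 1300, tier = "abinitio")
  expect_length(merge_models(list(a), list(b)), 2L)

  ## identical footprints across tiers: evidence wins
  dup <- merge_models(list(toy_model("ev", 1, 300, score = 10)),
                      list(toy_model("ab", 1, 300, tier = "abinitio")))
  expect_length(dup, 1L)
  expect_identical(dup[[1]]$source_tier, "evidence")

  ## Jaccard 200/500 = 0.4 < 0.5: both kept
  j4 <- merge_models(list(toy_model("x", 1, 350)), list(toy_model("y", 151, 500,
                                                                  tier = "abinitio")))
  expect_length(j4, 2L)

  ## Jaccard 200/300 >= 0.5 on the same tier: higher score, then smaller start
  tie <- merge_models(list(toy_model("lo", 51, 300, score = 5),
                           toy_model("hi", 1, 250, score = 9)), list())
  expect_length(tie, 1L)
  expect_identical(tie[[1]]$gene_id, "hi")

  ## opposite strands never merge
  st <- merge_models(list(toy_model("p", 1, 300)),
                     list(toy_model("m", 1, 300, tier = "abinitio", strand = "-")))
  expect_length(st, 2L)
})

test_that("merge_models is idempotent and sorts by position", {
  set.seed(17)
  ev <- lapply(1:6, function(i) toy_model(paste0("e", i), i * 1000, i * 1000 + 200))
  ab <- lapply(1:4, function(i) toy_model(paste0("a", i), i * 1000 + 30,
                                          i * 1000 + 230, tier = "abinitio"))
  m1 <- merge_models(ev, ab)
  m2 <- merge_models(m1, list())
  expect_identical(vapply(m1, `[[`, "", "gene_id"), vapply(m2, `[[`, "", "gene_id"))
  starts <- vapply(m1, function(m) m$exons$start[1], numeric(1))
  expect_false(is.unsorted(starts))
})

test_that("pseudogene flagging detects stops, frameshifts and missing starts", {
  genome_free <- function(cds) {
    m <- toy_model("t", 1, nchar(cds))
    m$cds <- cds
    m
  }
  set.seed(41)
  clean <- paste0("ATG", back_translate(random_protein(40, setdiff(strsplit(
    "ARNDCQEGHILKMFPSTWYV", "")[[1]], "M"))), "TAA")
  expect_identical(flag_pseudogene(genome_free(clean))$status, "integral")

  internal_stop <- paste0(substring(clean, 1, 60), "TAA", substring(clean, 64))
  fs <- flag_pseudogene(genome_free(internal_stop))
  expect_identical(fs$status, "pseudogene")
  expect_match(fs$attributes[["pseudogene_evidence"]], "internal_stop")

  ## planted 1-bp deletion shifts the frame
  del <- paste0(substring(clean, 1, 50), substring(clean, 52))
  fdel <- flag_pseudogene(genome_free(del))
  expect_identical(fdel$status, "pseudogene")
  expect_match(fdel$attributes[["pseudogene_evidence"]], "frameshift")

  ## missing ATG only counts with substantial archetype coverage
  no_atg <- sub("^ATG", "CTG", clean)
  expect_identical(flag_pseudogene(genome_free(no_atg))$status, "integral")
  expect_identical(flag_pseudogene(genome_free(no_atg), arch_coverage = 0.9)$status,
                   "pseudogene")
})
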