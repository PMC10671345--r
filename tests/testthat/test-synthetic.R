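test_that("family members preserve scaffold, repeats and signal structure", {
  set.seed(19)
  reg <- family_registry()
  ## divergence 0: mature region identical to the archetype
  m0 <- generate_family_member("hirudin", divergence = 0)
  expect_identical(m0$mature, reg$archetype[reg$family == "hirudin"])
  expect_true(startsWith(m0$protein, "M"))
  expect_identical(translate_frame(m0$cds),
                   paste0(m0$protein, "*"))

  ## cysteine scaffold preserved at any divergence
  for (dv in c(0.05, 0.15, 0.3)) {
    m <- generate_family_member("hirudin", divergence = dv)
    expect_length(cysteine_positions(m$mature), 6L)
  }

  ## repeat families keep their planted unit structure
  g <- generate_family_member("granulin", divergence = 0.08)
  rep_g <- detect_tandem_repeats(g$mature)
  expect_equal(nrow(rep_g), 5L)
  expect_true(all(rep_g$n_cysteines == 12L))
  a <- generate_family_member("antistasin", divergence = 0.08)
  rep_a <- detect_tandem_repeats(a$mature)
  expect_equal(nrow(rep_a), 2L)
  expect_true(all(rep_a$n_cysteines == 10L))

  expect_error(generate_family_member("hirudin", divergence = 0.5))
  expect_error(generate_family_member("nope"), "unknown family")
})

small_config <- function(seed)
  generator_config(genome_length = 80000L,
                   planted = c(hirudin = 2L, destabilase = 2L),
                   pseudogene_count = 1L, decoy_count = 2L, seed = seed)

test_that("generation is deterministic: identical seeds, identical bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic(generate_genome(small_config(4L)), d1)
  write_synthetic(generate_genome(small_config(4L)), d2)
  for (f in c("genome.fa", "evidence.fa", "abinitio.gff3", "truth.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  ## a different seed changes the genome
  write_synthetic(generate_genome(small_config(5L)), d2)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d2, "genome.fa"))))
})

test_that("the truth layer matches the requested configuration", {
  ds <- generate_genome(small_config(4L))
  expect_equal(nrow(ds$truth$genes), 4L)
  expect_equal(sum(ds$truth$genes$status == "pseudogene"), 1L)
  expect_equal(nrow(ds$truth$decoys), 2L)
  ## evidence holds exactly the integral genes
  expect_setequal(names(ds$evidence),
                  ds$truth$genes$gene_id[ds$truth$genes$status == "integral"])
  ## planted gene intervals do not overlap
  g <- ds$truth$genes[order(ds$truth$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  ## each evidence CDS equals the spliced truth exons
  for (gid in names(ds$evidence)) {
    row <- ds$truth$genes[ds$truth$genes$gene_id == gid, ]
    m <- gene_model(gid, row$chrom, row$strand, ds$truth$exons[[gid]])
    expect_identical(model_spliced_cds(m, ds$genome), ds$evidence[[gid]])
  }
})

test_that("a zero-planting genome contains no archetype locus", {
  cfg <- generator_config(genome_length = 30000L, planted = c(hirudin = 0L),
                          pseudogene_count = 0L, decoy_count = 0L, seed = 8L)
  ds <- generate_genome(cfg)
  expect_equal(nrow(ds$truth$genes), 0L)
  loci <- sixframe_scan(ds$genome, archetype_proteins())
  expect_equal(nrow(loci), 0L)
})

test_that("infeasible packings are a configuration error", {
  cfg <- generator_config(genome_length = 4000L,
                          planted = c(granulin = 3L, lumbrokinase = 3L),
                          pseudogene_count = 0L, decoy_count = 0L, seed = 1L)
  expect_error(generate_genome(cfg), "infeasible packing")
})

truth_models <- function(ds) {
  lapply(seq_len(nrow(ds$truth$genes)), function(i) {
    g <- ds$truth$genes[i, ]
    gene_model(g$gene_id, g$chrom, g$strand, ds$truth$exons[[g$gene_id]],
               status = g$status, family = g$family)
  })
}

test_that("recovery scoring is exact on the truth itself", {
  ds <- generate_genome(small_config(4L))
  preds <- truth_models(ds)
  sc <- score_recovery(preds, ds$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$boundary_accuracy, 1)
  expect_equal(sc$family_accuracy, 1)
  expect_equal(sc$status_accuracy, 1)

  sc0 <- score_recovery(list(), ds$truth)
  expect_equal(sc0$recall, 0)

  ## one spurious extra prediction on a decoy lowers precision only
  dec <- ds$truth$decoys[1, ]
  spurious <- gene_model("spur", dec$chrom, dec$strand,
                         data.frame(start = dec$start, end = dec$end),
                         family = "hirudin")
  sc1 <- score_recovery(c(preds, list(spurious)), ds$truth)
  expect_lt(sc1$precision, 1)
  expect_equal(sc1$recall, 1)
})
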