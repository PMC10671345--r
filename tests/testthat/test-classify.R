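test_that("every archetype assigns to its own family with index 100", {
  reg <- family_registry()
  for (i in seq_len(nrow(reg))) {
    af <- assign_family(reg$archetype[i], reg)
    expect_identical(af$family, reg$family[i])
    expect_equal(af$index, 100)
  }
})

test_that("mutated family members assign to their family", {
  set.seed(1)
  mem <- generate_family_member("hirudin", divergence = 0.10)
  af <- assign_family(mem$protein)
  expect_identical(af$family, "hirudin")
  ## oracle: the hirudin archetype is strictly the best by raw score
  tab <- af$table
  expect_identical(tab$family[which.max(tab$score)], "hirudin")
  expect_gt(sort(tab$score, decreasing = TRUE)[1],
            sort(tab$score, decreasing = TRUE)[2])
})

test_that("random proteins are not classified by the pipeline retention rule", {
  set.seed(1)
  reg <- family_registry()
  cfg <- mine_config()
  for (i in 1:5) {
    p <- random_protein(80)
    cl <- hirumine:::.classify_model(p, reg, cfg)
    expect_true(is.na(cl$family))
  }
})

test_that("nj on three taxa solves the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  ## leaf branch lengths: (2+3-4)/2, (2+4-3)/2, (3+4-2)/2
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.5, 1.5, 2.5))
  expect_match(tree_newick(tr), "^\\(")
})

test_that("nj recovers a 4-taxon additive tree exactly", {
  ## tree ((A,B),(C,D)) with every branch length 1
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[LETTERS[1:4], LETTERS[1:4]]),
               unname(d))
})

test_that("nj is deterministic under total ties", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  expect_identical(tree_newick(nj_tree(d)), tree_newick(nj_tree(d)))
  expect_error(nj_tree(d[1:2, 1:2]))
})

test_that("nj recovers random additive topologies", {
  for (sd in 1:10) {
    set.seed(sd)
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    d <- as.matrix(stats::cophenetic(tr0))
    tr1 <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr1))), 0)
  }
})

superfamily_panel <- function(divergences, seed = 10) {
  set.seed(seed)
  reg <- family_registry()
  fams <- c("hirustasin", "guamerin", "piguamerin", "bdellastasin", "poecistasin")
  panel <- setNames(vapply(fams, function(f)
    generate_family_member(f, divergence = divergences)$mature, ""), fams)
  panel
}

test_that("subtype assignment follows the enclosing-clade rule", {
  reg <- family_registry()
  panel <- superfamily_panel(0.05)
  labels <- names(panel)
  g <- reg$archetype[reg$family == "guamerin"]
  out <- assign_subtype(g, panel, labels, "hirustasin")
  expect_identical(out$label, "guamerin")

  ## two identical references with conflicting labels: fallback
  twin <- c(r1 = panel[["hirustasin"]], r2 = panel[["hirustasin"]])
  out2 <- assign_subtype(reg$archetype[reg$family == "hirustasin"], twin,
                         c("x", "y"), "hirustasin")
  expect_identical(out2$label, "hirustasin-like")

  ## a non-member query is a domain error
  expect_error(assign_subtype(reg$archetype[reg$family == "hirudin"], panel,
                              labels, "hirustasin"), "superfamily")
})

test_that("generator-derived subtype variants are recovered", {
  reg <- family_registry()
  fams <- c("hirustasin", "guamerin", "piguamerin", "bdellastasin", "poecistasin")
  panel <- setNames(reg$archetype[match(fams, reg$family)], fams)
  for (sd in 1:10) {
    set.seed(sd + 100)
    v <- generate_family_member("poecistasin", divergence = 0.05)$mature
    ## oracle: nearest reference by exhaustive pairwise distance
    dists <- vapply(panel, function(p) protein_distance(v, p), numeric(1))
    expect_identical(names(which.min(dists)), "poecistasin")
    out <- assign_subtype(v, panel, fams, "hirustasin")
    expect_identical(out$label, "poecistasin")
  }
})

test_that("activity clades are voted by nearest neighbours", {
  set.seed(6)
  refs <- setNames(vapply(1:6, function(i)
    generate_family_member("hirudin", divergence = 0.12)$mature, ""),
    paste0("ref", 1:6))
  labels <- rep(c("active", "inactive"), each = 3)
  expect_identical(activity_clade(refs[["ref1"]], refs, labels), "active")
  expect_identical(activity_clade(refs[["ref5"]], refs, labels), "inactive")
  ## equidistant tie with k = 2 is unresolved
  expect_identical(activity_clade(refs[["ref1"]],
                                  c(a = refs[["ref2"]], b = refs[["ref2"]],
                                    c = refs[["ref2"]]),
                                  c("active", "inactive", "active"), k = 2L),
                   "unknown")
  expect_error(activity_clade(refs[["ref1"]], refs[1:2], labels[1:2]), "at least 3")
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(12)
  seqs <- setNames(vapply(1:4, function(i) random_protein(50), ""), letters[1:4])
  d <- distance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})
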