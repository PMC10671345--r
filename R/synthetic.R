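## Synthetic study-condition generator: desk-scale genomes with planted
## antithrombotic genes (family-correct cysteine scaffolds, signal
## peptides, tandem repeats, GT..AG introns), transcript evidence, a
## degraded ab-initio prediction set, decoys, pseudogenes, and ground
## truth for recovery scoring. Identical seeds give identical output.

.AA_NO_C <- setdiff(AA_CHARS, c("C", "X", "*"))
.SIGNAL_FILLER <- c("K", "R", "N", "D", "Q", "E", "T", "H")  # polar, no A/G/S/C

.random_signal_peptide <- function() {
  ## M + 2 polar + 8 hydrophobic core + polar filler + cleavage residue A;
  ## satisfies the package's signal-peptide heuristic by construction and
  ## introduces no cysteine. Cleavage offset sampled in 15..19.
  cleav <- sample(15:19, 1L)
  core <- sample(c("L", "V", "F", "I", "W"), 8L, replace = TRUE)
  filler_len <- cleav - 11L  # offsets 11 .. cleav-1
  paste(c("M", sample(.SIGNAL_FILLER, 2L, replace = TRUE), core,
          sample(.SIGNAL_FILLER, filler_len, replace = TRUE), "A"),
        collapse = "")
}

.mutate_protein <- function(protein, divergence) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  eligible <- which(ch != "C" & seq_along(ch) > 1L)
  n_mut <- stats::rbinom(1L, length(eligible), divergence)
  if (n_mut > 0L) {
    pick <- sample(eligible, n_mut)
    ch[pick] <- vapply(ch[pick],
                       function(a) sample(setdiff(.AA_NO_C, a), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate one synthetic family member
#'
#' Starts from the packaged archetype, applies random substitutions at the
#' given rate at non-cysteine, non-initial positions (the cysteine scaffold
#' and any repeat structure are preserved by construction), prepends a
#' synthetic signal peptide when the family expects one (an `M` start
#' otherwise), and reverse-translates with uniform random codons plus a
#' random stop codon. Draws come from the current RNG state.
#'
#' @param family family name.
#' @param divergence substitution fraction in `[0, 0.3]`.
#' @param registry registry table.
#' @return list with `protein`, `mature`, `cds`.
#' @export
generate_family_member <- function(family, divergence = 0.1,
                                   registry = family_registry()) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  d <- family_descriptor(family, registry)
  mature <- .mutate_protein(d$archetype, divergence)
  protein <- if (d$signal %in% c("yes", "mixed"))
    paste0(.random_signal_peptide(), mature)
  else paste0("M", mature)
  cds <- paste0(back_translate(protein), sample(c("TAA", "TGA", "TAG"), 1L))
  list(protein = protein, mature = mature, cds = cds)
}

## split a CDS of length len into n_exons parts, each >= min_exon
.split_exons <- function(len, n_exons, min_exon = 90L) {
  if (n_exons * min_exon > len) n_exons <- max(1L, len %/% min_exon)
  if (n_exons == 1L) return(len)
  extra <- len - n_exons * min_exon
  cuts <- sort(sample.int(extra + 1L, n_exons - 1L, replace = TRUE) - 1L)
  min_exon + diff(c(0L, cuts, extra))
}

.random_intron <- function(min_len = 60L, max_len = 500L) {
  len <- sample(min_len:max_len, 1L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

#' Generator configuration
#'
#' Defaults are the package's reference study conditions: a 500 kb genome
#' with 25 planted genes over 10 families (hirudin x5 mirroring the
#' multi-copy structure of the real catalogue), 10% protein divergence
#' from the archetypes, 2 introns per gene, 2 pseudogenes (a lumbrokinase
#' and a destabilase copy, mirroring the pseudogenes of the real genome),
#' 5 decoy genes and an ab-initio prediction set containing 60% of the
#' planted genes.
#'
#' @param genome_length genome size in bp.
#' @param planted named integer vector: family -> number of planted genes.
#' @param divergence substitution fraction per planted gene, in `[0, 0.3]`.
#' @param introns_per_gene introns inserted into each planted gene.
#' @param pseudogene_count number of planted genes degraded into
#'   pseudogenes (premature stop or 1-bp deletion, alternating).
#' @param decoy_count number of random non-target genes.
#' @param abinitio_sensitivity fraction of planted genes present (with
#'   exact coordinates) in the ab-initio GFF3.
#' @param seed mandatory RNG seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(genome_length = 500000L,
                             planted = c(hirudin = 5L, granulin = 1L,
                                         antistasin = 2L, lefaxin = 3L,
                                         eglin = 2L, HMEI = 3L, saratin = 2L,
                                         apyrase = 2L, lumbrokinase = 3L,
                                         destabilase = 2L),
                             divergence = 0.10, introns_per_gene = 2L,
                             pseudogene_count = 2L, decoy_count = 5L,
                             abinitio_sensitivity = 0.6, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(planted >= 0L), divergence >= 0, divergence <= 0.3,
            introns_per_gene >= 0L, pseudogene_count >= 0L,
            abinitio_sensitivity >= 0, abinitio_sensitivity <= 1)
  structure(list(genome_length = as.integer(genome_length), planted = planted,
                 divergence = divergence,
                 introns_per_gene = as.integer(introns_per_gene),
                 pseudogene_count = as.integer(pseudogene_count),
                 decoy_count = as.integer(decoy_count),
                 abinitio_sensitivity = abinitio_sensitivity,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## choose which planted genes become pseudogenes: mirror the real genome
## (a lumbrokinase and a destabilase copy) when those families have spare
## copies, then fall back to random multi-exon genes.
.designate_pseudogenes <- function(genes, k) {
  if (k == 0L) return(integer())
  pick <- integer()
  for (fam in c("lumbrokinase", "destabilase")) {
    if (length(pick) >= k) break
    i <- which(genes$family == fam)
    i <- setdiff(i, pick)
    if (length(i)) pick <- c(pick, i[length(i)])
  }
  if (length(pick) < k) {
    rest <- setdiff(seq_len(nrow(genes)), pick)
    pick <- c(pick, sample(rest, k - length(pick)))
  }
  pick[seq_len(k)]
}

.degrade_cds <- function(cds, type) {
  n <- nchar(cds)
  ncod <- n %/% 3L
  if (type == "stop") {
    j <- sample(seq(round(0.40 * ncod), round(0.60 * ncod)), 1L)
    paste0(substring(cds, 1L, 3L * (j - 1L)), "TAA", substring(cds, 3L * j + 1L))
  } else { # frameshift: single-bp deletion in the first half
    p <- sample(seq(round(0.30 * n), round(0.50 * n)), 1L)
    paste0(substring(cds, 1L, p - 1L), substring(cds, p + 1L))
  }
}

#' Generate a synthetic genome with planted antithrombotic genes
#'
#' Uniform-random background; planted genes are placed non-overlapping
#' (minimum spacing 5 kb) on random strands and split into exons by
#' GT..AG introns; pseudogene-designated genes receive a premature stop or
#' a 1-bp deletion; the evidence FASTA holds the spliced CDS of every
#' integral planted gene; the ab-initio model set holds an
#' `abinitio_sensitivity` fraction of the planted genes (exact
#' coordinates) plus all decoy genes. Identical configs (same seed) give
#' byte-identical output.
#'
#' @param config a [generator_config()].
#' @param registry registry table.
#' @return an object of class `synthetic_dataset`: `genome` (named
#'   character), `evidence` (named character), `abinitio` (list of
#'   `gene_model`), `truth` (list: `genes` data.frame, `exons` list,
#'   `decoys` data.frame), `config`.
#' @export
generate_genome <- function(config, registry = family_registry()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, .generate_genome_impl(config, registry))
}

.generate_genome_impl <- function(config, registry) {
  chrom <- "chr1"
  L <- config$genome_length

  ## plan genes
  fams <- rep(names(config$planted), config$planted)
  n_genes <- length(fams)
  genes <- data.frame(gene_id = sprintf("%s_p%02d", fams, stats::ave(
    seq_along(fams), fams, FUN = seq_along)), family = fams,
    stringsAsFactors = FALSE)
  pseudo_idx <- .designate_pseudogenes(genes, config$pseudogene_count)
  genes$status <- rep("integral", nrow(genes))
  genes$status[pseudo_idx] <- "pseudogene"

  members <- lapply(genes$family, generate_family_member,
                    divergence = config$divergence, registry = registry)
  cds_list <- vapply(members, `[[`, character(1), "cds")
  ptype <- rep(c("stop", "frameshift"), length.out = length(pseudo_idx))
  for (i in seq_along(pseudo_idx))
    cds_list[pseudo_idx[i]] <- .degrade_cds(cds_list[pseudo_idx[i]], ptype[i])

  ## decoys: random coding-like genes unrelated to any archetype (full
  ## 20-residue alphabet, unlike the cysteine-scaffolded planted genes)
  aa20 <- setdiff(AA_CHARS, c("X", "*"))
  decoy_cds <- as.character(replicate(config$decoy_count, {
    prot <- paste(c("M", sample(aa20, sample(100:200, 1L), replace = TRUE)),
                  collapse = "")
    paste0(back_translate(prot), "TAA")
  }))

  ## build gene inserts (exons + introns), then place everything
  build_insert <- function(cds, n_introns) {
    widths <- .split_exons(nchar(cds), n_introns + 1L)
    ends <- cumsum(widths)
    exon_seqs <- substring(cds, c(1L, head(ends, -1L) + 1L), ends)
    introns <- if (length(widths) > 1L)
      replicate(length(widths) - 1L, .random_intron()) else character()
    seqc <- exon_seqs[1]
    local_exons <- data.frame(start = 1L, end = widths[1])
    for (k in seq_along(introns)) {
      seqc <- paste0(seqc, introns[k], exon_seqs[k + 1L])
      s <- nchar(seqc) - widths[k + 1L] + 1L
      local_exons <- rbind(local_exons, data.frame(start = s, end = nchar(seqc)))
    }
    list(seq = seqc, exons = local_exons)
  }

  all_cds <- c(cds_list, decoy_cds)
  n_all <- length(all_cds)
  inserts <- lapply(seq_len(n_all), function(i) {
    ni <- if (i <= n_genes) config$introns_per_gene
    else sample(0:1, 1L)                      # decoys: 0-1 introns
    build_insert(all_cds[[i]], ni)
  })
  widths <- vapply(inserts, function(x) nchar(x$seq), integer(1))
  if (sum(widths) * 2L > L)
    stop("infeasible packing: planted genes exceed half the genome",
         call. = FALSE)

  ## non-overlapping placement, min 5 kb spacing
  occupied <- data.frame(start = integer(), end = integer())
  starts <- integer(n_all)
  for (i in seq_len(n_all)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      s <- sample.int(L - widths[i] - 2000L, 1L) + 1000L
      e <- s + widths[i] - 1L
      if (!nrow(occupied) ||
          all(s > occupied$end + 5000L | e < occupied$start - 5000L)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing: could not place gene ", i, call. = FALSE)
    occupied <- rbind(occupied, data.frame(start = s, end = e))
    starts[i] <- s
  }
  strands <- sample(c("+", "-"), n_all, replace = TRUE)

  ## background, then overwrite with the inserts
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  truth_exons <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    ins <- inserts[[i]]
    s <- if (strands[i] == "+") ins$seq else reverse_complement(ins$seq)
    bg[starts[i]:(starts[i] + widths[i] - 1L)] <-
      strsplit(s, "", fixed = TRUE)[[1]]
    le <- ins$exons
    if (strands[i] == "+") {
      ex <- data.frame(start = starts[i] + le$start - 1L,
                       end = starts[i] + le$end - 1L)
    } else {
      ex <- data.frame(start = starts[i] + (widths[i] - le$end),
                       end = starts[i] + (widths[i] - le$start))
      ex <- ex[order(ex$start), ]
    }
    rownames(ex) <- NULL
    truth_exons[[i]] <- ex
  }
  genome <- setNames(paste(bg, collapse = ""), chrom)

  gene_rows <- data.frame(
    gene_id = genes$gene_id, family = genes$family,
    chrom = rep(chrom, n_genes),
    strand = strands[seq_len(n_genes)],
    start = starts[seq_len(n_genes)],
    end = starts[seq_len(n_genes)] + widths[seq_len(n_genes)] - 1L,
    status = genes$status, stringsAsFactors = FALSE)
  decoy_rows <- if (config$decoy_count > 0L) data.frame(
    decoy_id = sprintf("decoy_%02d", seq_len(config$decoy_count)),
    chrom = chrom, strand = strands[n_genes + seq_len(config$decoy_count)],
    start = starts[n_genes + seq_len(config$decoy_count)],
    end = starts[n_genes + seq_len(config$decoy_count)] +
      widths[n_genes + seq_len(config$decoy_count)] - 1L,
    stringsAsFactors = FALSE)
  else data.frame()

  ## evidence: spliced CDS of every integral planted gene
  integral <- which(genes$status == "integral")
  evidence <- setNames(cds_list[integral], genes$gene_id[integral])

  ## ab-initio: a sensitivity fraction of planted genes + all decoys
  n_ab <- round(config$abinitio_sensitivity * n_genes)
  ab_idx <- sort(sample(n_genes, n_ab))
  abinitio <- c(
    lapply(ab_idx, function(i)
      gene_model(gene_id = paste0("ab_", genes$gene_id[i]), chrom = chrom,
                 strand = strands[i], exons = truth_exons[[i]],
                 source_tier = "abinitio")),
    lapply(seq_len(config$decoy_count), function(j) {
      i <- n_genes + j
      gene_model(gene_id = sprintf("ab_decoy_%02d", j),
                 chrom = chrom, strand = strands[i], exons = truth_exons[[i]],
                 source_tier = "abinitio")
    }))

  structure(list(
    genome = genome, evidence = evidence, abinitio = abinitio,
    truth = list(genes = gene_rows,
                 exons = setNames(truth_exons[seq_len(n_genes)], genes$gene_id),
                 decoys = decoy_rows),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d bp genome, %d planted genes (%d pseudo), %d decoys\n",
              nchar(x$genome[[1]]), nrow(x$truth$genes),
              sum(x$truth$genes$status == "pseudogene"),
              nrow(x$truth$decoys)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits genome.fa, evidence.fa, abinitio.gff3, truth.gff3 and a config
#' echo (config.json).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_fasta(dataset$evidence, file.path(dir, "evidence.fa"))
  write_gff3(dataset$abinitio, file.path(dir, "abinitio.gff3"))
  truth_models <- lapply(seq_len(nrow(dataset$truth$genes)), function(i) {
    g <- dataset$truth$genes[i, ]
    gene_model(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               exons = dataset$truth$exons[[g$gene_id]], status = g$status,
               source_tier = "evidence", family = g$family)
  })
  write_gff3(truth_models, file.path(dir, "truth.gff3"))
  cfg <- dataset$config
  jsonlite::write_json(cfg[setdiff(names(cfg), character())],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Score predicted gene models against the planted truth
#'
#' A prediction matches a truth gene iff same chromosome and strand and the
#' Jaccard overlap of the CDS footprints is at least `min_jaccard`
#' (greedy one-to-one assignment by decreasing overlap).
#'
#' @param predicted list of `gene_model`.
#' @param truth the `truth` element of a `synthetic_dataset`.
#' @param min_jaccard match threshold (default 0.8).
#' @return list of metrics in `[0, 1]`: `precision`, `recall`,
#'   `boundary_accuracy`, `family_accuracy`, `status_accuracy`, plus
#'   `n_pseudogenes_true` / `n_pseudogenes_flagged` and the `matches`
#'   table.
#' @export
score_recovery <- function(predicted, truth, min_jaccard = 0.8) {
  tg <- truth$genes
  n_pred <- length(predicted); n_true <- nrow(tg)
  if (n_pred == 0L)
    return(list(precision = NA_real_, recall = 0, boundary_accuracy = NA_real_,
                family_accuracy = NA_real_, status_accuracy = NA_real_,
                n_pseudogenes_true = sum(tg$status == "pseudogene"),
                n_pseudogenes_flagged = 0L, matches = data.frame()))
  cand <- list()
  for (p in seq_len(n_pred)) for (t in seq_len(n_true)) {
    m <- predicted[[p]]
    if (m$chrom != tg$chrom[t] || m$strand != tg$strand[t]) next
    sp <- model_span(m)
    if (sp[1] > tg$end[t] || tg$start[t] > sp[2]) next
    jac <- footprint_jaccard(m$exons, truth$exons[[tg$gene_id[t]]])
    if (jac >= min_jaccard)
      cand[[length(cand) + 1L]] <- data.frame(pred = p, true = t, jaccard = jac)
  }
  matches <- data.frame(pred = integer(), true = integer(), jaccard = numeric())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$jaccard, cand$pred), ]
    used_p <- used_t <- logical(0)
    for (r in seq_len(nrow(cand))) {
      p <- cand$pred[r]; t <- cand$true[r]
      if (p %in% matches$pred || t %in% matches$true) next
      matches <- rbind(matches, cand[r, ])
    }
  }
  exact_boundary <- family_ok <- status_ok <- logical(nrow(matches))
  for (r in seq_len(nrow(matches))) {
    m <- predicted[[matches$pred[r]]]
    t <- matches$true[r]
    te <- truth$exons[[tg$gene_id[t]]]
    exact_boundary[r] <- nrow(m$exons) == nrow(te) &&
      all(m$exons$start == te$start) && all(m$exons$end == te$end)
    family_ok[r] <- !is.na(m$family) && m$family == tg$family[t]
    status_ok[r] <- m$status == tg$status[t]
  }
  pseudo_t <- which(tg$status == "pseudogene")
  flagged <- sum(vapply(seq_len(nrow(matches)), function(r)
    matches$true[r] %in% pseudo_t &&
      predicted[[matches$pred[r]]]$status == "pseudogene", logical(1)))
  list(precision = nrow(matches) / n_pred,
       recall = nrow(matches) / n_true,
       boundary_accuracy = if (nrow(matches)) mean(exact_boundary) else NA_real_,
       family_accuracy = if (nrow(matches)) mean(family_ok) else NA_real_,
       status_accuracy = if (nrow(matches)) mean(status_ok) else NA_real_,
       n_pseudogenes_true = length(pseudo_t),
       n_pseudogenes_flagged = as.integer(flagged),
       matches = matches)
}
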