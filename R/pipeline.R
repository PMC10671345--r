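## End-to-end annotation: six-frame scan -> candidate gene regions ->
## spliced evidence mapping (+ archetype back-translation rescue of
## unexplained loci) -> evidence/ab-initio merging -> pseudogene flagging
## -> family classification -> feature validation -> catalogue.

.cluster_regions <- function(loci, config) {
  if (!nrow(loci)) return(loci[0, ])
  out <- list()
  for (key in unique(paste(loci$chrom, loci$strand))) {
    sub <- loci[paste(loci$chrom, loci$strand) == key, ]
    sub <- sub[order(sub$start), ]
    cl <- cumsum(c(1L, diff(sub$start) > config$cluster_gap +
                     (sub$end[-nrow(sub)] - sub$start[-nrow(sub)])))
    for (ci in unique(cl)) {
      s <- sub[cl == ci, ]
      best <- which.max(s$raw_score)
      out[[length(out) + 1L]] <- data.frame(
        chrom = s$chrom[1], strand = s$strand[1],
        start = min(s$start), end = max(s$end),
        best_archetype = s$best_archetype[best],
        raw_score = s$raw_score[best], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

.overlaps_any <- function(chrom, strand, start, end, models) {
  for (m in models) {
    if (m$chrom != chrom || m$strand != strand) next
    sp <- model_span(m)
    if (sp[1] <= end && start <= sp[2]) return(TRUE)
  }
  FALSE
}

## classification used by the pipeline: best archetype by similarity index,
## assigned when the index reaches min_similarity. Homology confirmation
## against random look-alikes is NOT done here: retained models must also
## overlap a six-frame scan locus (.has_confirming_locus), whose
## band-limited extension alignment cannot be reached by the gap-chained
## local alignments random (decoy) proteins produce under cheap gap
## extension.
.classify_model <- function(protein, registry, config) {
  assign_family(protein, registry, min_index = config$min_similarity,
                min_score = config$locus_score_min)
}

## does a model overlap a same-strand candidate locus at or above the scan
## score threshold? Every retained model must be anchored to the genome
## homology signal, not only to its own protein-level alignment.
.has_confirming_locus <- function(model, loci, config) {
  if (!nrow(loci)) return(FALSE)
  sp <- model_span(model)
  hit <- loci$chrom == model$chrom & loci$strand == model$strand &
    loci$raw_score >= config$locus_score_min &
    loci$start <= sp[2] & sp[1] <= loci$end
  any(hit)
}

#' Annotate a genome for antithrombotic gene families
#'
#' Runs the complete mining pipeline on a genome with transcript/CDS
#' evidence and an ab-initio gene prediction set, and returns classified
#' gene models plus the per-family catalogue.
#'
#' @param genome named character vector of chromosome sequences, or a FASTA
#'   path.
#' @param evidence named character vector of CDS evidence sequences, or a
#'   FASTA path (NULL for none).
#' @param abinitio list of `gene_model` objects, or a GFF3 path (NULL for
#'   none).
#' @param registry registry table.
#' @param config a [mine_config()].
#' @param seed RNG seed (archetype back-translation during locus rescue is
#'   the only stochastic step).
#' @param tiers which model tiers to use: subset of
#'   `c("evidence", "abinitio")`.
#' @param rescue map archetype back-translations onto candidate loci not
#'   explained by any model (recovers pseudogenes absent from the evidence
#'   set); only active when the evidence tier is enabled.
#' @param source_name column name for the catalogue.
#' @return an object of class `antithrombotic_annotation` with elements
#'   `models` (classified, family-assigned), `dropped` (models failing
#'   classification), `loci`, `regions`, `catalogue`, `features`, `config`.
#' @export
annotate_genome <- function(genome, evidence = NULL, abinitio = NULL,
                            registry = family_registry(),
                            config = mine_config(), seed = 1L,
                            tiers = c("evidence", "abinitio"),
                            rescue = TRUE, source_name = "this_run") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(evidence) && length(evidence) == 1L && file.exists(evidence))
    evidence <- read_fasta(evidence)
  if (is.character(abinitio) && length(abinitio) == 1L && file.exists(abinitio))
    abinitio <- read_gff3(abinitio)
  if (is.null(evidence)) evidence <- character()
  if (is.null(abinitio)) abinitio <- list()
  arch <- archetype_proteins(registry)

  loci <- sixframe_scan(genome, arch, config)
  regions <- .cluster_regions(loci, config)

  ## pre-assign evidence CDSs to families (cheap protein-level screen)
  ev_family <- character(0)
  if (length(evidence) && "evidence" %in% tiers) {
    ev_family <- vapply(evidence, function(cds) {
      p <- sub("\\*+$", "", translate_frame(cds, 0L))
      .classify_model(p, registry, config)$family
    }, character(1))
  }

  evidence_models <- list()
  if (nrow(regions) && "evidence" %in% tiers && length(evidence)) {
    for (ri in seq_len(nrow(regions))) {
      r <- regions[ri, ]
      cand <- which(ev_family == r$best_archetype)
      best <- NULL
      for (ci in cand) {
        m <- splice_map(evidence[[ci]], genome, r$chrom,
                        r$start - config$flank, r$end + config$flank,
                        strand = r$strand, config = config,
                        gene_id = sprintf("ev_r%02d_%s", ri, names(evidence)[ci]),
                        source_tier = "evidence")
        if (!is.null(m) && (is.null(best) || m$score > best$score)) best <- m
      }
      if (!is.null(best)) evidence_models[[length(evidence_models) + 1L]] <- best
    }
  }

  ## rescue: loci regions explained by neither evidence models nor the
  ## ab-initio set get a spliced mapping of the back-translated archetype
  rescue_models <- list()
  if (rescue && "evidence" %in% tiers && nrow(regions)) {
    known <- c(evidence_models, if ("abinitio" %in% tiers) abinitio)
    for (ri in seq_len(nrow(regions))) {
      r <- regions[ri, ]
      if (.overlaps_any(r$chrom, r$strand, r$start, r$end, known)) next
      bt <- with_seed(seed + ri, back_translate(arch[[r$best_archetype]]))
      m <- splice_map(bt, genome, r$chrom, r$start - config$flank,
                      r$end + config$flank, strand = r$strand, config = config,
                      gene_id = sprintf("rescue_r%02d_%s", ri, r$best_archetype),
                      source_tier = "evidence")
      if (is.null(m)) next
      ## a rescue model must actually be the region's family: the frame
      ## with the best registry alignment has to recover the same family
      ## the locus was seeded by
      fams <- vapply(0:2, function(f) {
        p <- sub("\\*+$", "", translate_frame(m$cds, f))
        if (!nzchar(p)) return(NA_character_)
        .classify_model(p, registry, config)$family
      }, character(1))
      if (!any(!is.na(fams) & fams == r$best_archetype)) next
      rescue_models[[length(rescue_models) + 1L]] <- m
    }
  }

  ## fill in CDS/protein for ab-initio models
  ab_models <- list()
  if ("abinitio" %in% tiers && length(abinitio)) {
    ab_models <- lapply(abinitio, function(m) {
      m$cds <- model_spliced_cds(m, genome)
      m$protein <- translate_frame(m$cds, 0L)
      m
    })
  }

  merged <- merge_models(c(evidence_models, rescue_models), ab_models,
                         dup_jaccard = config$dup_jaccard)

  ## classify, flag, and keep assignable models. For inexact mappings
  ## (cross-member or back-translated queries, where end-trimming and net
  ## indels break the query's codon correspondence) the reading frame of
  ## the spliced genomic CDS is inferred by homology: the frame whose
  ## translation aligns best against the registry wins.
  kept <- list(); dropped <- list()
  for (m in merged) {
    if (!.has_confirming_locus(m, loci, config)) {
      dropped[[length(dropped) + 1L]] <- m; next
    }
    nm <- if ("n_mismatch" %in% names(m$attributes))
      as.integer(m$attributes[["n_mismatch"]]) else 0L
    cov <- if ("coverage" %in% names(m$attributes))
      as.numeric(m$attributes[["coverage"]]) else 1
    inexact <- isTRUE(nm > 0L) || isTRUE(cov < 0.999)
    if (inexact && !is.na(m$cds)) {
      best_f <- NULL
      for (f in 0:2) {
        p <- sub("\\*+$", "", translate_frame(m$cds, f))
        if (!nzchar(p)) next
        cl_f <- .classify_model(p, registry, config)
        if (!is.na(cl_f$family) &&
            (is.null(best_f) || cl_f$score > best_f$cl$score))
          best_f <- list(frame = f, prot = p, cl = cl_f)
      }
      if (!is.null(best_f)) {
        m$protein <- translate_frame(m$cds, best_f$frame)
        m$attributes[["cds_frame"]] <- as.character(best_f$frame)
      }
    }
    prot <- sub("\\*+$", "", m$protein)
    if (!nzchar(prot)) { dropped[[length(dropped) + 1L]] <- m; next }
    cl <- .classify_model(prot, registry, config)
    if (is.na(cl$family)) { dropped[[length(dropped) + 1L]] <- m; next }
    m$family <- cl$family
    m$attributes <- c(m$attributes,
                      similarity_index = sprintf("%.2f", cl$index),
                      archetype_coverage = sprintf("%.3f", cl$coverage))
    m <- flag_pseudogene(m, arch_coverage = cl$coverage)
    kept[[length(kept) + 1L]] <- m
  }

  ## stable ids ordered along the genome
  if (length(kept)) {
    ord <- order(vapply(kept, `[[`, character(1), "chrom"),
                 vapply(kept, function(m) model_span(m)[1], numeric(1)))
    kept <- kept[ord]
    fam_counter <- integer(0)
    for (i in seq_along(kept)) {
      f <- kept[[i]]$family
      fam_counter[f] <- if (is.na(fam_counter[f])) 1L else fam_counter[f] + 1L
      kept[[i]]$attributes <- c(kept[[i]]$attributes,
                                source_id = kept[[i]]$gene_id)
      kept[[i]]$gene_id <- sprintf("%s_g%02d", f, fam_counter[f])
    }
  }

  features <- setNames(
    lapply(kept, function(m)
      protein_features(sub("\\*.*$", "", m$protein), m$family, registry)),
    vapply(kept, `[[`, character(1), "gene_id"))

  catalogue <- build_catalogue(setNames(list(kept), source_name))

  structure(list(models = kept, dropped = dropped, loci = loci,
                 regions = regions, catalogue = catalogue,
                 features = features, config = config, seed = seed),
            class = "antithrombotic_annotation")
}

#' @export
print.antithrombotic_annotation <- function(x, ...) {
  cat(sprintf("<antithrombotic_annotation> %d gene model(s) (%d pseudogene), %d dropped\n",
              length(x$models),
              sum(vapply(x$models, `[[`, character(1), "status") == "pseudogene"),
              length(x$dropped)))
  if (length(x$models)) {
    fams <- vapply(x$models, `[[`, character(1), "family")
    print(table(fams))
  }
  invisible(x)
}

#' @export
summary.antithrombotic_annotation <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$catalogue)
  invisible(object)
}

#' Write annotation results
#'
#' Emits the merged model set as GFF3 plus the model proteins as FASTA
#' (the final-catalogue analogue of a merged prediction GFF).
#'
#' @param annotation an `antithrombotic_annotation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(annotation$models, file.path(dir, "antithrombotic.gff3"))
  prots <- setNames(
    vapply(annotation$models, function(m) sub("\\*.*$", "", m$protein),
           character(1)),
    vapply(annotation$models, `[[`, character(1), "gene_id"))
  if (length(prots)) write_fasta(prots, file.path(dir, "proteins.faa"))
  write_catalogue(annotation$catalogue, file.path(dir, "catalogue.tsv"))
  invisible(dir)
}
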