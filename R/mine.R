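## Candidate-locus discovery and gene-model construction:
##  - six-frame seeded homology scan of the genome against archetype proteins
##  - spliced CDS-to-genome mapping with GT..AG introns (est2genome style)
##  - evidence/ab-initio model merging with footprint-Jaccard deduplication
##  - pseudogene flagging on the spliced genomic CDS

#' Mining configuration
#'
#' Tunables of the homology-mining stage. Defaults are calibrated for
#' desk-scale genomes (hundreds of kilobases) and are all exposed here.
#'
#' @param seed_k amino-acid seed word length for the six-frame scan.
#' @param seed_pair_dist two seeds on one (frame, diagonal) within this many
#'   residues trigger an extension.
#' @param locus_score_min minimum Smith-Waterman raw score (BLOSUM62, EMBOSS
#'   gap defaults) for a candidate locus to be reported.
#' @param band_pad residues of slack around the seeded archetype span when
#'   extending.
#' @param flank nucleotides of genomic context added on each side of a
#'   candidate locus cluster before spliced mapping.
#' @param cluster_gap same-strand loci closer than this (nt) are treated as
#'   exons of one candidate gene region.
#' @param min_intron,max_intron admissible intron length range (nt); introns
#'   must have GT..AG termini.
#' @param intron_penalty fixed score penalty per intron.
#' @param nt_match,nt_mismatch,nt_gap_open,nt_gap_extend nucleotide scoring
#'   for spliced mapping (gap of length L costs open + extend * L).
#' @param min_coverage minimum fraction of the CDS that must align for a
#'   mapping to be retained.
#' @param min_similarity minimum similarity index (%) of a model protein
#'   against its best archetype for the model to be retained.
#' @param min_arch_coverage archetype-coverage fraction above which a model
#'   lacking a start codon is treated as a pseudogene candidate.
#' @param max_gap_run locus-extension alignments are split into compact
#'   segments at gap runs of this many columns or more; each segment is
#'   thresholded on its own (genuine loci are compact per-exon matches).
#' @param dup_jaccard CDS-footprint Jaccard at or above which two same-strand
#'   models are duplicates.
#' @return an object of class `mine_config`.
#' @export
mine_config <- function(seed_k = 4L, seed_pair_dist = 40L, locus_score_min = 60,
                        band_pad = 30L, flank = 3000L, cluster_gap = 2000L,
                        min_intron = 30L, max_intron = 20000L,
                        intron_penalty = 40L, nt_match = 5L, nt_mismatch = -4L,
                        nt_gap_open = 8L, nt_gap_extend = 2L,
                        min_coverage = 0.6, min_similarity = 50,
                        min_arch_coverage = 0.6, max_gap_run = 10L,
                        dup_jaccard = 0.5) {
  structure(as.list(environment()), class = "mine_config")
}

## ---- six-frame scan ----------------------------------------------------

## aa position (1-based, in the frame translation of strand sequence of
## length L) -> nt interval on the forward genome
.aa_to_nt <- function(p_start, p_end, frame, strand, L) {
  if (strand == "+") {
    c(frame + 3L * (p_start - 1L) + 1L, frame + 3L * p_end)
  } else {
    c(L - frame - 3L * p_end + 1L, L - frame - 3L * (p_start - 1L))
  }
}

#' Six-frame archetype scan of a genome
#'
#' Translates every sequence in all six frames, finds exact `seed_k`-mer
#' protein seeds shared with the archetypes, and extends seed pairs that
#' co-occur on one (frame, diagonal) by full local alignment of the
#' archetype against a bounded window of the frame translation. Windows
#' reaching `locus_score_min` become candidate loci; overlapping same-strand
#' loci are merged (best archetype kept).
#'
#' @param genome named character vector of nucleotide sequences.
#' @param archetypes named character vector of archetype proteins.
#' @param config a [mine_config()].
#' @return data.frame of loci: chrom, start, end, strand, frame,
#'   best_archetype, raw_score, protein_window.
#' @export
sixframe_scan <- function(genome, archetypes, config = mine_config()) {
  stopifnot(length(genome) > 0, length(archetypes) > 0)
  k <- config$seed_k
  scheme <- scoring_scheme()

  ## archetype k-mer index
  arch_kmers <- lapply(archetypes, function(p) {
    n <- nchar(p)
    if (n < k) return(data.frame(kmer = character(), pos = integer()))
    pos <- seq_len(n - k + 1L)
    data.frame(kmer = substring(p, pos, pos + k - 1L), pos = pos,
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, lapply(seq_along(arch_kmers), function(i)
    cbind(arch_kmers[[i]], arch = names(archetypes)[i])))
  if (!nrow(idx)) return(.empty_loci())
  idx_by_kmer <- split(seq_len(nrow(idx)), idx$kmer)

  hits <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") genome[[chrom]] else reverse_complement(genome[[chrom]])
      for (frame in 0:2) {
        prot <- translate_frame(seqs, frame)
        n <- nchar(prot)
        if (n < k) next
        gpos <- seq_len(n - k + 1L)
        gk <- substring(prot, gpos, gpos + k - 1L)
        ## all (genome kmer, archetype kmer) coincidences
        m <- match(gk, names(idx_by_kmer))
        found <- which(!is.na(m))
        if (!length(found)) next
        rows_list <- idx_by_kmer[m[found]]
        counts <- lengths(rows_list)
        rows <- unlist(rows_list, use.names = FALSE)
        seeds <- data.frame(gpos = rep(gpos[found], counts),
                            apos = idx$pos[rows], arch = idx$arch[rows],
                            stringsAsFactors = FALSE)
        seeds$diag <- seeds$gpos - seeds$apos
        ## seed pairing: two seeds, same (arch, diagonal), within distance
        seeds <- seeds[order(seeds$arch, seeds$diag, seeds$gpos), ]
        grp <- paste(seeds$arch, seeds$diag)
        trig <- unlist(lapply(split(seq_len(nrow(seeds)), grp), function(ii) {
          if (length(ii) < 2L) return(integer())
          g <- seeds$gpos[ii]
          keep <- c(FALSE, diff(g) <= config$seed_pair_dist)
          ii[keep | c(keep[-1L], FALSE)]
        }))
        if (!length(trig)) next
        tr <- seeds[sort(unique(trig)), ]
        ## one extension window per (arch, coarse diagonal/position cluster)
        for (arch in unique(tr$arch)) {
          sub <- tr[tr$arch == arch, ]
          La <- nchar(archetypes[[arch]])
          sub <- sub[order(sub$diag, sub$gpos), ]
          cl <- cumsum(c(1L, (diff(sub$diag) > 15L | diff(sub$gpos) > La)))
          for (ci in unique(cl)) {
            s <- sub[cl == ci, ]
            d0 <- round(stats::median(s$diag))
            w1 <- max(1L, d0 + 1L - config$band_pad)
            w2 <- min(n, d0 + La + config$band_pad)
            window <- substring(prot, w1, w2)
            aln <- local_align(archetypes[[arch]], window, scheme)
            segs <- .compact_segments(aln, scheme, config$max_gap_run)
            if (is.null(segs)) next
            segs <- segs[segs$score >= config$locus_score_min, , drop = FALSE]
            for (si in seq_len(nrow(segs))) {
              p1 <- w1 + segs$s1[si] - 1L
              p2 <- w1 + segs$s2[si] - 1L
              nt <- .aa_to_nt(p1, p2, frame, strand, L)
              hits[[length(hits) + 1L]] <- data.frame(
                chrom = chrom, start = nt[1], end = nt[2], strand = strand,
                frame = frame, best_archetype = arch,
                raw_score = segs$score[si],
                protein_window = substring(prot, p1, p2),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(hits)) return(.empty_loci())
  loci <- do.call(rbind, hits)
  .merge_loci(loci)
}

## Split a (possibly gap-bridged) window alignment into compact segments at
## gap runs of at least max_gap_run columns, scoring each segment by its
## own columns (substitution scores minus affine costs of its short gaps).
## A multi-exon gene bridged across intron garbage decomposes into its
## per-exon matches; gap-chained random patchwork decomposes into
## sub-threshold fragments.
.compact_segments <- function(aln, scheme, max_gap_run = 10L) {
  if (aln$alignment_length == 0L) return(NULL)
  qa <- strsplit(aln$query_aligned, "", fixed = TRUE)[[1]]
  sa <- strsplit(aln$subject_aligned, "", fixed = TRUE)[[1]]
  gap <- qa == "-" | sa == "-"
  qpos <- aln$query_span[1] - 1L + cumsum(qa != "-")
  spos <- aln$subject_span[1] - 1L + cumsum(sa != "-")
  runs <- rle(gap)
  seg <- integer(length(gap)); cur <- 1L; at <- 1L
  for (r in seq_along(runs$lengths)) {
    ii <- at:(at + runs$lengths[r] - 1L)
    if (runs$values[r] && runs$lengths[r] >= max_gap_run) {
      seg[ii] <- NA_integer_; cur <- cur + 1L
    } else seg[ii] <- cur
    at <- at + runs$lengths[r]
  }
  out <- list()
  for (sid in unique(seg[!is.na(seg)])) {
    ii <- which(seg == sid)
    g <- gap[ii]
    ## trim leading/trailing gap columns of the segment
    nz <- which(!g)
    if (!length(nz)) next
    ii <- ii[min(nz):max(nz)]; g <- gap[ii]
    score <- sum(scheme$matrix[cbind(qa[ii][!g], sa[ii][!g])])
    if (any(g)) {
      gr <- rle(g)
      glen <- gr$lengths[gr$values]
      score <- score - sum(scheme$gap_open + scheme$gap_extend * glen)
    }
    out[[length(out) + 1L]] <- data.frame(
      score = score,
      q1 = min(qpos[ii][!g]), q2 = max(qpos[ii][!g]),
      s1 = min(spos[ii][!g]), s2 = max(spos[ii][!g]),
      length = length(ii), n_gap = sum(g))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

.empty_loci <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(),
             best_archetype = character(), raw_score = numeric(),
             protein_window = character(), stringsAsFactors = FALSE)
}

## merge overlapping same-strand loci, keeping the best-scoring archetype
.merge_loci <- function(loci) {
  out <- list()
  for (key in unique(paste(loci$chrom, loci$strand))) {
    sub <- loci[paste(loci$chrom, loci$strand) == key, ]
    sub <- sub[order(sub$start, sub$end), ]
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur$end) {
        cur$end <- max(cur$end, sub$end[i])
        cur$start <- min(cur$start, sub$start[i])
        if (sub$raw_score[i] > cur$raw_score) {
          cur$raw_score <- sub$raw_score[i]
          cur$best_archetype <- sub$best_archetype[i]
          cur$frame <- sub$frame[i]
          cur$protein_window <- sub$protein_window[i]
        }
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

## ---- spliced mapping ---------------------------------------------------

.NT_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

#' Spliced alignment of a CDS to a genomic region
#'
#' est2genome-style dynamic program: match/mismatch columns, affine short
#' indels, and intron gaps admitted only at GT..AG termini with length at
#' least `min_intron`, at a fixed per-intron penalty. Returns the gene model
#' maximizing the local alignment score, or NULL when less than
#' `min_coverage` of the CDS aligns (mapping failure: the locus is dropped).
#'
#' @param cds CDS sequence (5'->3'; length >= 60 recommended).
#' @param genome named character vector of chromosome sequences.
#' @param chrom,region_start,region_end genomic region to map against.
#' @param strand strand on which to map (`"+"` or `"-"`).
#' @param config a [mine_config()].
#' @param gene_id identifier for the resulting model.
#' @param source_tier provenance tier recorded on the model.
#' @return a `gene_model` (with `score`, `cds`, `protein` filled in and the
#'   mapping coverage in `attributes["coverage"]`), or NULL.
#' @export
splice_map <- function(cds, genome, chrom, region_start, region_end,
                       strand = "+", config = mine_config(),
                       gene_id = "gene1", source_tier = "evidence") {
  stopifnot(chrom %in% names(genome))
  L <- nchar(genome[[chrom]])
  region_start <- max(1L, as.integer(region_start))
  region_end <- min(L, as.integer(region_end))
  region <- substring(genome[[chrom]], region_start, region_end)
  if (strand == "-") region <- reverse_complement(region)

  q <- unname(.NT_CODE[strsplit(cds, "", fixed = TRUE)[[1]]])
  g <- unname(.NT_CODE[strsplit(region, "", fixed = TRUE)[[1]]])
  if (anyNA(q) || anyNA(g)) stop("non-nucleotide residue in input", call. = FALSE)

  res <- .cpp_splice_align(q, g, config$nt_match, config$nt_mismatch,
                           config$nt_gap_open, config$nt_gap_extend,
                           config$intron_penalty, config$min_intron)
  if (!length(res$exon_start)) return(NULL)
  coverage <- (res$q_end - res$q_start + 1L) / nchar(cds)
  if (coverage < config$min_coverage) return(NULL)

  ## region (strand-local) coordinates -> forward-genome coordinates
  rlen <- nchar(region)
  if (strand == "+") {
    ex_start <- region_start + res$exon_start - 1L
    ex_end <- region_start + res$exon_end - 1L
  } else {
    ex_start <- region_start + (rlen - res$exon_end)
    ex_end <- region_start + (rlen - res$exon_start)
  }
  model <- gene_model(gene_id = gene_id, chrom = chrom, strand = strand,
                      exons = data.frame(start = ex_start, end = ex_end),
                      source_tier = source_tier, score = res$score,
                      attributes = c(coverage = sprintf("%.3f", coverage),
                                     n_mismatch = res$n_mismatch))
  model$cds <- model_spliced_cds(model, genome)
  ## the query CDS starts at a codon boundary (q = 1); if end-trimming of
  ## the local alignment removed leading query bases, translate the spliced
  ## genomic CDS in the frame the query imposes
  frame0 <- (3L - (res$q_start - 1L) %% 3L) %% 3L
  model$protein <- translate_frame(model$cds, frame0)
  model$attributes <- c(model$attributes, cds_frame = frame0)
  model
}

## ---- merging and pseudogene flagging -----------------------------------

#' Merge evidence and ab-initio gene models
#'
#' Two models are duplicates iff they lie on the same strand and the Jaccard
#' overlap of their genomic CDS footprints is at least `dup_jaccard`
#' (default 0.5). Within a duplicate group the evidence-tier model wins;
#' ties within a tier go to the higher alignment score, then the smaller
#' start. Non-duplicates pass through. Output is sorted by (chrom, start).
#'
#' @param evidence,abinitio lists of `gene_model` objects on one genome.
#' @param dup_jaccard duplicate threshold.
#' @return list of `gene_model` objects.
#' @export
merge_models <- function(evidence, abinitio = list(), dup_jaccard = 0.5) {
  all_models <- c(evidence, abinitio)
  n <- length(all_models)
  if (n == 0L) return(list())
  ## union-find over duplicate pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  spans <- t(vapply(all_models, model_span, numeric(2)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- all_models[[i]]; b <- all_models[[j]]
    if (a$chrom != b$chrom || a$strand != b$strand) next
    if (spans[i, 1] > spans[j, 2] || spans[j, 1] > spans[i, 2]) next
    if (footprint_jaccard(a$exons, b$exons) >= dup_jaccard) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), roots), function(ii) {
    tier <- vapply(all_models[ii], `[[`, character(1), "source_tier")
    sc <- vapply(all_models[ii], function(m) ifelse(is.na(m$score), -Inf, m$score),
                 numeric(1))
    st <- spans[ii, 1]
    pref <- ii[order(tier != "evidence", -sc, st)]
    pref[1]
  }, integer(1))
  out <- all_models[sort(keep)]
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, function(m) model_span(m)[1], numeric(1)))
  out[ord]
}

#' Flag a gene model as pseudogene or integral
#'
#' A model is a pseudogene iff its spliced genomic CDS contains an internal
#' stop codon, or its length is not a multiple of 3 (frameshift), or it
#' lacks an initial ATG while its protein covers at least 60% of its
#' archetype. Every criterion hit is recorded in the model's attributes.
#'
#' @param model a `gene_model` with `cds` filled in.
#' @param arch_coverage fraction of the best archetype covered by the model
#'   protein (NA skips the missing-ATG criterion).
#' @return the model with `status` (and attributes) updated.
#' @export
flag_pseudogene <- function(model, arch_coverage = NA_real_) {
  stopifnot(inherits(model, "gene_model"), !is.na(model$cds))
  cds <- model$cds
  frame <- if ("cds_frame" %in% names(model$attributes))
    as.integer(model$attributes[["cds_frame"]]) else 0L
  hits <- character()
  prot <- translate_frame(cds, frame)
  body <- sub("\\*+$", "", prot)
  if (grepl("*", body, fixed = TRUE)) hits <- c(hits, "internal_stop")
  if ((nchar(cds) - frame) %% 3L != 0L) hits <- c(hits, "frameshift")
  if (substring(cds, 1L, 3L) != "ATG" && !is.na(arch_coverage) &&
      arch_coverage >= 0.6)
    hits <- c(hits, "no_start_codon")
  model$status <- if (length(hits)) "pseudogene" else "integral"
  if (length(hits))
    model$attributes <- c(model$attributes,
                          pseudogene_evidence = paste(hits, collapse = ","))
  model
}
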