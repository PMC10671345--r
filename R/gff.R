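## Gene models and GFF3 serialization.
##
## A gene model is an S3 list: exon coordinates on a genome (ascending
## genomic order; minus-strand models are read right-to-left when spliced),
## the derived CDS/protein, an integral/pseudogene status and a provenance
## tier. GFF3 output is the v3 dialect with gene/mRNA/exon/CDS rows and the
## attributes ID, Parent, family, source_tier and biotype; coordinates on
## disk are 1-based inclusive, identical to the in-memory convention.

#' Construct a gene model
#'
#' @param gene_id identifier.
#' @param chrom chromosome/contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer `start`, `end` columns (1-based
#'   inclusive, ascending, non-overlapping).
#' @param cds spliced CDS (5'->3'), or NA if not yet derived.
#' @param protein translated protein, or NA.
#' @param status `"integral"` or `"pseudogene"`.
#' @param source_tier `"evidence"` or `"abinitio"`.
#' @param family assigned family name or NA.
#' @param score alignment score supporting the model (NA for ab initio).
#' @param attributes named character vector of extra attributes.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NA_character_,
                       protein = NA_character_, status = "integral",
                       source_tier = "evidence", family = NA_character_,
                       score = NA_real_, attributes = character()) {
  stopifnot(is.data.frame(exons), nrow(exons) >= 1L,
            all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"),
            status %in% c("integral", "pseudogene"),
            source_tier %in% c("evidence", "abinitio"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon end < start", call. = FALSE)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch", call. = FALSE)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, protein = protein,
                 status = status, source_tier = source_tier,
                 family = family, score = score, attributes = attributes),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s:%d-%d(%s) %d exon(s), %s, %s, family=%s\n",
              x$gene_id, x$chrom, model_span(x)[1], model_span(x)[2],
              x$strand, nrow(x$exons), x$status, x$source_tier,
              ifelse(is.na(x$family), "unassigned", x$family)))
  invisible(x)
}

model_span <- function(model) c(min(model$exons$start), max(model$exons$end))

## exon phases in translation order (5'->3')
model_phases <- function(model) {
  widths <- model$exons$end - model$exons$start + 1L
  if (model$strand == "-") widths <- rev(widths)
  ph <- cumsum(c(0L, widths[-length(widths)])) %% 3L
  ## phase p means p bases must be removed to reach the next codon start:
  ## GFF3 phase of exon k is (3 - cum_len %% 3) %% 3
  ph <- (3L - ph %% 3L) %% 3L
  ph[1] <- 0L
  if (model$strand == "-") rev(ph) else ph
}

#' Extract the spliced CDS of a model from the genome
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand models).
#'
#' @param model a `gene_model`.
#' @param genome named character vector of chromosome sequences.
#' @return nucleotide sequence.
#' @export
model_spliced_cds <- function(model, genome) {
  chromseq <- genome[[model$chrom]]
  if (is.null(chromseq)) stop("chromosome not in genome: ", model$chrom, call. = FALSE)
  parts <- substring(chromseq, model$exons$start, model$exons$end)
  s <- paste(parts, collapse = "")
  if (model$strand == "-") reverse_complement(s) else s
}

#' Write gene models to a GFF3 file
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    if (nrow(m$exons) < 1L) stop("model without exons: ", m$gene_id, call. = FALSE)
    sp <- model_span(m)
    extra <- if (length(m$attributes))
      paste0(";", paste0(names(m$attributes), "=", m$attributes, collapse = ";"))
    else ""
    biotype <- if (m$status == "pseudogene") "pseudogene" else "protein_coding"
    gene_attr <- sprintf("ID=%s;family=%s;source_tier=%s;biotype=%s%s",
                         m$gene_id, ifelse(is.na(m$family), "unassigned", m$family),
                         m$source_tier, biotype, extra)
    score <- if (is.na(m$score)) "." else format(m$score, trim = TRUE)
    row <- function(type, s, e, ph, attr)
      paste(m$chrom, "hirumine", type, s, e, score, m$strand, ph, attr, sep = "\t")
    tid <- paste0(m$gene_id, ".t1")
    lines <- c(lines,
               row("gene", sp[1], sp[2], ".", gene_attr),
               row("mRNA", sp[1], sp[2], ".", sprintf("ID=%s;Parent=%s", tid, m$gene_id)))
    ph <- model_phases(m)
    for (k in seq_len(nrow(m$exons))) {
      lines <- c(lines,
                 row("exon", m$exons$start[k], m$exons$end[k], ".",
                     sprintf("ID=%s.exon%d;Parent=%s", tid, k, tid)),
                 row("CDS", m$exons$start[k], m$exons$end[k], ph[k],
                     sprintf("ID=%s.cds;Parent=%s", tid, tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.parse_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- vapply(kv, function(p) if (length(p) >= 2) p[2] else "", character(1))
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}

#' Read gene models from a GFF3 file
#'
#' Accepts the dialect written by [write_gff3()]: gene rows carry ID,
#' family, source_tier and biotype; CDS rows define the exon structure.
#' A round trip `read_gff3(write_gff3(x))` reproduces exon coordinates,
#' strand and status attributes exactly.
#'
#' @param path path to a GFF3 file.
#' @return list of `gene_model` objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  rows <- which(keep)
  if (!length(rows)) return(list())
  fields <- strsplit(raw[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("malformed GFF3: expected 9 columns, got %d at line %d",
                 nf[which(nf != 9L)[1]], rows[which(nf != 9L)[1]]), call. = FALSE)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "source", "type", "start", "end", "score",
                  "strand", "phase", "attr")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)

  genes <- tab[tab$type == "gene", , drop = FALSE]
  cds <- tab[tab$type == "CDS", , drop = FALSE]
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  mrna_parent <- setNames(
    vapply(mrna$attr, function(a) .parse_attrs(a)[["Parent"]], character(1)),
    vapply(mrna$attr, function(a) .parse_attrs(a)[["ID"]], character(1)))

  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    at <- .parse_attrs(genes$attr[i])
    gid <- at[["ID"]]
    tids <- names(mrna_parent)[mrna_parent == gid]
    cd <- cds[vapply(cds$attr, function(a) {
      p <- .parse_attrs(a); !is.na(p["Parent"]) && p[["Parent"]] %in% tids
    }, logical(1)), , drop = FALSE]
    if (!nrow(cd))  # tolerate exon-only entries
      cd <- tab[tab$type == "exon" & vapply(tab$attr, function(a) {
        p <- .parse_attrs(a); !is.na(p["Parent"]) && p[["Parent"]] %in% tids
      }, logical(1)), , drop = FALSE]
    if (!nrow(cd)) stop("gene without CDS/exon rows: ", gid, call. = FALSE)
    known <- c("ID", "Parent", "family", "source_tier", "biotype")
    extra <- at[setdiff(names(at), known)]
    fam <- if (!is.na(at["family"]) && at[["family"]] != "unassigned")
      at[["family"]] else NA_character_
    sc <- suppressWarnings(as.numeric(genes$score[i]))
    models[[i]] <- gene_model(
      gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
      exons = data.frame(start = cd$start, end = cd$end),
      status = if (!is.na(at["biotype"]) && at[["biotype"]] == "pseudogene")
        "pseudogene" else "integral",
      source_tier = if (!is.na(at["source_tier"])) at[["source_tier"]] else "abinitio",
      family = fam, score = sc, attributes = extra)
  }
  models
}
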