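## Catalogue aggregation: per-family x per-source gene counts, totals and
## function-category summaries, plus the antithrombin titration formula.
## The hirustasin row is special-cased throughout: hirustasin and
## hirustasin-like are reported as a joint pair that counts as ONE family
## but whose members both enter the totals.

CATALOGUE_FAMILIES <- c("hirudin", "granulin", "antistasin", "lefaxin",
                        "therostasin", "hirustasin", "hirustasin-like",
                        "guamerin", "piguamerin", "bdellastasin",
                        "poecistasin", "eglin", "bdellin", "LDTI", "HMEI",
                        "saratin", "apyrase", "lumbrokinase", "destabilase",
                        "GGT", "LCI", "hyaluronidase")

#' Build a per-family x per-source gene catalogue
#'
#' Counts classified gene models per family and source. Models without an
#' assigned family are excluded from the counts but logged in the
#' `unassigned` attribute; pseudogenes are counted (with per-source
#' pseudogene tallies kept in the `pseudogenes` attribute).
#'
#' @param models_by_source named list: source name -> list of `gene_model`.
#' @return a `catalogue_table`: data.frame families x sources.
#' @export
build_catalogue <- function(models_by_source) {
  stopifnot(is.list(models_by_source), !is.null(names(models_by_source)))
  tab <- matrix(0L, nrow = length(CATALOGUE_FAMILIES),
                ncol = length(models_by_source),
                dimnames = list(CATALOGUE_FAMILIES, names(models_by_source)))
  pseudo <- setNames(integer(length(models_by_source)), names(models_by_source))
  unassigned <- setNames(integer(length(models_by_source)), names(models_by_source))
  for (src in names(models_by_source)) {
    for (m in models_by_source[[src]]) {
      fam <- m$family
      if (is.na(fam)) { unassigned[src] <- unassigned[src] + 1L; next }
      if (!fam %in% CATALOGUE_FAMILIES)
        stop("model family not in catalogue: ", fam, call. = FALSE)
      tab[fam, src] <- tab[fam, src] + 1L
      if (m$status == "pseudogene") pseudo[src] <- pseudo[src] + 1L
    }
  }
  structure(as.data.frame(tab), class = c("catalogue_table", "data.frame"),
            pseudogenes = pseudo, unassigned = unassigned)
}

#' Column totals and nonzero-family counts of a catalogue
#'
#' Totals sum all cells (the hirustasin/hirustasin-like pair contributes
#' both members); the nonzero-family count treats that pair as a single
#' family.
#'
#' @param table a `catalogue_table`.
#' @return data.frame with one row per source: `total`, `n_families`.
#' @export
catalogue_totals <- function(table) {
  stopifnot(inherits(table, "catalogue_table") || is.data.frame(table))
  m <- as.matrix(table)
  pair <- c("hirustasin", "hirustasin-like")
  stopifnot(all(pair %in% rownames(m)))
  totals <- colSums(m)
  merged <- m[setdiff(rownames(m), pair), , drop = FALSE]
  merged <- rbind(merged, hirustasin_pair = colSums(m[pair, , drop = FALSE]))
  nfam <- colSums(merged > 0)
  data.frame(source = colnames(m), total = as.integer(totals),
             n_families = as.integer(nfam), row.names = NULL)
}

#' Function-category summary of the registry
#'
#' @param registry registry table.
#' @return named integer vector: families per function category (summing to
#'   the registry size).
#' @export
category_summary <- function(registry = family_registry()) {
  cats <- c("coagulation inhibitor", "platelet aggregation inhibitor",
            "fibrinolysis enhancer", "tissue penetration enhancer")
  out <- vapply(cats, function(cc) sum(registry$category == cc), integer(1))
  stopifnot(sum(out) == nrow(registry))
  out
}

#' Antithrombin titration specific activity
#'
#' `U = (C1 * V1) / (C2 * V2)`: thrombin units neutralized per mg of
#' inhibitor, from a fibrinogen-clotting titration.
#'
#' @param C1 thrombin activity concentration (U/mL).
#' @param V1 total thrombin volume added (mL).
#' @param C2 test-protein concentration (mg/mL).
#' @param V2 test-protein volume (mL).
#' @return specific activity in U/mg.
#' @export
#' @examples
#' titration_activity(50, 0.020, 0.5, 0.100)  # 20 U/mg
titration_activity <- function(C1, V1, C2, V2) {
  if (!all(is.finite(c(C1, V1, C2, V2)))) stop("non-finite input", call. = FALSE)
  if (C2 <= 0 || V2 <= 0) stop("C2 and V2 must be positive", call. = FALSE)
  if (C1 < 0 || V1 < 0) stop("C1 and V1 must be non-negative", call. = FALSE)
  (C1 * V1) / (C2 * V2)
}

#' Published per-family gene counts (packaged transcription)
#'
#' The printed per-family antithrombotic gene counts from published
#' H. manillensis surveys (two earlier studies and the BRAKER /
#' BRAKER-plus predictions), transcribed verbatim as a packaged fixture so
#' that aggregation arithmetic is testable without external genomes. The
#' `printed_totals` attribute records the totals as printed; the Zheng
#' column's cells sum to one less than its printed total, and
#' [check_printed_totals()] surfaces (never reconciles) that discrepancy.
#'
#' @return a `catalogue_table` with sources guan2019, zheng2022, braker,
#'   braker_plus and a `printed_totals` attribute.
#' @export
published_gene_counts <- function() {
  path <- system.file("extdata", "published_tables",
                      "antithrombotic_gene_counts.tsv", package = "hirumine")
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(identical(sort(raw$family), sort(CATALOGUE_FAMILIES)))
  m <- as.matrix(raw[, setdiff(names(raw), "family"), drop = FALSE])
  rownames(m) <- raw$family
  m <- m[CATALOGUE_FAMILIES, , drop = FALSE]
  printed <- c(guan2019 = 28L, zheng2022 = 46L, braker = 61L, braker_plus = 72L)
  structure(as.data.frame(m), class = c("catalogue_table", "data.frame"),
            printed_totals = printed)
}

#' Compare computed column totals against printed totals
#'
#' @param table a catalogue with a `printed_totals` attribute.
#' @return data.frame of source, computed and printed totals with a
#'   `consistent` flag; inconsistencies raise a warning (they are reported,
#'   not reconciled).
#' @export
check_printed_totals <- function(table = published_gene_counts()) {
  printed <- attr(table, "printed_totals")
  stopifnot(!is.null(printed))
  tot <- catalogue_totals(table)
  out <- data.frame(source = tot$source, computed = tot$total,
                    printed = as.integer(printed[tot$source]))
  out$consistent <- out$computed == out$printed
  if (any(!out$consistent))
    warning("printed column total(s) disagree with cell sums: ",
            paste(out$source[!out$consistent], collapse = ", "),
            " (reported as computed)", call. = FALSE)
  out
}

#' @export
print.catalogue_table <- function(x, ...) {
  cat("Antithrombotic gene catalogue (families x sources)\n")
  print.data.frame(x)
  tot <- catalogue_totals(x)
  cat("totals: ", paste(sprintf("%s=%d", tot$source, tot$total), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write a catalogue as TSV or Markdown
#'
#' @param table a `catalogue_table`.
#' @param path output path; `.md` gives a Markdown table, else TSV.
#' @return the path, invisibly.
#' @export
write_catalogue <- function(table, path) {
  df <- data.frame(family = rownames(table), table, check.names = FALSE)
  if (grepl("\\.md$", path)) {
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    writeLines(c(header, sep, rows), path)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
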