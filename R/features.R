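## Protein-level validation: cysteine scaffolds, internal tandem repeats,
## and a deterministic signal-peptide heuristic. Positions in feature
## reports are 0-based offsets (the common sequence-feature convention);
## repeat spans are 0-based half-open.

HYDROPHOBIC <- c("A", "I", "L", "F", "V", "M", "W", "C")

#' Cysteine positions of a protein
#'
#' @param protein protein sequence.
#' @return 0-based integer offsets of every `C`.
#' @export
#' @examples
#' cysteine_positions("ACCA")  # 1 2
cysteine_positions <- function(protein) {
  check_alphabet(setNames(protein, "protein"), "protein")
  p <- gregexpr("C", protein, fixed = TRUE)[[1]]
  if (p[1] == -1L) integer() else as.integer(p) - 1L
}

#' Signal-peptide heuristic
#'
#' A deterministic approximation of a von-Heijne-style rule (a neural
#' predictor is out of scope): a signal peptide is called iff the protein
#' starts with M, some window of 8 consecutive residues within offsets 1-20
#' contains at least 6 hydrophobic residues (A,I,L,F,V,M,W,C), and a small
#' residue (A, G or S) occurs at an offset in \[15, 35\] after that
#' hydrophobic core. The cleavage position is the first such offset; the
#' mature protein starts at the following residue.
#'
#' @param protein protein sequence.
#' @return list with `present` (logical) and `cleavage` (0-based offset of
#'   the last signal residue, NA when absent).
#' @export
predict_signal_peptide <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  absent <- list(present = FALSE, cleavage = NA_integer_)
  if (n < 16L || ch[1] != "M") return(absent)
  hyd <- ch %in% HYDROPHOBIC
  core_end <- NA_integer_
  for (s in 2:min(14L, n - 7L)) {      # window start offset 1..13 (0-based)
    if (s + 7L > min(21L, n)) break    # window must sit within offsets 1-20
    if (sum(hyd[s:(s + 7L)]) >= 6L) { core_end <- s + 7L; break }
  }
  if (is.na(core_end)) return(absent)
  lo <- max(16L, core_end + 1L); hi <- min(36L, n)  # offsets 15..35, 1-based idx
  if (lo > hi) return(absent)
  cand <- which(ch[lo:hi] %in% c("A", "G", "S"))
  if (!length(cand)) return(absent)
  list(present = TRUE, cleavage = lo + cand[1] - 2L)  # back to 0-based
}

#' Mature protein after signal-peptide cleavage
#'
#' Removes the predicted signal peptide when one is called; otherwise
#' returns the input.
#'
#' @param protein protein sequence.
#' @return mature protein sequence.
#' @export
mature_protein <- function(protein) {
  sp <- predict_signal_peptide(protein)
  if (sp$present) substring(protein, sp$cleavage + 2L) else protein
}

#' Check a protein against its family cysteine scaffold
#'
#' Counts cysteines on the mature protein (after predicted cleavage) and
#' compares against the family expectation. Families without a declared
#' count (lefaxin, eglin) always conform. A deviation is reported, never
#' rejected outright.
#'
#' @param protein protein sequence.
#' @param family family name (must exist in the registry).
#' @param registry registry table.
#' @return list with `conforms`, `expected`, `observed`.
#' @export
check_scaffold <- function(protein, family, registry = family_registry()) {
  d <- family_descriptor(family, registry)
  mat <- mature_protein(protein)
  obs <- length(cysteine_positions(mat))
  if (is.na(d$expected_cys))
    return(list(conforms = TRUE, expected = NA_integer_, observed = obs))
  list(conforms = obs == d$expected_cys, expected = d$expected_cys,
       observed = obs)
}

#' Detect internal tandem repeats
#'
#' Aligns the protein against itself locally with the main diagonal masked
#' (only offsets of at least `min_unit_length` are admissible). A
#' self-alignment whose similarity index reaches `min_index`, whose length
#' is at least `min_unit_length` and which covers at least 80% of one
#' period is the signature of a tandem array; it is segmented into
#' consecutive non-overlapping units of one period, and each unit reports
#' its cysteine count.
#'
#' @param protein protein sequence (length >= 2 * min_unit_length).
#' @param min_unit_length minimum repeat-unit length (residues).
#' @param min_index minimum similarity index (%) between repeat copies.
#' @return data.frame of units: `start`, `end` (0-based half-open),
#'   `n_cysteines`, `unit_index`. Zero rows when no repeat is found.
#' @export
detect_tandem_repeats <- function(protein, min_unit_length = 20L, min_index = 40) {
  n <- nchar(protein)
  empty <- data.frame(start = integer(), end = integer(),
                      n_cysteines = integer(), unit_index = integer())
  if (n < 2L * min_unit_length) return(empty)
  aln <- .self_align_offdiag(protein, min_offset = min_unit_length)
  if (aln$alignment_length == 0L) return(empty)
  denom <- aln$alignment_length - aln$n_gap_columns
  if (denom <= 0L) return(empty)
  idx <- 100 * aln$n_similar / denom
  q0 <- aln$query_span[1]; q1 <- aln$query_span[2]
  s0 <- aln$subject_span[1]; s1 <- aln$subject_span[2]
  period <- s0 - q0
  span_len <- q1 - q0 + 1L
  if (idx < min_index || period < min_unit_length ||
      span_len < min_unit_length || span_len < 0.8 * period)
    return(empty)
  ## tandem array occupies [q0, s1]; cut into periods from q0
  starts <- seq(q0, s1, by = period)
  ends <- pmin(starts + period - 1L, s1)
  keep <- (ends - starts + 1L) >= 0.6 * period
  starts <- starts[keep]; ends <- ends[keep]
  units <- data.frame(
    start = starts - 1L,                     # 0-based half-open
    end = ends,                              # end exclusive == 1-based end
    n_cysteines = vapply(seq_along(starts), function(i)
      length(cysteine_positions(substring(protein, starts[i], ends[i]))),
      integer(1)),
    unit_index = seq_along(starts))
  units
}

#' Full protein feature report
#'
#' Signal peptide call, cysteine positions (mature protein), scaffold
#' conformance against the family expectation, and internal tandem repeats.
#'
#' @param protein protein sequence.
#' @param family family name, or NA to skip the scaffold check.
#' @param registry registry table.
#' @return an object of class `protein_features`.
#' @export
protein_features <- function(protein, family = NA_character_,
                             registry = family_registry()) {
  sp <- predict_signal_peptide(protein)
  mat <- mature_protein(protein)
  scaffold <- if (!is.na(family)) check_scaffold(protein, family, registry)
  else list(conforms = NA, expected = NA_integer_,
            observed = length(cysteine_positions(mat)))
  structure(list(
    family = family,
    signal_peptide = sp,
    cysteine_positions = cysteine_positions(mat),
    cysteine_count = length(cysteine_positions(mat)),
    scaffold = scaffold,
    repeats = detect_tandem_repeats(mat)), class = "protein_features")
}

#' @export
print.protein_features <- function(x, ...) {
  cat("<protein_features>",
      if (!is.na(x$family)) paste0("family=", x$family) else "", "\n")
  cat("  signal peptide:",
      if (x$signal_peptide$present)
        sprintf("cleavage at offset %d", x$signal_peptide$cleavage)
      else "absent", "\n")
  cat(sprintf("  cysteines (mature): %d%s\n", x$cysteine_count,
              if (!is.na(x$scaffold$expected))
                sprintf(" (expected %d: %s)", x$scaffold$expected,
                        ifelse(isTRUE(x$scaffold$conforms), "conforms", "deviates"))
              else ""))
  cat(sprintf("  tandem repeats: %d unit(s)\n", nrow(x$repeats)))
  invisible(x)
}

#' Serialize feature reports
#'
#' @param reports list of `protein_features` (named by protein id).
#' @param path output path; `.json` gives JSON, anything else a TSV.
#' @return the path, invisibly.
#' @export
write_feature_reports <- function(reports, path) {
  rows <- lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(protein = id,
               family = r$family,
               signal_peptide = ifelse(r$signal_peptide$present,
                                       r$signal_peptide$cleavage, NA_integer_),
               cysteine_count = r$cysteine_count,
               cysteine_positions = paste(r$cysteine_positions, collapse = ","),
               scaffold = if (is.na(r$scaffold$conforms)) NA_character_
               else if (isTRUE(r$scaffold$conforms)) "conforms"
               else sprintf("deviates(expected %d, observed %d)",
                            r$scaffold$expected, r$scaffold$observed),
               n_repeat_units = nrow(r$repeats),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (grepl("\\.json$", path))
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  else
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
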