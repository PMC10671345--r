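## Sequence data model: sequences are named character vectors of upper-case
## residues; the name is the record identifier. Genomic coordinates are
## 1-based inclusive throughout (the convention of IRanges/GFF3), so what is
## written to GFF3 is exactly what is held in memory.

NUC_CHARS <- c("A", "C", "G", "T", "N")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Validate residues against an alphabet
#'
#' @param x character vector of sequences.
#' @param alphabet `"nucleotide"` (A,C,G,T,N) or `"protein"` (20 amino
#'   acids plus X and `*`).
#' @return `x`, invisibly, or an error naming the offending characters.
#' @keywords internal
check_alphabet <- function(x, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  ok <- if (alphabet == "nucleotide") NUC_CHARS else AA_CHARS
  for (i in seq_along(x)) {
    ch <- unique(strsplit(x[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, ok)
    if (length(bad))
      stop(sprintf("invalid %s residue(s) %s in sequence %s", alphabet,
                   paste(bad, collapse = ","),
                   if (is.null(names(x))) i else names(x)[i]), call. = FALSE)
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Returns an ordered, named character vector: one element per record, in
#' file order, residues upper-cased.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return named character vector of sequences.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  empty <- !nzchar(out)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, n))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide sequence
#'
#' Standard complement; `N` maps to `N`. An involution.
#'
#' @param x a single nucleotide sequence (character scalar).
#' @return the reverse complement.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  check_alphabet(x, "nucleotide")
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.genetic_code <- function() {
  if (is.null(.hirumine_cache$gc)) .hirumine_cache$gc <- Biostrings::GENETIC_CODE
  .hirumine_cache$gc
}

#' Translate a nucleotide sequence in a given frame
#'
#' Uses the standard nuclear genetic code. Stop codons are rendered `*`,
#' a trailing partial codon is dropped, and any codon containing `N`
#' translates to `X`. A sequence shorter than one codon in the requested
#' frame gives an empty protein (not an error).
#'
#' @param x nucleotide sequence (character scalar).
#' @param frame 0, 1 or 2: offset of the first codon on the given strand.
#' @return protein sequence (possibly empty).
#' @export
#' @examples
#' translate_frame("ATGAAA")        # "MK"
#' translate_frame("ATGTAA")        # "M*"
translate_frame <- function(x, frame = 0L) {
  stopifnot(length(x) == 1L, frame %in% 0:2)
  n <- nchar(x)
  ncod <- (n - frame) %/% 3L
  if (ncod <= 0L) return("")
  starts <- seq(frame + 1L, by = 3L, length.out = ncod)
  codons <- substring(x, starts, starts + 2L)
  aa <- unname(.genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Back-translate a protein with uniform random codon choice
#'
#' Each residue is encoded by one of its synonymous codons chosen uniformly
#' at random from the standard code (draws come from the current RNG
#' state). `*` is encoded by a random stop codon; `X` by `NNN`.
#'
#' @param protein protein sequence (character scalar).
#' @return nucleotide sequence of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  gc <- .genetic_code()
  inv <- .hirumine_cache$gc_inv
  if (is.null(inv)) {
    inv <- split(names(gc), unname(gc))
    .hirumine_cache$gc_inv <- inv
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    if (a == "X") return("NNN")
    opts <- inv[[a]]
    if (is.null(opts)) stop("cannot back-translate residue ", a, call. = FALSE)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Genomic interval
#'
#' 1-based inclusive interval on a named sequence.
#'
#' @param chrom sequence identifier.
#' @param start,end integer bounds, `1 <= start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return a one-row data.frame.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(start >= 1L, end >= start, strand %in% c("+", "-"))
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

## Jaccard overlap of two position sets given as exon tables (start/end cols)
footprint_jaccard <- function(exons_a, exons_b) {
  cover <- function(ex) {
    idx <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
    unique(idx)
  }
  a <- cover(exons_a); b <- cover(exons_b)
  length(intersect(a, b)) / length(union(a, b))
}

## restore-on-exit seeding helper: runs expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
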