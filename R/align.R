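## Affine-gap protein alignment (Smith-Waterman / Needleman-Wunsch, Gotoh
## three-state recurrence in compiled code) with BLOSUM62, and the
## similarity index used throughout the pipeline:
##
##   similarity index = 100 * n_similar / (alignment length - gap columns)
##
## where a column is "similar" when both residues are present and their
## BLOSUM62 score is positive (identities included; X and * never count).

#' Load the packaged BLOSUM62 matrix
#'
#' The NCBI plain-text BLOSUM62 (half-bit units), shipped with the package.
#'
#' @return a symmetric numeric matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.hirumine_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "hirumine")
    m <- as.matrix(read.table(path, check.names = FALSE))
    colnames(m) <- rownames(m)
    .hirumine_cache$blosum62 <- m
  }
  .hirumine_cache$blosum62
}

#' Alignment scoring scheme
#'
#' Defaults are the EMBOSS `water`/`needle` defaults: BLOSUM62, gap open
#' 10.0, gap extend 0.5, with a gap of length L costing `open + extend * L`.
#'
#' @param matrix substitution matrix (residue-named, symmetric).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 10.0, gap_extend = 0.5) {
  stopifnot(is.matrix(matrix), gap_open >= 0, gap_extend >= 0,
            isTRUE(all.equal(matrix, t(matrix))))
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

.encode_protein <- function(x, residues) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, residues) - 1L
  if (anyNA(code))
    stop("residue(s) not in substitution matrix: ",
         paste(unique(ch[is.na(code)]), collapse = ","), call. = FALSE)
  code
}

.make_alignment <- function(a, b, res, scheme) {
  qi <- res$qidx; si <- res$sidx
  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- strsplit(b, "", fixed = TRUE)[[1]]
  qa <- ifelse(qi > 0L, ach[pmax(qi, 1L)], "-")
  sa <- ifelse(si > 0L, bch[pmax(si, 1L)], "-")
  len <- length(qa)
  gap <- qi == 0L | si == 0L
  both <- !gap
  ident <- both & qa == sa & !(qa %in% c("X", "*"))
  mat <- scheme$matrix
  simil <- logical(len)
  if (any(both))
    simil[both] <- mat[cbind(qa[both], sa[both])] > 0 &
      !(qa[both] %in% c("X", "*")) & !(sa[both] %in% c("X", "*"))
  if (len) {
    qr <- range(qi[qi > 0L]); sr <- range(si[si > 0L])
  } else {
    qr <- c(NA_integer_, NA_integer_); sr <- qr
  }
  structure(list(score = res$score,
                 query = a, subject = b,
                 query_aligned = paste(qa, collapse = ""),
                 subject_aligned = paste(sa, collapse = ""),
                 query_span = qr, subject_span = sr,
                 alignment_length = len,
                 n_gap_columns = sum(gap),
                 n_identical = sum(ident),
                 n_similar = sum(simil)),
            class = "protein_alignment")
}

.pair_align <- function(a, b, scheme, local, min_diag = NA_integer_) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L ||
      !nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty character scalars", call. = FALSE)
  res <- .encode_protein(a, rownames(scheme$matrix))
  sub <- .encode_protein(b, rownames(scheme$matrix))
  out <- .cpp_pair_align(res, sub, scheme$matrix, scheme$gap_open,
                         scheme$gap_extend, local, min_diag)
  .make_alignment(a, b, out, scheme)
}

#' Local (Smith-Waterman) protein alignment
#'
#' Optimal affine-gap local alignment. Among co-optimal alignments the
#' longest is reported (remaining ties resolved deterministically by the
#' traceback preference match > gap-in-subject > gap-in-query and by the
#' smallest end coordinates). If no positive-scoring pair exists the score
#' is 0 and the alignment is empty.
#'
#' @param a,b protein sequences (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return a `protein_alignment` with score, aligned strings, spans and the
#'   identical/similar/gap tallies feeding [similarity_index()].
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
local_align <- function(a, b, scheme = scoring_scheme()) {
  .pair_align(a, b, scheme, local = TRUE)
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' Optimal affine-gap global alignment with end gaps penalized.
#'
#' @inheritParams local_align
#' @return a `protein_alignment`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  .pair_align(a, b, scheme, local = FALSE)
}

## self-alignment with the main diagonal masked: used by tandem-repeat
## detection; only cells with subject - query offset >= min_offset are
## admissible.
.self_align_offdiag <- function(a, min_offset, scheme = scoring_scheme()) {
  .pair_align(a, a, scheme, local = TRUE, min_diag = as.integer(min_offset))
}

#' Similarity index of an alignment
#'
#' `100 * n_similar / (alignment_length - n_gap_columns)`: the percentage
#' of gap-free columns whose residue pair has a positive BLOSUM62 score.
#'
#' @param aln a `protein_alignment`.
#' @return percentage in `[0, 100]`.
#' @export
similarity_index <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  denom <- aln$alignment_length - aln$n_gap_columns
  if (denom <= 0)
    stop("similarity index undefined: alignment has no gap-free columns",
         call. = FALSE)
  100 * aln$n_similar / denom
}

#' @export
print.protein_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("# protein alignment  score: %.1f  length: %d\n",
              x$score, x$alignment_length))
  cat(sprintf("# identical: %d  similar: %d  gap columns: %d\n",
              x$n_identical, x$n_similar, x$n_gap_columns))
  if (x$alignment_length > 0) {
    denom <- x$alignment_length - x$n_gap_columns
    if (denom > 0)
      cat(sprintf("# similarity index: %.2f%%\n", 100 * x$n_similar / denom))
    qa <- x$query_aligned; sa <- x$subject_aligned
    for (s in seq(1L, x$alignment_length, by = width)) {
      e <- min(s + width - 1L, x$alignment_length)
      q <- substring(qa, s, e); t <- substring(sa, s, e)
      qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
      mid <- ifelse(qc == tc & qc != "-", "|",
                    ifelse(qc != "-" & tc != "-", ".", " "))
      cat(sprintf("query   %5d %s\n", x$query_span[1] + s - 1L, q))
      cat(sprintf("              %s\n", paste(mid, collapse = "")))
      cat(sprintf("subject %5d %s\n", x$subject_span[1] + s - 1L, t))
    }
  }
  invisible(x)
}
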