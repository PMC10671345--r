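## Independent reference implementations used as test oracles. The affine
## alignment oracle is a plain three-state dynamic program in R (scores
## only); it is itself validated against exhaustive enumeration of all
## alignments on tiny inputs. Cost model: a gap run of length L costs
## open + extend * L.

oracle_align <- function(a, b, gap_open = 10, gap_extend = 0.5, local = FALSE,
                         mat = blosum62()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  if (local) { M[, 1] <- 0; M[1, ] <- 0 } else {
    for (i in seq_len(m)) X[i + 1, 1] <- -(gap_open + gap_extend * i)
    for (j in seq_len(n)) Y[1, j + 1] <- -(gap_open + gap_extend * j)
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- mat[A[i], B[j]]
    d <- max(M[i, j], X[i, j], Y[i, j], if (local) 0 else NEG)
    M[i + 1, j + 1] <- d + s
    X[i + 1, j + 1] <- max(M[i, j + 1], X[i, j + 1] + gap_open, Y[i, j + 1]) -
      gap_open - gap_extend
    Y[i + 1, j + 1] <- max(M[i + 1, j], X[i + 1, j], Y[i + 1, j] + gap_open) -
      gap_open - gap_extend
    if (local && M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
  }
  if (local) best else max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

## exhaustive enumeration of every global alignment (tiny inputs only)
enum_global_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                              mat = blosum62()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  paths <- function(i, j) {
    if (i > length(A) && j > length(B)) return(list(character()))
    out <- list()
    if (i <= length(A) && j <= length(B))
      for (p in paths(i + 1, j + 1)) out[[length(out) + 1L]] <- c("D", p)
    if (i <= length(A))
      for (p in paths(i + 1, j)) out[[length(out) + 1L]] <- c("X", p)
    if (j <= length(B))
      for (p in paths(i, j + 1)) out[[length(out) + 1L]] <- c("Y", p)
    out
  }
  score_path <- function(cols) {
    qpos <- 1L; spos <- 1L; sc <- 0
    r <- rle(cols)
    for (k in seq_along(r$lengths)) {
      ty <- r$values[k]; L <- r$lengths[k]
      if (ty == "D") {
        for (z in seq_len(L)) {
          sc <- sc + mat[A[qpos], B[spos]]; qpos <- qpos + 1L; spos <- spos + 1L
        }
      } else {
        sc <- sc - gap_open - gap_extend * L
        if (ty == "X") qpos <- qpos + L else spos <- spos + L
      }
    }
    sc
  }
  max(vapply(paths(1L, 1L), score_path, numeric(1)))
}

## local = best global alignment over all substring pairs (or empty, 0)
enum_local_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                             mat = blosum62()) {
  m <- nchar(a); n <- nchar(b)
  best <- 0
  for (i1 in seq_len(m)) for (i2 in i1:m)
    for (j1 in seq_len(n)) for (j2 in j1:n) {
      sc <- enum_global_score(substring(a, i1, i2), substring(b, j1, j2),
                              gap_open, gap_extend, mat)
      if (sc > best) best <- sc
    }
  best
}

random_protein <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
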