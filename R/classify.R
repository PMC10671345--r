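## Family assignment against the archetype registry, neighbor-joining trees
## over similarity-index distances, subtype resolution within a superfamily,
## and activity-clade prediction for hirudins.

#' Assign a protein to an archetype family
#'
#' Aligns the protein locally against every archetype. A family is a
#' candidate when the similarity index reaches `min_index` AND the raw
#' alignment score reaches `min_score` (without the score requirement a
#' short perfect micro-alignment against an unrelated archetype reaches
#' index 100 and would outvote the true family) AND at least
#' `min_arch_coverage` of the archetype is covered. The best candidate by
#' index wins; index ties resolve by higher score, then registry order.
#'
#' @param protein protein sequence (non-empty).
#' @param registry registry table.
#' @param min_index minimum similarity index (%); default 50.
#' @param min_score minimum local alignment raw score; default 60 (the
#'   six-frame scan's homology threshold).
#' @param min_arch_coverage minimum archetype coverage fraction.
#' @return list with `family` (NA when unassigned), `index`, `coverage`,
#'   `score`, and the per-family `table` of candidate scores.
#' @export
assign_family <- function(protein, registry = family_registry(),
                          min_index = 50, min_score = 60,
                          min_arch_coverage = 0) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty character scalar", call. = FALSE)
  scheme <- scoring_scheme()
  fams <- registry$family
  idx <- cov <- sc <- numeric(length(fams))
  for (i in seq_along(fams)) {
    aln <- local_align(registry$archetype[i], protein, scheme)
    sc[i] <- aln$score
    if (aln$alignment_length == 0L ||
        aln$alignment_length - aln$n_gap_columns <= 0L) {
      idx[i] <- 0; cov[i] <- 0; next
    }
    idx[i] <- similarity_index(aln)
    cov[i] <- (aln$query_span[2] - aln$query_span[1] + 1L) /
      nchar(registry$archetype[i])
  }
  tab <- data.frame(family = fams, index = idx, coverage = cov, score = sc)
  ok <- idx >= min_index & sc >= min_score & cov >= min_arch_coverage
  if (!any(ok))
    return(list(family = NA_character_, index = max(idx), coverage = NA_real_,
                score = max(sc), table = tab))
  cand <- which(ok)
  best <- cand[order(-idx[cand], -sc[cand])][1]
  list(family = fams[best], index = idx[best], coverage = cov[best],
       score = sc[best], table = tab)
}

#' Similarity-index distance between two proteins
#'
#' `1 - similarity_index/100` of the global affine-gap alignment.
#'
#' @param a,b protein sequences.
#' @return distance in `[0, 1]`.
#' @export
protein_distance <- function(a, b) {
  1 - similarity_index(global_align(a, b)) / 100
}

#' Pairwise distance matrix over proteins
#'
#' @param seqs named character vector of proteins.
#' @return symmetric matrix of [protein_distance()] values, zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    d[i, j] <- d[j, i] <- protein_distance(seqs[[i]], seqs[[j]])
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via ape) on a symmetric distance matrix.
#' Negative branch-length estimates are clamped to zero and flagged in the
#' `clamped` attribute. Deterministic for fixed input.
#'
#' @param d symmetric numeric matrix (>= 3 taxa, zero diagonal, no NaN).
#' @return an `ape::phylo` tree; write with [tree_newick()].
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, !any(is.na(d)))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Newick serialization of a tree
#'
#' @param tree an `ape::phylo`.
#' @param digits branch-length precision.
#' @return newick string.
#' @export
tree_newick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}

#' Subtype assignment within a superfamily
#'
#' Builds a neighbor-joining tree over the labelled reference panel plus
#' the query (distances `1 - similarity_index/100` on global alignments),
#' roots it at the query, and walks outward: the smallest enclosing clade
#' containing at least one reference assigns its label iff all its
#' references agree and the nearest reference is within `radius`; otherwise
#' the fallback label `"<superfamily>-like"` is returned (mirroring how
#' unresolved hirustasin-superfamily members are reported).
#'
#' @param query protein sequence.
#' @param panel named character vector of reference proteins.
#' @param labels character vector of subtype labels, parallel to `panel`.
#' @param superfamily superfamily name used for the fallback label and for
#'   the domain check.
#' @param superfamily_members family names constituting the superfamily
#'   (the query must assign to one of them).
#' @param registry registry table.
#' @param radius maximum distance to the nearest reference.
#' @param min_index passed to [assign_family()] for the domain check.
#' @return list with `label`, `nearest`, `nearest_distance`.
#' @export
assign_subtype <- function(query, panel, labels, superfamily,
                           superfamily_members = HIRUSTASIN_SUPERFAMILY,
                           registry = family_registry(), radius = 0.6,
                           min_index = 50) {
  stopifnot(length(panel) >= 1L, length(labels) == length(panel))
  af <- assign_family(query, registry, min_index = min_index)
  if (is.na(af$family) || !(af$family %in% superfamily_members))
    stop("query does not assign to the ", superfamily, " superfamily",
         call. = FALSE)
  qd <- vapply(panel, function(p) protein_distance(query, p), numeric(1))
  nearest <- which.min(qd)
  fallback <- paste0(superfamily, "-like")
  out <- list(label = fallback, nearest = names(panel)[nearest],
              nearest_distance = unname(qd[nearest]))
  if (qd[nearest] > radius) return(out)
  ## references tied at the nearest distance with conflicting labels are
  ## unresolvable: fall back
  near_tie <- which(qd <= qd[nearest] + 1e-9)
  if (length(unique(labels[near_tie])) > 1L) return(out)
  if (length(panel) < 2L) { out$label <- labels[nearest]; return(out) }
  seqs <- c(panel, query = query)
  tr <- nj_tree(distance_matrix(seqs))
  ## root at the reference farthest from the query so that the query sits
  ## nested and its ancestors trace progressively larger enclosing clades
  tr <- ape::root(tr, outgroup = names(panel)[which.max(qd)],
                  resolve.root = TRUE)
  qtip <- which(tr$tip.label == "query")
  anc <- integer()
  node <- qtip
  repeat {
    e <- which(tr$edge[, 2] == node)
    if (!length(e)) break
    node <- tr$edge[e, 1]
    anc <- c(anc, node)
  }
  for (a in anc) {
    tips <- ape::extract.clade(tr, a)$tip.label
    refs <- setdiff(tips, "query")
    if (!length(refs)) next
    lab <- unique(labels[match(refs, names(panel))])
    if (length(lab) == 1L) out$label <- lab
    break
  }
  out
}

#' Activity-clade prediction for hirudins
#'
#' k-nearest-neighbour vote over labelled reference hirudins using
#' global-alignment similarity distances. A tie, or a nearest reference
#' farther than `radius`, gives `"unknown"`.
#'
#' @param query hirudin protein sequence.
#' @param references named character vector of reference proteins.
#' @param labels `"active"`/`"inactive"` labels parallel to `references`.
#' @param k number of neighbours (default 3).
#' @param radius maximum distance of the nearest reference.
#' @return `"active"`, `"inactive"` or `"unknown"`.
#' @export
activity_clade <- function(query, references, labels, k = 3L, radius = 0.6) {
  stopifnot(length(references) == length(labels))
  if (length(references) < 3L)
    stop("need at least 3 labelled reference hirudins", call. = FALSE)
  d <- vapply(references, function(p) protein_distance(query, p), numeric(1))
  if (min(d) > radius) return("unknown")
  k <- min(k, length(d))
  nn <- order(d)[seq_len(k)]
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) != 1L) "unknown" else top
}
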