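# Alignment-free proteome phylogeny: average-common-substring (ACS)
# lengths, the corrected symmetrized ARS distance, neighbor joining, and
# a permutation test relating tree structure to per-virus flags.
#
# A proteome is a character vector of uppercase amino-acid sequences;
# a proteome set is a named list of proteomes (names = virus ids).
# Substring matching never crosses protein boundaries: proteins are
# concatenated with sentinel characters distinct between the query and
# subject sides, and ambiguous residues (X/B/Z) are replaced by
# side-specific sentinels so they never match.

prep_proteome <- function(p, side = c("query", "subject")) {
  side <- match.arg(side)
  p <- toupper(p)
  amb <- if (side == "query") "!" else "?"
  bound <- if (side == "query") "#" else "@"
  p <- gsub("[XBZ*]", amb, p)
  paste(p, collapse = bound)
}

#' Average common-substring length between two proteomes
#'
#' For every residue position i of proteome A, take the length of the
#' longest substring starting at i that occurs anywhere in proteome B
#' (within a single protein; matches never cross protein boundaries);
#' positions with no match contribute 0 (set `drop_unmatched = TRUE` to
#' exclude them from the mean instead). The result is the mean over all
#' positions of A.
#'
#' @param a,b Character vectors of amino-acid sequences (proteomes).
#' @param drop_unmatched Exclude zero-match positions from the mean
#'   (default `FALSE`).
#' @return A single non-negative number.
#' @export
acs_length <- function(a, b, drop_unmatched = FALSE) {
  if (length(a) == 0 || length(b) == 0) abort("empty proteome")
  qa <- prep_proteome(a, "query")
  sb <- prep_proteome(b, "subject")
  na <- nchar(qa); nb <- nchar(sb)
  # every residue position of A counts, ambiguous ones contribute 0;
  # only the protein-boundary sentinels are excluded
  pos <- which(strsplit(qa, "")[[1]] != "#")
  lens <- integer(na)  # indexed by position in qa
  active <- pos
  l <- 0L
  while (length(active) > 0 && l < nb) {
    l <- l + 1L
    ok <- active + l - 1L <= na
    active <- active[ok]
    if (length(active) == 0) break
    subs <- substring(qa, active, active + l - 1L)
    bsubs <- unique(substring(sb, seq_len(nb - l + 1L),
                              seq_len(nb - l + 1L) + l - 1L))
    hit <- subs %in% bsubs
    lens[active[hit]] <- l
    active <- active[hit]
  }
  vals <- lens[pos]
  if (drop_unmatched) {
    vals <- vals[vals > 0]
    if (length(vals) == 0) return(0)
  }
  mean(vals)
}

#' Corrected, symmetrized average-common-substring distance
#'
#' The alignment-free distance between proteomes:
#' `d'(A -> B) = log(|B|) / L(A,B) - log(|A|) / L(A,A)` and
#' `d(A,B) = (d'(A -> B) + d'(B -> A)) / 2`, with `|.|` the total
#' residue count, natural logarithms, and `L` from [acs_length()]
#' (including the self term, which is computed, not assumed).
#' Identical proteomes have distance 0. If `L(A,B) = 0` the distance is
#' infinite and reported as `NA` with a warning.
#'
#' @param a,b Character vectors of amino-acid sequences.
#' @return A single number (`NA` when the proteomes share no substring).
#' @export
ars_distance <- function(a, b) {
  la_b <- acs_length(a, b)
  lb_a <- acs_length(b, a)
  if (la_b == 0 || lb_a == 0) {
    warn("proteomes share no common substring; distance undefined")
    return(NA_real_)
  }
  na <- sum(nchar(a)); nb <- sum(nchar(b))
  d_ab <- base::log(nb) / la_b - base::log(na) / acs_length(a, a)
  d_ba <- base::log(na) / lb_a - base::log(nb) / acs_length(b, b)
  (d_ab + d_ba) / 2
}

#' Pairwise ARS distance matrix of a proteome set
#'
#' @param proteomes Named list of proteomes (character vectors of
#'   amino-acid sequences).
#' @return A symmetric numeric matrix with zero diagonal; small negative
#'   values from the correction term are clipped to 0 with a message.
#' @export
ars_distance_matrix <- function(proteomes) {
  ids <- names(proteomes)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("proteomes must be a uniquely named list")
  }
  n <- length(proteomes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- ars_distance(proteomes[[i]], proteomes[[j]])
    }
  }
  neg <- d < 0 & !is.na(d)
  if (any(neg)) {
    inform(sprintf("%d negative distance(s) clipped to 0 (max deficit %.3g)",
                   sum(neg) / 2, -min(d[neg])))
    d[neg] <- 0
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining on a complete symmetric
#' distance matrix; negative branch lengths are clipped to 0 with a
#' message reporting the total deficit.
#'
#' @param d Symmetric numeric matrix (>= 3 taxa) with dimnames.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  if (anyNA(d) || any(!is.finite(d))) {
    abort("distance matrix has missing or infinite entries")
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("%d negative branch length(s) clipped to 0 (deficit %.3g)",
                   sum(neg), -sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Association between tree structure and per-virus flags
#'
#' Tests whether flagged taxa cluster on the tree: the statistic is the
#' mean patristic (branch-length) distance within the flagged group,
#' compared to a null built by shuffling the flags over the leaves.
#' Small p-values indicate the flagged taxa sit closer together on the
#' tree than random leaf sets of the same size.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param flags Named logical vector covering the leaf set.
#' @param n_perm Number of flag permutations (default 1000).
#' @param seed Integer seed.
#' @return A list with `statistic` (observed mean within-group
#'   patristic distance), `p_value`, `null` (permuted statistics) and
#'   `n_flagged`.
#' @export
tree_flag_association <- function(tree, flags, n_perm = 1000, seed = 1) {
  tips <- tree$tip.label
  if (!all(tips %in% names(flags))) {
    abort("flags must cover every leaf of the tree")
  }
  fl <- as.logical(flags[tips])
  if (sum(fl) < 2) abort("need at least 2 flagged leaves")
  pd <- ape::cophenetic.phylo(tree)
  within_mean <- function(f) {
    sub <- pd[f, f]
    mean(sub[upper.tri(sub)])
  }
  obs <- within_mean(fl)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) within_mean(sample(fl)),
           numeric(1))
  })
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  list(statistic = obs, p_value = p, null = null, n_flagged = sum(fl))
}

#' Read a proteome from a protein FASTA file
#'
#' @param path Path to a protein FASTA file.
#' @return A character vector of uppercase amino-acid sequences, named
#'   by the header token before the first whitespace.
#' @export
read_proteome_fasta <- function(path) {
  recs <- Biostrings::readAAStringSet(path)
  if (length(recs) == 0) abort(sprintf("no FASTA records in '%s'", path))
  out <- toupper(as.character(recs))
  names(out) <- sub("\\s.*$", "", names(recs))
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(d, path) {
  d <- as.matrix(d)
  lines <- c(
    sprintf("%5d", nrow(d)),
    vapply(seq_len(nrow(d)), function(i) {
      paste0(formatC(rownames(d)[i], width = -10),
             paste(sprintf("%.6f", d[i, ]), collapse = "  "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
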