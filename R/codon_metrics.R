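# Per-gene and per-virus sequence composition statistics: RSCF/RSCU,
# amino-acid frequencies, ENC, GC content, codon-pair bias, dinucleotide
# bias, nucleotide and amino-acid entropy biases.
#
# Ambiguity policy (global): any in-frame triplet containing a non-ACGT
# symbol is excluded from codon-level counts; the terminal stop codon is
# always excluded; internal stop codons are excluded from the 61 sense
# counts (a warning was already raised at read time).

# in-frame sense codons of one CDS, after the ambiguity/stop policy;
# positions of excluded codons are NA so adjacency can be tracked
countable_codons <- function(seq) {
  cods <- split_codons(seq)
  if (length(cods) == 0) return(character(0))
  if (cods[length(cods)] %in% .STOP_CODONS) cods <- cods[-length(cods)]
  cods[!cods %in% .SENSE_CODONS] <- NA_character_
  cods
}

# 61-long named integer count vector for one CDS
codon_count_vec <- function(seq) {
  cods <- countable_codons(seq)
  tab <- table(factor(cods[!is.na(cods)], levels = .SENSE_CODONS))
  setNames(as.integer(tab), .SENSE_CODONS)
}

#' Count in-frame codons per gene
#'
#' Counts non-overlapping in-frame triplets over the 61 sense codons.
#' The terminal stop codon and any triplet containing a non-ACGT symbol
#' are excluded.
#'
#' @param genes A gene table.
#' @param drop_zero Drop codon/gene combinations with zero count
#'   (default `TRUE`).
#' @return A long tibble with columns `gene_id`, `codon`, `count`.
#' @examples
#' g <- new_gene_table("g1", "v", "ATGGGCGGC")
#' codon_counts(g)
#' @export
codon_counts <- function(genes, drop_zero = TRUE) {
  out <- purrr::map2_dfr(genes$gene_id, genes$seq, function(id, s) {
    v <- codon_count_vec(s)
    tibble::tibble(gene_id = id, codon = names(v), count = unname(v))
  })
  if (drop_zero) out <- dplyr::filter(out, .data$count > 0)
  out
}

# gene x 61 count matrix (rows named by gene_id)
codon_count_matrix <- function(genes) {
  m <- t(vapply(genes$seq, codon_count_vec, integer(length(.SENSE_CODONS)),
                USE.NAMES = FALSE))
  rownames(m) <- genes$gene_id
  colnames(m) <- .SENSE_CODONS
  m
}

#' Relative synonymous codon frequencies (RSCF)
#'
#' Represents each gene as a 61-dimensional vector: each sense codon's
#' count divided by the total count of its synonymous family in that
#' gene. Within every amino-acid family present in a gene the entries sum
#' to 1. Families whose amino acid is absent from the gene take the fill
#' value (default 0, keeping the vector a pure frequency readout;
#' `fill = "uniform"` uses 1/degeneracy instead).
#'
#' @param genes A gene table.
#' @param fill Value for codons of absent amino acids: `0` or `"uniform"`.
#' @return A wide tibble: `gene_id`, `virus_id`, `label`, then one column
#'   per sense codon in canonical order.
#' @export
rscf <- function(genes, fill = 0) {
  m <- codon_count_matrix(genes)
  fam_tot <- t(apply(m, 1, function(v) tapply(v, .CODON_AA, sum)[.CODON_AA]))
  r <- m / fam_tot
  if (identical(fill, "uniform")) {
    fill_vals <- matrix(1 / .FAMILY_SIZE, nrow(m), ncol(m), byrow = TRUE)
  } else {
    stopifnot(is.numeric(fill), length(fill) == 1)
    fill_vals <- matrix(fill, nrow(m), ncol(m))
  }
  absent <- fam_tot == 0
  r[absent] <- fill_vals[absent]
  zero_genes <- rowSums(m) == 0
  if (any(zero_genes)) {
    abort(sprintf("gene(s) with zero countable codons: %s",
                  paste(head(rownames(m)[zero_genes], 5), collapse = ", ")))
  }
  dplyr::bind_cols(
    genes[c("gene_id", "virus_id", "label")],
    tibble::as_tibble(r)
  )
}

#' Relative synonymous codon usage (RSCU)
#'
#' Classical alternative normalization: observed count over the expected
#' count under within-family uniformity (RSCF times family size).
#' Provided as an optional alternative representation; the package's
#' analyses default to RSCF.
#'
#' @inheritParams rscf
#' @return A wide tibble shaped like [rscf()].
#' @export
rscu <- function(genes, fill = 0) {
  r <- rscf(genes, fill = fill)
  r[.SENSE_CODONS] <- sweep(as.matrix(r[.SENSE_CODONS]), 2, .FAMILY_SIZE, `*`)
  r
}

#' Amino-acid frequencies per gene
#'
#' Frequencies of the 20 amino acids over a gene's countable codons;
#' entries sum to 1 for every gene.
#'
#' @param genes A gene table.
#' @return A wide tibble: `gene_id`, `virus_id`, `label`, then one column
#'   per amino acid (one-letter code, alphabetical).
#' @export
aa_frequencies <- function(genes) {
  m <- codon_count_matrix(genes)
  if (any(rowSums(m) == 0)) abort("gene(s) with zero countable codons")
  aam <- t(apply(m, 1, function(v) tapply(v, .CODON_AA, sum)[.AA_LEVELS]))
  colnames(aam) <- .AA_LEVELS
  aam <- aam / rowSums(aam)
  dplyr::bind_cols(
    genes[c("gene_id", "virus_id", "label")],
    tibble::as_tibble(aam)
  )
}

# Wright's F for one synonymous family: counts -> F (NA if not computable)
wright_f <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  if (f == 0) return(NA_real_)
  f
}

# ENC from a 61-long codon count vector
enc_from_counts <- function(cv) {
  fams <- split(cv, .CODON_AA[names(cv)])
  degs <- vapply(fams, length, integer(1))
  fvals <- vapply(fams, wright_f, numeric(1))
  class_means <- vapply(c(2L, 3L, 4L, 6L), function(d) {
    x <- fvals[degs == d]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  names(class_means) <- c("F2", "F3", "F4", "F6")
  # Wright's substitution for the lone 3-fold family (Ile)
  if (is.na(class_means["F3"]) &&
      !is.na(class_means["F2"]) && !is.na(class_means["F4"])) {
    class_means["F3"] <- mean(class_means[c("F2", "F4")])
  }
  n_aa <- c(F2 = 9, F3 = 1, F4 = 5, F6 = 3)      # amino acids per class
  n_codons <- c(F2 = 18, F3 = 3, F4 = 20, F6 = 18) # codons per class
  avail <- !is.na(class_means)
  if (!any(avail)) return(NA_real_)
  enc <- 2 + sum(n_aa[avail] / class_means[avail])
  if (!all(avail)) {
    # a whole degeneracy class unobserved: drop its term and rescale
    enc <- enc * 61 / (61 - sum(n_codons[!avail]))
  }
  min(enc, 61)
}

#' Effective number of codons (ENC)
#'
#' Wright's statistic: how far a gene's synonymous codon usage departs
#' from uniform usage, from 20 (one codon per amino acid) to 61 (uniform
#' within every family). Computed as
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` averages, over
#' k-fold families with at least two observed codons,
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`. Families with fewer than two
#' codons or `F = 0` are excluded; a missing 3-fold class is estimated as
#' the mean of the 2- and 4-fold classes; any other missing class drops
#' its term with rescaling. The result is capped at 61 and is `NA` when
#' no family is computable. Genes shorter than 100 codons are flagged.
#'
#' @param genes A gene table.
#' @return A tibble with columns `gene_id`, `enc`, `short_gene`.
#' @export
enc <- function(genes) {
  m <- codon_count_matrix(genes)
  tibble::tibble(
    gene_id = genes$gene_id,
    enc = unname(apply(m, 1, enc_from_counts)),
    short_gene = unname(rowSums(m) < 100)
  )
}

#' GC content of nucleotide sequences
#'
#' Fraction of G and C among unambiguous bases; non-ACGT symbols are
#' excluded from numerator and denominator.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- sanitize_seq(seq)
  counts <- function(s, chars) {
    sum(stringr::str_count(s, stringr::fixed(chars)))
  }
  out <- vapply(seq, function(s) {
    gcn <- counts(s, "G") + counts(s, "C")
    acgt <- counts(s, "A") + counts(s, "T") + gcn
    if (acgt == 0) abort("sequence has no unambiguous A/C/G/T bases")
    gcn / acgt
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Normalized Shannon entropy of a frequency vector
#'
#' `H = -sum(p * log(p)) / log(alphabet_size)`, with `0 * log(0) = 0`;
#' equals 1 for the uniform distribution and 0 for a degenerate one.
#' Applied to nucleotide frequencies this is the nucleotide bias (NTB),
#' to amino-acid frequencies the amino-acid bias (AAB).
#'
#' @param freqs Non-negative frequencies summing to 1.
#' @param alphabet_size Size of the underlying alphabet (defaults to
#'   `length(freqs)`; use 4 for nucleotides, 20 for amino acids).
#' @return A fraction in `[0, 1]`.
#' @export
entropy_bias <- function(freqs, alphabet_size = length(freqs)) {
  if (any(freqs < 0)) abort("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-6) abort("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  -sum(p * log(p)) / log(alphabet_size)
}

# pooled mononucleotide frequencies over ACGT positions of many genes
nucleotide_freqs <- function(seqs) {
  counts <- vapply(.BASES, function(b) {
    sum(stringr::str_count(seqs, stringr::fixed(b)))
  }, numeric(1))
  if (sum(counts) == 0) abort("no unambiguous bases")
  counts / sum(counts)
}

# valid (sense, unambiguous) codon runs of each gene with adjacency kept
pooled_codon_pairs <- function(genes) {
  pair1 <- character(0); pair2 <- character(0)
  singles <- character(0)
  for (s in genes$seq) {
    cods <- countable_codons(s)
    ok <- !is.na(cods)
    singles <- c(singles, cods[ok])
    if (length(cods) >= 2) {
      i <- which(ok[-length(ok)] & ok[-1])
      pair1 <- c(pair1, cods[i])
      pair2 <- c(pair2, cods[i + 1])
    }
  }
  list(singles = singles, pair1 = pair1, pair2 = pair2)
}

#' Codon-pair scores (CPS) for a gene collection
#'
#' For each adjacent in-frame codon pair `(A, B)` encoding amino acids
#' `(X, Y)`, the score is the log ratio of observed to expected pair
#' occurrences, corrected for amino-acid pairing:
#' `CPS(AB) = ln( N(AB) * N(X) * N(Y) / (N(A) * N(B) * N(XY)) )`.
#' Counts are pooled over all genes; pairs spanning a dropped or
#' ambiguous codon are excluded; pairs with zero observed count have no
#' score; a zero denominator leaves the pair unscored (`NA`).
#'
#' @param genes A gene table.
#' @return A tibble with columns `codon1`, `codon2`, `n` (observed
#'   occurrences) and `cps`.
#' @export
cps_table <- function(genes) {
  pp <- pooled_codon_pairs(genes)
  if (length(pp$pair1) == 0) abort("no adjacent codon pairs in input")
  n_codon <- table(pp$singles)
  n_aa <- table(.CODON_AA[pp$singles])
  pair_key <- paste(pp$pair1, pp$pair2)
  n_pair <- table(pair_key)
  aa_pair_key <- paste(.CODON_AA[pp$pair1], .CODON_AA[pp$pair2])
  n_aapair <- table(aa_pair_key)

  keys <- names(n_pair)
  c1 <- sub(" .*", "", keys)
  c2 <- sub(".* ", "", keys)
  x <- unname(.CODON_AA[c1]); y <- unname(.CODON_AA[c2])
  expected <- as.numeric(n_codon[c1]) * as.numeric(n_codon[c2]) /
    (as.numeric(n_aa[x]) * as.numeric(n_aa[y])) *
    as.numeric(n_aapair[paste(x, y)])
  cps <- ifelse(expected > 0, log(as.numeric(n_pair) / expected), NA_real_)
  tibble::tibble(codon1 = c1, codon2 = c2,
                 n = as.integer(n_pair), cps = cps) |>
    dplyr::arrange(.data$codon1, .data$codon2)
}

#' Codon-pair bias (CPB)
#'
#' Mean codon-pair score over codon-pair occurrences pooled across all
#' genes. With `weighting = "occurrence"` (default) each adjacent pair
#' occurrence contributes its pair's CPS once; `"distinct"` averages
#' over distinct scored pairs instead.
#'
#' @param genes A gene table.
#' @param weighting `"occurrence"` or `"distinct"`.
#' @return A single numeric value.
#' @export
cpb <- function(genes, weighting = c("occurrence", "distinct")) {
  weighting <- match.arg(weighting)
  tab <- cps_table(genes)
  tab <- tab[!is.na(tab$cps), ]
  if (nrow(tab) == 0) abort("no scored codon pairs")
  if (weighting == "occurrence") {
    sum(tab$n * tab$cps) / sum(tab$n)
  } else {
    mean(tab$cps)
  }
}

#' Dinucleotide scores (DNTS) for a gene collection
#'
#' For each dinucleotide `xy`, the observed over expected ratio
#' `f(xy) / (f(x) * f(y))`, where `f(xy)` is the pooled frequency of
#' overlapping adjacent pairs within genes (never across gene
#' boundaries) and `f(x)` the pooled mononucleotide frequency. Pairs
#' containing an ambiguous base are excluded. Counting is on the coding
#' strand with no distinction of reading-frame position.
#'
#' @param genes A gene table.
#' @return A tibble with columns `dinucleotide`, `n`, `dnts`.
#' @export
dnts <- function(genes) {
  seqs <- sanitize_seq(genes$seq)
  if (sum(nchar(seqs)) < 2) abort("total sequence length below 2")
  f1 <- nucleotide_freqs(seqs)
  dints <- as.vector(outer(.BASES, .BASES, paste0))
  counts <- vapply(dints, function(d) {
    # overlapping occurrences: count at shifted offsets
    sum(stringr::str_count(seqs, paste0("(?=", d, ")")))
  }, numeric(1))
  total <- sum(counts)
  if (total == 0) abort("no unambiguous dinucleotides")
  f2 <- counts / total
  expected <- f1[substr(dints, 1, 1)] * f1[substr(dints, 2, 2)]
  tibble::tibble(
    dinucleotide = dints,
    n = as.integer(counts),
    dnts = unname(ifelse(expected > 0, f2 / expected, NA_real_))
  )
}

#' Dinucleotide bias (DNTB)
#'
#' Mean dinucleotide score over adjacent dinucleotide occurrences pooled
#' across all genes (occurrence-weighted by default; `"distinct"`
#' averages over scored dinucleotide types).
#'
#' @inheritParams cpb
#' @return A single numeric value.
#' @export
dntb <- function(genes, weighting = c("occurrence", "distinct")) {
  weighting <- match.arg(weighting)
  tab <- dnts(genes)
  tab <- tab[!is.na(tab$dnts) & tab$n > 0, ]
  if (nrow(tab) == 0) abort("no scored dinucleotides")
  if (weighting == "occurrence") {
    sum(tab$n * tab$dnts) / sum(tab$n)
  } else {
    mean(tab$dnts)
  }
}

#' Per-gene genomic feature table
#'
#' One row per gene with the compositional features used throughout the
#' package: codon length, GC content, ENC, nucleotide bias (NTB,
#' normalized nucleotide entropy), amino-acid bias (AAB, normalized
#' amino-acid entropy), and optionally tAI and MTDR when weights or a
#' decoding-rate table are supplied.
#'
#' @param genes A gene table.
#' @param tai_weights Optional tAI weight table from
#'   [normalize_weights()] or [host_adjusted_tai()].
#' @param tdr Optional TDR table from [tdr_table()].
#' @return A tibble with one row per gene.
#' @export
gene_features <- function(genes, tai_weights = NULL, tdr = NULL) {
  m <- codon_count_matrix(genes)
  ntb <- vapply(genes$seq, function(s) {
    entropy_bias(nucleotide_freqs(sanitize_seq(s)), 4)
  }, numeric(1), USE.NAMES = FALSE)
  aam <- as.matrix(aa_frequencies(genes)[.AA_LEVELS])
  aab <- apply(aam, 1, entropy_bias, alphabet_size = 20)
  out <- tibble::tibble(
    gene_id = genes$gene_id,
    virus_id = genes$virus_id,
    label = genes$label,
    length_codons = unname(rowSums(m)),
    gc = gc_content(genes$seq),
    enc = unname(apply(m, 1, enc_from_counts)),
    ntb = ntb,
    aab = aab
  )
  if (!is.null(tai_weights)) {
    out$tai <- tai_of_gene(genes, tai_weights)$tai
  }
  if (!is.null(tdr)) {
    out$mtdr <- mtdr(genes, tdr)$mtdr
  }
  out
}

#' Pooled per-virus (or per temporal group) feature table
#'
#' Pools codon and nucleotide counts over genes and reports virus-level
#' features: total coding length, ENC of the pooled codon counts, CPB,
#' DNTB, GC, NTB and AAB.
#'
#' @param genes A gene table (one or more viruses).
#' @param by_label Also split by temporal label (default `FALSE`).
#' @return A tibble with one row per virus (times label if requested).
#' @export
virus_features <- function(genes, by_label = FALSE) {
  keys <- if (by_label) c("virus_id", "label") else "virus_id"
  genes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      cv <- colSums(codon_count_matrix(g))
      aa <- tapply(cv, .CODON_AA, sum)[.AA_LEVELS]
      tibble::tibble(
        n_genes = nrow(g),
        coding_length = sum(nchar(g$seq)),
        enc = enc_from_counts(cv),
        cpb = cpb(g),
        dntb = dntb(g),
        gc = gc_content(paste(g$seq, collapse = "")),
        ntb = entropy_bias(nucleotide_freqs(sanitize_seq(g$seq)), 4),
        aab = entropy_bias(aa / sum(aa), 20)
      )
    }) |>
    dplyr::ungroup()
}
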