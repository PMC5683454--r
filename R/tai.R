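# tRNA adaptation index against a host tRNA pool, with wobble-interaction
# penalties adjusted by correlation optimization instead of expression data.
#
# The codon-anticodon pairing table is generated from the rule that a
# wobble anticodon is admissible only when its Watson-Crick codon encodes
# the same amino acid as the target codon (which keeps pairings inside a
# codon box and automatically excludes Met/Trp cross-reading), plus the
# bacterial lysidine special case (modified C34 reading AUA/Ile).

.WOBBLE_CLASSES <- c("WC", "GU", "IC", "IA", "UG", "LA")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Codon-anticodon pairing table
#'
#' All recognized codon-anticodon pairings for the tAI weight
#' computation: Watson-Crick (class `WC`) plus the standard wobble
#' classes `GU` (G34:U3), `IC` (inosine:C), `IA` (inosine:A), `UG`
#' (U34:G3), and for bacteria `LA` (lysidine-modified C34 reading the
#' AUA isoleucine codon). Anticodons are written 5'->3' in the DNA
#' alphabet; the first anticodon base is the wobble position.
#'
#' @param domain `"bacteria"` or `"eukaryote"`; switches the eligible
#'   pairing classes (lysidine is bacterial only).
#' @return A tibble with columns `codon`, `anticodon`, `class`.
#' @export
wobble_pairing_table <- function(domain = c("bacteria", "eukaryote")) {
  domain <- match.arg(domain)
  rows <- list()
  for (cod in .SENSE_CODONS) {
    c1 <- substr(cod, 1, 1); c2 <- substr(cod, 2, 2); c3 <- substr(cod, 3, 3)
    stem <- paste0(comp_base(c2), comp_base(c1))
    rows[[length(rows) + 1L]] <-
      tibble::tibble(codon = cod, anticodon = revcomp(cod), class = "WC")
    wob <- switch(c3,
      T = c("G", "GU"),
      C = c("A", "IC"),
      A = c("A", "IA"),
      G = c("T", "UG")
    )
    anticodon <- paste0(wob[1], stem)
    wc_codon <- revcomp(anticodon)
    if (wc_codon %in% .SENSE_CODONS &&
        .CODON_AA[[wc_codon]] == .CODON_AA[[cod]]) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(codon = cod, anticodon = anticodon, class = wob[2])
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (domain == "bacteria") {
    tab <- dplyr::bind_rows(
      tab,
      tibble::tibble(codon = "ATA", anticodon = "CAT", class = "LA")
    )
  }
  tab
}

#' Default wobble penalties
#'
#' The published selective-constraint values for prokaryotic tAI:
#' Watson-Crick pairings are fixed at 0; wobble classes carry the
#' standard penalties (`GU` 0.41, `IC` 0.28, `IA` 0.9999, `UG` 0.68,
#' `LA` 0.89).
#'
#' @return A named numeric vector over pairing classes, each in `[0, 1]`.
#' @export
default_wobble_penalties <- function() {
  c(WC = 0, GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68, LA = 0.89)
}

check_penalties <- function(s) {
  if (!all(.WOBBLE_CLASSES %in% names(s))) {
    abort(sprintf("penalties must name classes: %s",
                  paste(.WOBBLE_CLASSES, collapse = ", ")))
  }
  if (any(s < 0 | s > 1)) abort("each penalty must lie in [0, 1]")
  if (s[["WC"]] != 0) abort("Watson-Crick penalty is fixed at 0")
  invisible(s)
}

#' Read a tRNA pool table
#'
#' Two-column delimited text `anticodon,copies` (DNA alphabet, 5'->3').
#'
#' @param path Path to the file.
#' @return A tibble with columns `anticodon`, `copies`.
#' @export
read_trna_pool <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  pool <- tibble::tibble(anticodon = sanitize_seq(as.character(tab$anticodon)),
                         copies = as.integer(tab$copies))
  check_trna_pool(pool)
  pool
}

check_trna_pool <- function(pool) {
  if (!all(c("anticodon", "copies") %in% names(pool))) {
    abort("tRNA pool needs columns anticodon, copies")
  }
  if (!all(grepl("^[ACGT]{3}$", pool$anticodon))) {
    abort("anticodons must be ACGT triplets")
  }
  if (any(pool$copies < 0) || sum(pool$copies) == 0) {
    abort("tRNA pool needs non-negative copies with at least one nonzero")
  }
  invisible(pool)
}

#' Absolute tAI weights from a tRNA pool
#'
#' `W(codon) = sum over cognate anticodons of (1 - s_class) * copies`,
#' using the pairing table of [wobble_pairing_table()].
#'
#' @param pool A tRNA pool tibble (`anticodon`, `copies`).
#' @param s Named penalty vector (see [default_wobble_penalties()]).
#' @param domain `"bacteria"` or `"eukaryote"`.
#' @return A tibble with columns `codon`, `W` (61 rows, canonical order).
#' @export
absolute_weights <- function(pool, s = default_wobble_penalties(),
                             domain = c("bacteria", "eukaryote")) {
  domain <- match.arg(domain)
  check_trna_pool(pool)
  check_penalties(s)
  tab <- wobble_pairing_table(domain)
  tab$copies <- pool$copies[match(tab$anticodon, pool$anticodon)]
  tab$copies[is.na(tab$copies)] <- 0L
  tab$contrib <- (1 - s[tab$class]) * tab$copies
  w <- tapply(tab$contrib, factor(tab$codon, levels = .SENSE_CODONS), sum)
  tibble::tibble(codon = .SENSE_CODONS, W = as.numeric(w))
}

#' Normalize absolute weights to relative adaptiveness
#'
#' `w = W / max(W)`; codons with `W = 0` are imputed with the geometric
#' mean of the nonzero relative weights so the downstream geometric mean
#' stays defined.
#'
#' @param W Tibble from [absolute_weights()] (columns `codon`, `W`).
#' @return A tibble with columns `codon`, `w`, each `w` in `(0, 1]`.
#' @export
normalize_weights <- function(W) {
  if (all(W$W == 0)) abort("all absolute weights are zero")
  w <- W$W / max(W$W)
  nz <- w > 0
  w[!nz] <- exp(mean(log(w[nz])))
  tibble::tibble(codon = W$codon, w = w)
}

#' tRNA adaptation index of genes
#'
#' Geometric mean of the per-codon relative adaptiveness over each
#' gene's countable codons:
#' `tAI = exp(mean(log(w(codon_k))))`.
#'
#' @param genes A gene table.
#' @param weights Tibble from [normalize_weights()] (columns `codon`, `w`).
#' @return A tibble with columns `gene_id`, `tai`.
#' @export
tai_of_gene <- function(genes, weights) {
  wv <- setNames(weights$w, weights$codon)
  tibble::tibble(
    gene_id = genes$gene_id,
    tai = vapply(genes$seq, function(s) {
      cods <- countable_codons(s)
      cods <- cods[!is.na(cods)]
      if (length(cods) == 0) return(NA_real_)
      exp(mean(log(wv[cods])))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Directional codon-usage bias score per gene
#'
#' A per-gene scalar codon-bias measure used as the default objective of
#' the wobble-penalty optimization: the mean, over a gene's codon
#' occurrences, of the ratio of the codon's frequency to the product of
#' its positional nucleotide frequencies within that gene. Values above
#' 1 indicate codon choices more concentrated than their nucleotide
#' composition explains.
#'
#' Note: this objective is a documented stand-in for the
#' expression-free calibration measure, which is not restated in the
#' sources available to this package; ENC (negated) and an RSCU-based
#' score are available as alternatives in [optimize_penalties()].
#'
#' @param genes A gene table.
#' @return A tibble with columns `gene_id`, `bias`.
#' @export
directional_codon_bias <- function(genes) {
  tibble::tibble(
    gene_id = genes$gene_id,
    bias = vapply(genes$seq, function(s) {
      cods <- countable_codons(s)
      cods <- cods[!is.na(cods)]
      if (length(cods) == 0) return(NA_real_)
      L <- length(cods)
      fc <- table(cods) / L
      pos_freq <- lapply(1:3, function(i) {
        table(factor(substr(cods, i, i), levels = .BASES)) / L
      })
      expected <- as.numeric(pos_freq[[1]][substr(cods, 1, 1)]) *
        as.numeric(pos_freq[[2]][substr(cods, 2, 2)]) *
        as.numeric(pos_freq[[3]][substr(cods, 3, 3)])
      mean(as.numeric(fc[cods]) / expected)
    }, numeric(1), USE.NAMES = FALSE)
  )
}

# per-gene objective vector for the optimizer
tai_objective_values <- function(host_genes, objective) {
  switch(objective,
    directional = directional_codon_bias(host_genes)$bias,
    enc = -enc(host_genes)$enc,
    rscu = {
      r <- rscu(host_genes)
      m <- as.matrix(r[.SENSE_CODONS])
      cm <- codon_count_matrix(host_genes)
      rowSums(m * cm) / rowSums(cm)  # occurrence-weighted mean RSCU
    }
  )
}

#' Optimize wobble penalties against a codon-bias objective
#'
#' Calibrates the free s-values without gene expression data by
#' maximizing the Spearman correlation between per-gene tAI and a
#' per-gene codon-usage-bias objective over a host gene collection.
#' Coordinate ascent over the free classes on a fixed grid
#' (step `grid`), with `n_restarts` random restarts from a fixed seed;
#' deterministic given the seed.
#'
#' @param host_genes A gene table with at least 50 genes.
#' @param pool Host tRNA pool (`anticodon`, `copies`).
#' @param objective `"directional"` (default, see
#'   [directional_codon_bias()]), `"enc"` (negated ENC) or `"rscu"`.
#' @param domain `"bacteria"` or `"eukaryote"`.
#' @param free Pairing classes whose penalties are optimized; defaults
#'   to every wobble class present in the domain's pairing table.
#' @param grid Grid step for each s in `[0, 1]` (default 0.05).
#' @param n_restarts Random restarts (default 10).
#' @param seed Integer seed controlling the restarts.
#' @return An object of class `wobble_opt`: a list with `s` (full named
#'   penalty vector), `correlation` (achieved Spearman correlation),
#'   `objective`, and `n_genes`.
#' @export
optimize_penalties <- function(host_genes, pool,
                               objective = c("directional", "enc", "rscu"),
                               domain = c("bacteria", "eukaryote"),
                               free = NULL, grid = 0.05, n_restarts = 10,
                               seed = 1) {
  objective <- match.arg(objective)
  domain <- match.arg(domain)
  if (nrow(host_genes) < 50) {
    abort("penalty optimization needs at least 50 host genes")
  }
  obj <- tai_objective_values(host_genes, objective)
  if (sd(obj, na.rm = TRUE) == 0 || all(is.na(obj))) {
    abort("objective is constant across host genes; correlation undefined")
  }
  pairing <- wobble_pairing_table(domain)
  if (is.null(free)) free <- setdiff(unique(pairing$class), "WC")
  grid_vals <- seq(0, 1, by = grid)

  # precompute per-gene codon counts once; tAI ranking then only needs
  # the log-weight vector
  cm <- codon_count_matrix(host_genes)
  ctot <- rowSums(cm)
  score_fun <- function(s) {
    w <- normalize_weights(absolute_weights(pool, s, domain))
    tai <- exp(as.vector(cm %*% base::log(w$w)) / ctot)
    if (sd(tai, na.rm = TRUE) == 0) return(-Inf)
    suppressWarnings(cor(tai, obj, method = "spearman",
                         use = "complete.obs"))
  }

  base_s <- default_wobble_penalties()
  best <- list(s = base_s, score = -Inf)
  starts <- withr::with_seed(seed, {
    c(list(base_s), lapply(seq_len(max(0, n_restarts - 1)), function(i) {
      s <- base_s
      s[free] <- sample(grid_vals, length(free), replace = TRUE)
      s
    }))
  })
  for (s0 in starts) {
    s <- s0
    cur <- score_fun(s)
    repeat {
      improved <- FALSE
      for (cl in free) {
        trial_scores <- vapply(grid_vals, function(v) {
          st <- s; st[cl] <- v; score_fun(st)
        }, numeric(1))
        k <- which.max(trial_scores)
        if (trial_scores[k] > cur + 1e-12) {
          s[cl] <- grid_vals[k]
          cur <- trial_scores[k]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (cur > best$score) best <- list(s = s, score = cur)
  }
  if (!is.finite(best$score)) {
    warn("optimization did not improve from any start; returning best found")
  }
  structure(
    list(s = best$s, correlation = best$score, objective = objective,
         domain = domain, n_genes = nrow(host_genes)),
    class = "wobble_opt"
  )
}

#' @export
print.wobble_opt <- function(x, ...) {
  cat("Wobble-penalty optimization\n")
  cat(sprintf("  objective: %s over %d host genes (%s)\n",
              x$objective, x$n_genes, x$domain))
  cat(sprintf("  achieved Spearman correlation: %.3f\n", x$correlation))
  cat("  s:", paste(sprintf("%s=%.2f", names(x$s), x$s), collapse = " "), "\n")
  invisible(x)
}

#' Host-adjusted tAI weights in one step
#'
#' Optimizes the wobble penalties on host genes, then returns the
#' normalized per-codon weights for scoring viral genes.
#'
#' @inheritParams optimize_penalties
#' @return A tibble with columns `codon`, `w`, carrying the optimization
#'   result as attribute `"opt"`.
#' @export
host_adjusted_tai <- function(host_genes, pool,
                              objective = c("directional", "enc", "rscu"),
                              domain = c("bacteria", "eukaryote"), ...) {
  opt <- optimize_penalties(host_genes, pool, objective = objective,
                            domain = domain, ...)
  w <- normalize_weights(absolute_weights(pool, opt$s, opt$domain))
  attr(w, "opt") <- opt
  w
}
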