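# The core statistic: separation of early vs. late genes in synonymous
# codon (RSCF) or amino-acid frequency space, measured by the
# Davies-Bouldin score with a label-permutation null; PCA projection with
# a maximum-margin line for display; subsampling robustness; per-feature
# Wilcoxon comparisons.

# numeric matrix + early/late label vector from a labeled gene table
separation_points <- function(genes, space = c("rscf", "aa"), fill = 0) {
  space <- match.arg(space)
  genes <- genes[genes$label %in% .TEMPORAL_LABELS, ]
  check_temporal_groups(genes)
  wide <- if (space == "rscf") rscf(genes, fill = fill) else aa_frequencies(genes)
  cols <- if (space == "rscf") .SENSE_CODONS else .AA_LEVELS
  list(x = as.matrix(wide[cols]), labels = genes$label,
       gene_id = genes$gene_id, space = space)
}

#' Davies-Bouldin score for a two-group point set
#'
#' For two clusters, `DBS = (S_early + S_late) / M`, where `S_g` is the
#' mean Euclidean distance of group g's points to their centroid and `M`
#' the Euclidean distance between the two centroids. Smaller is better
#' separated; coincident centroids give `Inf` (non-separable).
#'
#' @param x Numeric matrix, one row per point.
#' @param labels Vector with exactly two distinct values, one per row.
#' @return A single numeric value (possibly `Inf`).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  groups <- unique(labels)
  if (length(groups) != 2) abort("exactly two groups required")
  i1 <- labels == groups[1]
  dbs_from_split(x, i1)
}

# internal fast path: logical index of group 1
dbs_from_split <- function(x, i1) {
  x1 <- x[i1, , drop = FALSE]
  x2 <- x[!i1, , drop = FALSE]
  c1 <- colMeans(x1); c2 <- colMeans(x2)
  s1 <- mean(sqrt(rowSums((x1 - rep(c1, each = nrow(x1)))^2)))
  s2 <- mean(sqrt(rowSums((x2 - rep(c2, each = nrow(x2)))^2)))
  m <- sqrt(sum((c1 - c2)^2))
  if (m == 0) return(Inf)
  (s1 + s2) / m
}

#' Permutation test of early/late separation
#'
#' Compares the observed Davies-Bouldin score to scores under random
#' permutations of the group labels (group sizes preserved). The
#' one-sided empirical p-value in the smaller-is-better-separated
#' direction uses the add-one correction:
#' `p = (1 + #\{DBS_perm <= DBS_obs\}) / (1 + n_perm)`.
#'
#' @param x Numeric matrix, one row per gene.
#' @param labels Two-valued label vector.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed; the test is deterministic given it.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `separation_test`: list with
#'   `dbs_observed`, `null_scores`, `p_value`, `n_permutations`,
#'   `significant`, `alpha`, `n_early`, `n_late`.
#' @export
dbs_permutation_test <- function(x, labels, n_perm = 1000, seed = 1,
                                 alpha = 0.05) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  x <- as.matrix(x)
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("exactly two groups required")
  i1 <- labels == groups[1]
  n <- length(labels); n1 <- sum(i1)
  obs <- dbs_from_split(x, i1)
  null_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n, n1)
      ii <- logical(n); ii[idx] <- TRUE
      dbs_from_split(x, ii)
    }, numeric(1))
  })
  p <- (1 + sum(null_scores <= obs)) / (1 + n_perm)
  structure(
    list(dbs_observed = obs, null_scores = null_scores, p_value = p,
         n_permutations = n_perm, significant = is.finite(obs) && p <= alpha,
         alpha = alpha, n_early = sum(labels == "early"),
         n_late = sum(labels == "late")),
    class = "separation_test"
  )
}

#' Test early/late separation of a labeled gene table
#'
#' The package's headline analysis for one virus: represent each labeled
#' gene in RSCF (61-dim) or amino-acid frequency (20-dim) space and run
#' the Davies-Bouldin permutation test. The returned object carries the
#' PCA projection and maximum-margin line for [autoplot.separation_test()].
#'
#' @param genes A labeled gene table (>= 2 genes per temporal group).
#' @param space `"rscf"` (synonymous codon space, default) or `"aa"`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @param fill RSCF fill policy for absent amino acids (see [rscf()]).
#' @param margin_line Also compute the maximum-margin display line in
#'   the PCA plane (default `FALSE`; [autoplot.separation_test()]
#'   derives it on demand).
#' @return A `separation_test` object (see [dbs_permutation_test()]),
#'   with elements `space`, `virus_id`, `pca` and `margin_line` added.
#' @examples
#' v <- synth_virus(synth_config(n_early = 10, n_late = 10, divergence = 0.8,
#'                               seed = 1))
#' st <- separation_test(v$genes, n_perm = 200, seed = 2)
#' glance(st)
#' @export
separation_test <- function(genes, space = c("rscf", "aa"), n_perm = 1000,
                            seed = 1, alpha = 0.05, fill = 0,
                            margin_line = FALSE) {
  pts <- separation_points(genes, space = space, fill = fill)
  st <- dbs_permutation_test(pts$x, pts$labels, n_perm = n_perm,
                             seed = seed, alpha = alpha)
  st$space <- pts$space
  st$virus_id <- paste(unique(genes$virus_id), collapse = "+")
  st$pca <- pca_project(pts$x, labels = pts$labels, gene_id = pts$gene_id)
  st$margin_line <- if (margin_line) {
    tryCatch(
      suppressWarnings(
        max_margin_line(st$pca$scores[c("pc1", "pc2")], pts$labels)
      ),
      error = function(e) NULL
    )
  } else NULL
  st
}

#' @export
print.separation_test <- function(x, ...) {
  cat("Early/late separation test",
      if (!is.null(x$space)) sprintf("(%s space)", toupper(x$space)), "\n")
  if (!is.null(x$virus_id)) cat(sprintf("  virus: %s\n", x$virus_id))
  cat(sprintf("  %d early vs %d late genes\n", x$n_early, x$n_late))
  cat(sprintf("  observed DBS: %.4f\n", x$dbs_observed))
  cat(sprintf("  permutation p-value: %.4g (%d permutations)%s\n",
              x$p_value, x$n_permutations,
              if (x$significant) "  *significant*" else ""))
  invisible(x)
}

#' @rdname separation_test
#' @param x A `separation_test` object.
#' @param ... Unused.
#' @export
glance.separation_test <- function(x, ...) {
  tibble::tibble(
    virus_id = x$virus_id %||% NA_character_,
    space = x$space %||% NA_character_,
    n_early = x$n_early, n_late = x$n_late,
    dbs = x$dbs_observed, p_value = x$p_value,
    n_permutations = x$n_permutations,
    significant = x$significant
  )
}

#' @rdname separation_test
#' @export
tidy.separation_test <- function(x, ...) {
  tibble::tibble(
    permutation = seq_len(x$n_permutations),
    dbs = x$null_scores
  )
}

#' PCA projection of a point set
#'
#' Mean-centered (not variance-scaled: RSCF entries share a scale)
#' projection onto the first two principal components, with
#' explained-variance fractions. With rank below 2 the second component
#' carries zero variance.
#'
#' @param x Numeric matrix with at least 3 rows.
#' @param labels,gene_id Optional per-row annotation columns.
#' @return A list with `scores` (tibble: `pc1`, `pc2`, plus annotation)
#'   and `var_explained` (length-2 fractions of total variance).
#' @export
pca_project <- function(x, labels = NULL, gene_id = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("PCA projection needs at least 3 points")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- ncol(pc$x)
  scores <- tibble::tibble(
    pc1 = pc$x[, 1],
    pc2 = if (k >= 2) pc$x[, 2] else rep(0, nrow(x))
  )
  if (!is.null(gene_id)) scores$gene_id <- gene_id
  if (!is.null(labels)) scores$label <- labels
  var_tot <- sum(pc$sdev^2)
  ve <- c(pc$sdev[1]^2, if (k >= 2) pc$sdev[2]^2 else 0) / var_tot
  list(scores = scores, var_explained = ve)
}

#' Maximum-margin separating line in the plane
#'
#' The line maximizing the Euclidean distance to the nearest point of
#' either group (hard-margin linear SVM, approximated with a very large
#' soft-margin penalty). If the groups are not linearly separable the
#' soft-margin solution is returned and flagged.
#'
#' @param coords Two-column numeric matrix or data frame.
#' @param labels Two-valued label vector.
#' @param cost Soft-margin penalty (default `1e6`, effectively hard).
#' @return A list with `a`, `b`, `c` (line `a*x + b*y + c = 0`, with
#'   `a^2 + b^2 = 1`), `margin` (distance to the nearest point) and
#'   `separable`.
#' @export
max_margin_line <- function(coords, labels, cost = 1e6) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("need points from both groups")
  y <- factor(labels, levels = groups)
  if (nrow(coords) == 2) {
    # perpendicular bisector of the two points
    d <- coords[2, ] - coords[1, ]
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) abort("coincident points")
    a <- d[1] / nrm; b <- d[2] / nrm
    mid <- colMeans(coords)
    cc <- -(a * mid[1] + b * mid[2])
    return(list(a = unname(a), b = unname(b), c = unname(cc),
                margin = nrm / 2, separable = TRUE))
  }
  fit <- e1071::svm(x = coords, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  wv <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  nrm <- sqrt(sum(wv^2))
  if (nrm < 1e-12) {
    # fully symmetric non-separable configuration (e.g. XOR)
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                margin = 0, separable = FALSE))
  }
  a <- wv[1] / nrm; b <- wv[2] / nrm; cc <- -rho / nrm
  signed <- (coords %*% c(a, b) + cc)
  side <- ifelse(y == groups[1], signed * sign(sum(signed[y == groups[1]])), 0)
  pred <- stats::predict(fit, coords)
  separable <- all(pred == y) && min(abs(signed)) > 0
  list(a = unname(a), b = unname(b), c = unname(cc),
       margin = min(abs(signed)), separable = separable)
}

#' Subsampling robustness of the separation signal
#'
#' Repeatedly samples `n_early` early and `n_late` late genes without
#' replacement (defaults 8 and 14, the sizes typical of human viruses),
#' reruns the permutation test on each subsample, and reports the
#' fraction of rounds significant at `alpha`.
#'
#' @param genes A labeled gene table with at least `n_early` early and
#'   `n_late` late genes.
#' @param n_early,n_late Genes sampled per group (defaults 8 and 14).
#' @param n_rounds Subsampling rounds (default 100).
#' @param n_perm Permutations per round (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @param space,fill Passed to the point construction (see
#'   [separation_test()]).
#' @return A list with `fraction_significant`, `rounds` (tibble of
#'   per-round DBS and p), and the sampling sizes.
#' @export
subsample_robustness <- function(genes, n_early = 8, n_late = 14,
                                 n_rounds = 100, n_perm = 1000, seed = 1,
                                 alpha = 0.05, space = "rscf", fill = 0) {
  pts <- separation_points(genes, space = space, fill = fill)
  idx_e <- which(pts$labels == "early")
  idx_l <- which(pts$labels == "late")
  if (length(idx_e) < n_early || length(idx_l) < n_late) {
    abort(sprintf(
      "need >= %d early and >= %d late genes; found %d early, %d late",
      n_early, n_late, length(idx_e), length(idx_l)
    ))
  }
  sub_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max, n_rounds)
  })
  rounds <- purrr::map_dfr(seq_len(n_rounds), function(r) {
    pick <- withr::with_seed(sub_seeds[r], {
      c(sample(idx_e, n_early), sample(idx_l, n_late))
    })
    st <- dbs_permutation_test(pts$x[pick, , drop = FALSE],
                               pts$labels[pick], n_perm = n_perm,
                               seed = sub_seeds[r], alpha = alpha)
    tibble::tibble(round = r, dbs = st$dbs_observed,
                   p_value = st$p_value, significant = st$significant)
  })
  list(fraction_significant = mean(rounds$significant),
       rounds = rounds, n_early = n_early, n_late = n_late,
       n_rounds = n_rounds, alpha = alpha)
}

#' Wilcoxon rank-sum comparison of a feature between temporal groups
#'
#' Two-sided rank-sum p-value plus a direction: +1 when the early-gene
#' mean exceeds the late-gene mean, -1 for the reverse, 0 on exact
#' equality. When every value is tied across both groups the p-value
#' is 1.
#'
#' @param values_early,values_late Numeric vectors (>= 2 values each).
#' @return A one-row tibble: `p_value`, `direction`, `mean_early`,
#'   `mean_late`.
#' @export
wilcoxon_feature_separation <- function(values_early, values_late) {
  values_early <- values_early[!is.na(values_early)]
  values_late <- values_late[!is.na(values_late)]
  if (length(values_early) < 2 || length(values_late) < 2) {
    abort("need at least 2 values per group")
  }
  if (length(unique(c(values_early, values_late))) == 1) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_early, values_late,
                         alternative = "two.sided")$p.value
    )
  }
  dm <- mean(values_early) - mean(values_late)
  tibble::tibble(
    p_value = p,
    direction = sign(dm),
    mean_early = mean(values_early),
    mean_late = mean(values_late)
  )
}
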