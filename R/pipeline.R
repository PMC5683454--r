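# Orchestration over a collection of viruses: per-virus separation tests
# in RSCF and amino-acid space, per-gene features with per-feature
# early/late Wilcoxon comparisons, pooled per-virus features, optional
# proteome phylogeny, and the comparison of features between viruses
# with and without a significant separation signal.

# deterministic sub-seed for (virus index, analysis index); keeps
# per-virus results stable when the study is recomposed
derive_seed <- function(seed, virus_index, analysis_index = 1L) {
  # double arithmetic: exact below 2^53, avoids 32-bit overflow for
  # large study seeds; result always a valid set.seed() integer
  as.integer((as.numeric(seed) * 1009 + virus_index * 131 +
                analysis_index) %% 2147483587) + 1L
}

.GENE_FEATURES <- c("gc", "enc", "ntb", "aab")
.VIRUS_FEATURES <- c("coding_length", "enc", "cpb", "dntb", "ntb", "gc", "aab")

#' Run the full temporal codon-usage study
#'
#' For every virus in the gene table: the early/late separation test in
#' RSCF and amino-acid space, the per-gene feature table, per-feature
#' early-vs-late Wilcoxon comparisons, and pooled per-virus features.
#' Optionally an ACS/NJ proteome phylogeny with a flag-association test.
#' Failures are isolated per virus: one bad virus is logged and marked
#' missing without aborting the study. Everything is deterministic
#' given `seed` (per-virus sub-seeds are derived from it).
#'
#' @param genes A labeled gene table covering one or more viruses.
#' @param spaces Analysis spaces, subset of `c("rscf", "aa")`.
#' @param n_perm Label permutations per test (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer study seed.
#' @param fill RSCF fill policy (see [rscf()]).
#' @param proteomes Optional named list of proteomes for the phylogeny
#'   (names must match `virus_id`s).
#' @return An object of class `study_report`: list with tibbles
#'   `separation`, `feature_tests`, `gene_features`, `virus_features`,
#'   `failures`, and optionally `tree` plus `tree_association`.
#' @export
run_study <- function(genes, spaces = c("rscf", "aa"), n_perm = 1000,
                      alpha = 0.05, seed = 1, fill = 0, proteomes = NULL) {
  spaces <- match.arg(spaces, c("rscf", "aa"), several.ok = TRUE)
  virus_ids <- unique(genes$virus_id)
  if (length(virus_ids) == 0) abort("empty virus list")
  sep_rows <- list(); ft_rows <- list(); gf_rows <- list()
  vf_rows <- list(); failures <- list()

  for (vi in seq_along(virus_ids)) {
    vid <- virus_ids[vi]
    g <- genes[genes$virus_id == vid, ]
    for (si in seq_along(spaces)) {
      sp <- spaces[si]
      res <- tryCatch(
        separation_test(g, space = sp, n_perm = n_perm,
                        seed = derive_seed(seed, vi, si), alpha = alpha,
                        fill = fill),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          virus_id = vid, analysis = paste0("separation_", sp),
          message = conditionMessage(res))
      } else {
        sep_rows[[length(sep_rows) + 1L]] <- glance(res)
      }
    }
    gf <- tryCatch(gene_features(g), error = function(e) e)
    if (inherits(gf, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        virus_id = vid, analysis = "gene_features",
        message = conditionMessage(gf))
    } else {
      gf_rows[[length(gf_rows) + 1L]] <- gf
      ft <- tryCatch({
        purrr::map_dfr(.GENE_FEATURES, function(f) {
          ve <- gf[[f]][gf$label == "early"]
          vl <- gf[[f]][gf$label == "late"]
          dplyr::bind_cols(
            tibble::tibble(virus_id = vid, feature = f),
            wilcoxon_feature_separation(ve, vl)
          )
        })
      }, error = function(e) e)
      if (inherits(ft, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          virus_id = vid, analysis = "feature_tests",
          message = conditionMessage(ft))
      } else {
        ft_rows[[length(ft_rows) + 1L]] <- ft
      }
    }
    vf <- tryCatch(virus_features(g), error = function(e) e)
    if (inherits(vf, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        virus_id = vid, analysis = "virus_features",
        message = conditionMessage(vf))
    } else {
      vf_rows[[length(vf_rows) + 1L]] <- vf
    }
  }

  separation <- dplyr::bind_rows(sep_rows)
  if (nrow(separation)) {
    # BH-adjusted p-values across viruses within each space; reported
    # alongside the raw per-virus p-values as a labeled extension
    separation <- separation |>
      dplyr::group_by(.data$space) |>
      dplyr::mutate(p_adjusted_bh = stats::p.adjust(.data$p_value,
                                                    method = "BH")) |>
      dplyr::ungroup()
  }
  report <- list(
    separation = separation,
    feature_tests = dplyr::bind_rows(ft_rows),
    gene_features = dplyr::bind_rows(gf_rows),
    virus_features = dplyr::bind_rows(vf_rows),
    failures = dplyr::bind_rows(failures),
    alpha = alpha, n_perm = n_perm, seed = seed
  )

  if (!is.null(proteomes)) {
    phylo_res <- tryCatch({
      d <- ars_distance_matrix(proteomes)
      tree <- nj_tree(d)
      sig <- report$separation |>
        dplyr::filter(.data$space == "rscf")
      flags <- setNames(sig$significant, sig$virus_id)
      assoc <- if (sum(flags[tree$tip.label], na.rm = TRUE) >= 2) {
        tree_flag_association(tree, flags, n_perm = n_perm,
                              seed = derive_seed(seed, 0L, 99L))
      } else NULL
      list(distances = d, tree = tree, association = assoc)
    }, error = function(e) {
      report$failures <<- dplyr::bind_rows(
        report$failures,
        tibble::tibble(virus_id = NA_character_, analysis = "phylogeny",
                       message = conditionMessage(e)))
      NULL
    })
    if (!is.null(phylo_res)) {
      report$distances <- phylo_res$distances
      report$tree <- phylo_res$tree
      report$tree_association <- phylo_res$association
    }
  }
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Temporal codon-usage study report\n")
  n_vir <- length(unique(x$separation$virus_id))
  cat(sprintf("  %d virus(es), %d permutations, alpha = %g\n",
              n_vir, x$n_perm, x$alpha))
  for (sp in unique(x$separation$space)) {
    sub <- x$separation[x$separation$space == sp, ]
    cat(sprintf("  %s space: %d of %d viruses significant\n",
                toupper(sp), sum(sub$significant), nrow(sub)))
  }
  if (nrow(x$failures)) {
    cat(sprintf("  %d analysis failure(s) logged\n", nrow(x$failures)))
  }
  if (!is.null(x$tree)) cat("  proteome phylogeny attached\n")
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
glance.study_report <- function(x, ...) {
  x$separation |>
    dplyr::group_by(.data$space) |>
    dplyr::summarise(n_viruses = dplyr::n(),
                     n_significant = sum(.data$significant),
                     .groups = "drop")
}

#' @rdname run_study
#' @export
tidy.study_report <- function(x, ...) {
  x$separation
}

#' Compare virus-level features between separation groups
#'
#' Splits viruses into those with and without a significant early/late
#' RSCF separation and compares each pooled virus-level feature (coding
#' length, ENC, CPB, DNTB, NTB, GC, AAB) between the two groups with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param report A `study_report` from [run_study()].
#' @param space Space whose significance flag defines the groups
#'   (default `"rscf"`).
#' @return A tibble with one row per feature: `feature`, `p_value`,
#'   `direction` (+1 when the significant group's mean is higher),
#'   `n_significant`, `n_nonsignificant`.
#' @export
group_feature_comparison <- function(report, space = "rscf") {
  sep <- report$separation[report$separation$space == space, ]
  vf <- dplyr::left_join(report$virus_features,
                         sep[c("virus_id", "significant")],
                         by = "virus_id")
  vf <- vf[!is.na(vf$significant), ]
  n_sig <- sum(vf$significant); n_non <- sum(!vf$significant)
  if (n_sig == 0 || n_non == 0) {
    inform("one separation group is empty; comparison skipped")
    return(tibble::tibble(feature = character(0), p_value = numeric(0),
                          direction = numeric(0),
                          n_significant = integer(0),
                          n_nonsignificant = integer(0)))
  }
  purrr::map_dfr(.VIRUS_FEATURES, function(f) {
    a <- vf[[f]][vf$significant]
    b <- vf[[f]][!vf$significant]
    if (length(unique(c(a, b))) == 1) {
      p <- 1
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    tibble::tibble(feature = f, p_value = p,
                   direction = sign(mean(a) - mean(b)),
                   n_significant = n_sig, n_nonsignificant = n_non)
  })
}

#' Write the report tables of a study as delimited text
#'
#' Emits `separation.csv`, `feature_tests.csv`, `gene_features.csv`,
#' `virus_features.csv`, `failures.csv` and, when a phylogeny is
#' attached, `distances.phylip` and `tree.nwk`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("separation", "feature_tests", "gene_features",
            "virus_features", "failures")
  for (tb in tabs) {
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$tree)) {
    write_distance_phylip(report$distances, file.path(dir, "distances.phylip"))
    ape::write.tree(report$tree, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
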