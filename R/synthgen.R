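# Synthetic-data generators: every input the pipeline consumes, with
# planted, known structure, so all stages are testable without
# downloads. All generators are pure functions of (config, seed).

# typical globular-protein amino-acid composition (frequencies sum to 1)
.AA_COMPOSITION <- c(
  A = 0.080, C = 0.014, D = 0.054, E = 0.067, F = 0.039,
  G = 0.071, H = 0.023, I = 0.060, K = 0.058, L = 0.096,
  M = 0.024, N = 0.040, P = 0.047, Q = 0.039, R = 0.055,
  S = 0.066, T = 0.053, V = 0.069, W = 0.011, Y = 0.029
)

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

# per-amino-acid synonymous codon distributions as a named list of
# frequency vectors (names = codons of the family)
random_family_distribution <- function(alpha = 1) {
  lapply(split(.SENSE_CODONS, .CODON_AA[.SENSE_CODONS]), function(cods) {
    setNames(rdirichlet1(rep(alpha, length(cods))), cods)
  })
}

#' Configuration for a synthetic virus
#'
#' Describes a two-group (early/late) synthetic viral gene set. Codons
#' are sampled per amino-acid family from `P_early` for early genes and
#' from `P_late = (1 - divergence) * P_early + divergence * Q` for late
#' genes, where `Q` is an independent Dirichlet perturbation (sparse,
#' concentration 0.5, so it sits away from `P_early`); `divergence = 0`
#' means both groups share one distribution. Default group sizes are
#' phage-scale; `preset = "human"` switches to the 8 early / 14 late
#' sizes typical of human viruses.
#'
#' @param n_early,n_late Gene counts per temporal group (phage-scale
#'   defaults 25 and 40).
#' @param gene_length_range Codon-count range genes are drawn from
#'   (default 100-400).
#' @param divergence Mixing weight `delta` in `[0, 1]` pulling the late
#'   distribution away from the early one.
#' @param gc_target Optional target mean GC fraction; family
#'   distributions are exponentially tilted to meet it (error when
#'   infeasible).
#' @param seed Integer seed; everything downstream is a pure function
#'   of the config including this seed.
#' @param preset `"phage"` (default) or `"human"`; presets only set
#'   `n_early`/`n_late` and are overridden by explicit arguments.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_early = NULL, n_late = NULL,
                         gene_length_range = c(100, 400), divergence = 0,
                         gc_target = NULL, seed = 1,
                         preset = c("phage", "human")) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
                  phage = c(25L, 40L),
                  human = c(8L, 14L))
  n_early <- as.integer(n_early %||% sizes[1])
  n_late <- as.integer(n_late %||% sizes[2])
  stopifnot(n_early >= 1, n_late >= 1,
            divergence >= 0, divergence <= 1,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 10)
  structure(
    list(n_early = n_early, n_late = n_late,
         gene_length_range = as.integer(gene_length_range),
         divergence = divergence, gc_target = gc_target,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# mean GC fraction contributed by one codon
codon_gc <- function(codons) {
  (stringr::str_count(codons, "G") + stringr::str_count(codons, "C")) / 3
}

# exponentially tilt per-family distributions so the expected GC over
# the amino-acid composition hits `target`
tilt_to_gc <- function(fams, target) {
  aa_of <- names(fams)
  mean_gc <- function(eta) {
    per_fam <- vapply(fams, function(p) {
      g <- codon_gc(names(p))
      w <- p * exp(eta * g)
      sum(w * g) / sum(w)
    }, numeric(1))
    sum(.AA_COMPOSITION[aa_of] * per_fam) / sum(.AA_COMPOSITION[aa_of])
  }
  lo <- mean_gc(-50); hi <- mean_gc(50)
  if (target < lo || target > hi) {
    abort(sprintf("gc_target %.3f infeasible; achievable range [%.3f, %.3f]",
                  target, lo, hi))
  }
  eta <- stats::uniroot(function(e) mean_gc(e) - target, c(-50, 50))$root
  lapply(fams, function(p) {
    w <- p * exp(eta * codon_gc(names(p)))
    w / sum(w)
  })
}

sample_gene <- function(len, fams) {
  aa <- sample(names(.AA_COMPOSITION), len, replace = TRUE,
               prob = .AA_COMPOSITION)
  cods <- character(len)
  for (a in unique(aa)) {
    idx <- which(aa == a)
    p <- fams[[a]]
    cods[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  paste0(paste(cods, collapse = ""), "TAA")
}

#' Generate a synthetic labeled virus
#'
#' Draws amino-acid sequences from a fixed composition and codons per
#' family from the early/late distributions of the config (see
#' [synth_config()]). Returns the gene table together with the ground
#' truth needed by recovery tests.
#'
#' @param cfg A `synth_config`.
#' @param virus_id Identifier for the generated virus.
#' @return A list with `genes` (a labeled gene table) and `truth`
#'   (list: `p_early`, `p_late`, `q`, `divergence`).
#' @export
synth_virus <- function(cfg, virus_id = "synth_virus") {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    p_early <- random_family_distribution(alpha = 1)
    q <- random_family_distribution(alpha = 0.5)
    p_late <- purrr::map2(p_early, q, function(pe, qq) {
      (1 - cfg$divergence) * pe + cfg$divergence * qq
    })
    if (!is.null(cfg$gc_target)) {
      p_early <- tilt_to_gc(p_early, cfg$gc_target)
      p_late <- tilt_to_gc(p_late, cfg$gc_target)
    }
    lens <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                   cfg$n_early + cfg$n_late, replace = TRUE)
    seqs <- c(
      vapply(lens[seq_len(cfg$n_early)], sample_gene, character(1),
             fams = p_early),
      vapply(lens[cfg$n_early + seq_len(cfg$n_late)], sample_gene,
             character(1), fams = p_late)
    )
    genes <- new_gene_table(
      gene_id = sprintf("g%03d", seq_along(seqs)),
      virus_id = virus_id,
      seq = seqs,
      label = rep(c("early", "late"), c(cfg$n_early, cfg$n_late))
    )
    list(genes = genes,
         truth = list(p_early = p_early, p_late = p_late, q = q,
                      divergence = cfg$divergence))
  })
}

#' Planted EMG truth parameters per codon
#'
#' Draws one `(mu, sigma, lam)` triple per sense codon for use with
#' [synth_ribo_profiles()]: `mu` uniform on `mu_range`, `sigma` and
#' `lam` uniform on their ranges.
#'
#' @param seed Integer seed.
#' @param mu_range,sigma_range,lam_range Parameter ranges.
#' @return A tibble with columns `codon`, `mu`, `sigma`, `lam`.
#' @export
synth_emg_truth <- function(seed = 1, mu_range = c(0.5, 2),
                            sigma_range = c(0.2, 0.5),
                            lam_range = c(0.8, 2)) {
  withr::with_seed(seed, {
    tibble::tibble(
      codon = .SENSE_CODONS,
      mu = runif(length(.SENSE_CODONS), mu_range[1], mu_range[2]),
      sigma = runif(length(.SENSE_CODONS), sigma_range[1], sigma_range[2]),
      lam = runif(length(.SENSE_CODONS), lam_range[1], lam_range[2])
    )
  })
}

# draw n EMG variates
remg <- function(n, mu, sigma, lam) {
  rnorm(n, mu, sigma) + rexp(n, lam)
}

#' Generate synthetic ribosome footprint profiles
#'
#' For every codon position of every gene, a dwell value is drawn from
#' that codon's EMG truth distribution and converted to a count by
#' scaling with `depth` and rounding (negative dwells clamp to 0).
#' Positions holding stop or ambiguous codons draw from the mean truth
#' parameters.
#'
#' @param genes A gene table.
#' @param emg_truth Tibble with columns `codon`, `mu`, `sigma`, `lam`
#'   (see [synth_emg_truth()]).
#' @param depth Positive scaling factor from dwell to expected counts.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_id`, `position`, `count`.
#' @export
synth_ribo_profiles <- function(genes, emg_truth, depth = 50, seed = 1) {
  if (depth <= 0) abort("depth must be positive")
  mu <- setNames(emg_truth$mu, emg_truth$codon)
  sg <- setNames(emg_truth$sigma, emg_truth$codon)
  lm <- setNames(emg_truth$lam, emg_truth$codon)
  mmu <- mean(emg_truth$mu); msg <- mean(emg_truth$sigma)
  mlm <- mean(emg_truth$lam)
  withr::with_seed(seed, {
    purrr::map2_dfr(genes$gene_id, genes$seq, function(id, s) {
      cods <- split_codons(s)
      known <- cods %in% names(mu)
      dwell <- numeric(length(cods))
      if (any(known)) {
        dwell[known] <- rnorm(sum(known), mu[cods[known]], sg[cods[known]]) +
          rexp(sum(known), lm[cods[known]])
      }
      if (any(!known)) {
        dwell[!known] <- remg(sum(!known), mmu, msg, mlm)
      }
      tibble::tibble(gene_id = id, position = seq_along(cods),
                     count = round(depth * pmax(dwell, 0)))
    })
  })
}

random_segment <- function(len) {
  paste(sample(names(.AA_COMPOSITION), len, replace = TRUE,
               prob = .AA_COMPOSITION), collapse = "")
}

#' Generate a proteome family along a phylogeny
#'
#' Builds a root proteome of random amino-acid segments (one segment
#' per protein) and evolves it down the tree: along each branch every
#' segment is independently replaced by a fresh random segment with
#' probability `min(1, shuffle_rate * branch_length)`. Leaves that are
#' close on the tree therefore share more intact segments, which the
#' ACS distance picks up.
#'
#' @param tree A rooted or unrooted `phylo` tree with branch lengths.
#' @param shuffle_rate Segment replacement rate per unit branch length.
#' @param n_segments Number of segments (proteins) per proteome.
#' @param segment_length Residues per segment.
#' @param seed Integer seed.
#' @return A named list of proteomes (one per leaf), with the
#'   generating tree attached as attribute `"tree"`.
#' @export
synth_proteome_family <- function(tree, shuffle_rate = 0.3, n_segments = 60,
                                  segment_length = 30, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  withr::with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    proteomes <- vector("list", n_tip + tree$Nnode)
    proteomes[[root]] <- vapply(seq_len(n_segments), function(i) {
      random_segment(segment_length)
    }, character(1))
    # cladewise (preorder) edge order guarantees parent-before-child
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      p <- proteomes[[par]]
      bl <- tree$edge.length[k]
      flip <- runif(n_segments) < pmin(1, shuffle_rate * bl)
      if (any(flip)) {
        p[flip] <- vapply(seq_len(sum(flip)), function(i) {
          random_segment(segment_length)
        }, character(1))
      }
      proteomes[[child]] <- p
    }
    leaves <- proteomes[seq_len(n_tip)]
    names(leaves) <- tree$tip.label
    attr(leaves, "tree") <- tree
    leaves
  })
}
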