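# Per-codon typical decoding rates from ribosome-profiling footprint
# counts, via maximum-likelihood fits of the exponentially modified
# Gaussian (EMG) to each codon's normalized footprint count (NFC)
# distribution, and the gene-level mean typical decoding rate (MTDR).

#' Read a ribosome footprint count table
#'
#' Delimited text with one row per codon position and header columns
#' `gene_id`, `position` (1-based codon index; `codon_position`
#' accepted) and `count`.
#'
#' @param path Path to the file.
#' @return A tibble with columns `gene_id`, `position`, `count`.
#' @export
read_ribo_counts <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  if ("codon_position" %in% names(tab) && !"position" %in% names(tab)) {
    tab$position <- tab$codon_position
  }
  req <- c("gene_id", "position", "count")
  if (!all(req %in% names(tab))) {
    abort("count table needs columns gene_id, position, count")
  }
  tibble::tibble(gene_id = as.character(tab$gene_id),
                 position = as.integer(tab$position),
                 count = as.numeric(tab$count))
}

#' Normalize footprint profiles to per-codon NFC values
#'
#' For each gene passing the coverage filter, the normalized footprint
#' count at an included position is the raw count divided by the gene's
#' mean count over included positions, so the per-gene NFC mean is 1.
#' The first and last `edge_exclude` codons are excluded (ramp and
#' boundary artifacts); zero-count positions are treated as missing
#' coverage and excluded unless `include_zeros = TRUE`, in which case
#' they enter both the mean and the samples.
#'
#' @param profiles Tibble with columns `gene_id`, `position`, `count`.
#' @param edge_exclude Codons trimmed from each gene end (default 5).
#' @param include_zeros Keep zero-count positions (default `FALSE`).
#' @param min_mean_count Coverage filter: genes with mean raw count per
#'   codon below this are excluded with a warning (default 1).
#' @return A tibble with columns `gene_id`, `position`, `count`, `nfc`
#'   containing only included positions.
#' @export
normalize_profile <- function(profiles, edge_exclude = 5,
                              include_zeros = FALSE, min_mean_count = 1) {
  dropped <- character(0)
  out <- profiles |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$position)
      len <- max(g$position)
      if (mean(g$count) < min_mean_count) {
        dropped <<- c(dropped, key$gene_id)
        return(g[0, ])
      }
      keep <- g$position > edge_exclude & g$position <= len - edge_exclude
      if (!include_zeros) keep <- keep & g$count > 0
      g <- g[keep, ]
      if (nrow(g) == 0 || mean(g$count) == 0) {
        dropped <<- c(dropped, key$gene_id)
        return(g[0, ])
      }
      g$nfc <- g$count / mean(g$count)
      g
    }) |>
    dplyr::ungroup()
  if (length(dropped)) {
    warn(sprintf("%d gene(s) excluded by the coverage filter: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  out
}

#' Pool NFC values by codon identity
#'
#' Each included position's NFC is appended to the sample of the codon
#' at that position of the gene's CDS. Positions holding stop or
#' ambiguous codons are dropped. The profile length of each gene must
#' match its CDS codon count.
#'
#' @param nfc Tibble from [normalize_profile()].
#' @param genes A gene table supplying the CDS sequences.
#' @return A tibble with columns `codon`, `nfc`.
#' @export
pool_nfc <- function(nfc, genes) {
  seqs <- setNames(genes$seq, genes$gene_id)
  nfc <- nfc[nfc$gene_id %in% names(seqs), ]
  out <- nfc |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      s <- seqs[[key$gene_id]]
      cods <- split_codons(s)
      if (max(g$position) > length(cods)) {
        abort(sprintf("profile of '%s' longer than its CDS (%d codons)",
                      key$gene_id, length(cods)))
      }
      g$codon <- cods[g$position]
      g
    }) |>
    dplyr::ungroup()
  out <- out[out$codon %in% .SENSE_CODONS, c("codon", "nfc")]
  out
}

#' Exponentially modified Gaussian density
#'
#' Density of the sum of a Gaussian (mean `mu`, sd `sigma`) and an
#' independent exponential (rate `lam`) random variable, evaluated on
#' the log scale internally for overflow safety:
#' `log f = log(lam) + lam^2 sigma^2 / 2 - lam (x - mu) +
#'  log Phi((x - mu)/sigma - lam * sigma)`.
#'
#' @param x Numeric vector of evaluation points.
#' @param mu,sigma,lam EMG parameters (`sigma`, `lam` positive).
#' @param log Return log-density (default `FALSE`).
#' @return Numeric vector of (log-)densities.
#' @export
demg <- function(x, mu, sigma, lam, log = FALSE) {
  stopifnot(sigma > 0, lam > 0)
  lf <- base::log(lam) + lam^2 * sigma^2 / 2 - lam * (x - mu) +
    stats::pnorm((x - mu) / sigma - lam * sigma, log.p = TRUE)
  if (log) lf else exp(lf)
}

# method-of-moments initializer for the EMG
emg_moment_init <- function(x) {
  m <- mean(x); v <- stats::var(x)
  g <- mean((x - m)^3) / v^1.5
  g <- min(max(g, 0.01), 1.9)   # EMG skewness lies in (0, 2)
  tau <- sqrt(v) * (g / 2)^(1/3)
  mu0 <- m - tau
  s2 <- v - tau^2
  if (s2 <= 0) s2 <- 0.05 * v
  c(mu = mu0, sigma = sqrt(s2), lam = 1 / tau)
}

#' Maximum-likelihood EMG fit to an NFC sample
#'
#' Fits `(mu, sigma, lam)` by maximizing the EMG log-likelihood with
#' derivative-free local search (Nelder-Mead on `(mu, log sigma,
#' log lam)`) from a method-of-moments start, plus jittered restarts
#' under a fixed seed. The returned log-likelihood is never below that
#' of the moment initializer.
#'
#' @param x Numeric sample (e.g. one codon's pooled NFC values).
#' @param min_n Minimum sample size (default 200).
#' @param n_restarts Jittered restarts beyond the moment start
#'   (default 3).
#' @param seed Integer seed for the jitter.
#' @return An object of class `emg_fit`: list with `mu`, `sigma`,
#'   `lam`, `loglik`, `converged`, `n`.
#' @export
fit_emg <- function(x, min_n = 200, n_restarts = 3, seed = 1) {
  x <- x[is.finite(x)]
  if (length(x) < min_n) {
    abort(sprintf("EMG fit needs >= %d observations; got %d",
                  min_n, length(x)))
  }
  init <- emg_moment_init(x)
  nll <- function(theta) {
    mu <- theta[1]; sigma <- exp(theta[2]); lam <- exp(theta[3])
    v <- -sum(demg(x, mu, sigma, lam, log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  theta0 <- c(init["mu"], base::log(init["sigma"]), base::log(init["lam"]))
  jitters <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) theta0 + rnorm(3, 0, 0.3))
  })
  best <- NULL
  for (start in c(list(theta0), jitters)) {
    fit <- tryCatch(
      stats::optim(start, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  ll_init <- -nll(theta0)
  if (is.null(best) || -best$value < ll_init) {
    # never report worse than the initializer
    best <- list(par = theta0, value = -ll_init, convergence = 1L)
  }
  structure(
    list(mu = unname(best$par[1]),
         sigma = exp(unname(best$par[2])),
         lam = exp(unname(best$par[3])),
         loglik = -best$value,
         converged = best$convergence == 0,
         n = length(x)),
    class = "emg_fit"
  )
}

#' @export
print.emg_fit <- function(x, ...) {
  cat(sprintf(
    "EMG fit (n = %d): mu = %.4f, sigma = %.4f, lambda = %.4f, loglik = %.2f%s\n",
    x$n, x$mu, x$sigma, x$lam, x$loglik,
    if (!x$converged) "  [not converged]" else ""
  ))
  invisible(x)
}

#' @rdname fit_emg
#' @param x An `emg_fit` object.
#' @param ... Unused.
#' @export
glance.emg_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, lam = x$lam,
                 tdr = 1 / x$mu, loglik = x$loglik,
                 converged = x$converged, n = x$n)
}

#' Per-codon typical decoding rate table
#'
#' Runs the NFC normalization, pools samples by codon, fits the EMG to
#' every codon with enough observations, and reports the typical
#' decoding rate `TDR = 1/mu` (the Gaussian component's mean locates
#' the typical dwell; its reciprocal is the rate).
#'
#' @param profiles Footprint count tibble (`gene_id`, `position`,
#'   `count`).
#' @param genes Gene table matching the profiles.
#' @param min_n Minimum pooled observations per codon (default 200).
#' @param seed Seed for the fit restarts.
#' @param ... Passed to [normalize_profile()].
#' @return A tibble with columns `codon`, `n`, `mu`, `sigma`, `lambda`,
#'   `tdr`, `converged`; codons with too few observations or failed
#'   fits carry `NA` in the fitted columns.
#' @export
tdr_table <- function(profiles, genes, min_n = 200, seed = 1, ...) {
  nfc <- normalize_profile(profiles, ...)
  pooled <- pool_nfc(nfc, genes)
  purrr::map_dfr(.SENSE_CODONS, function(cod) {
    xs <- pooled$nfc[pooled$codon == cod]
    base <- tibble::tibble(codon = cod, n = length(xs), mu = NA_real_,
                           sigma = NA_real_, lambda = NA_real_,
                           tdr = NA_real_, converged = NA)
    if (length(xs) < min_n) return(base)
    fit <- tryCatch(fit_emg(xs, min_n = min_n, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) return(base)
    tibble::tibble(codon = cod, n = fit$n, mu = fit$mu, sigma = fit$sigma,
                   lambda = fit$lam, tdr = 1 / fit$mu,
                   converged = fit$converged)
  })
}

#' Mean typical decoding rate of genes
#'
#' Gene-level translation-elongation efficiency estimate: the geometric
#' mean of the typical decoding rates of a gene's codons,
#' `MTDR = exp(mean(log tdr(codon_k)))`. Codons lacking a TDR are
#' skipped with a warning (or, with `missing = "skip_gene"`, the whole
#' gene is reported `NA`).
#'
#' @param genes A gene table.
#' @param tdr A TDR table from [tdr_table()].
#' @param missing `"skip_codon"` (default) or `"skip_gene"`.
#' @return A tibble with columns `gene_id`, `mtdr`, `n_codons_used`.
#' @export
mtdr <- function(genes, tdr, missing = c("skip_codon", "skip_gene")) {
  missing <- match.arg(missing)
  tv <- setNames(tdr$tdr, tdr$codon)
  any_skipped <- FALSE
  out <- purrr::map2_dfr(genes$gene_id, genes$seq, function(id, s) {
    cods <- countable_codons(s)
    cods <- cods[!is.na(cods)]
    vals <- tv[cods]
    if (anyNA(vals)) {
      if (missing == "skip_gene") {
        return(tibble::tibble(gene_id = id, mtdr = NA_real_,
                              n_codons_used = 0L))
      }
      any_skipped <<- TRUE
      vals <- vals[!is.na(vals)]
    }
    tibble::tibble(
      gene_id = id,
      mtdr = if (length(vals)) exp(mean(base::log(vals))) else NA_real_,
      n_codons_used = length(vals)
    )
  })
  if (any_skipped) warn("codons without a TDR were skipped in some genes")
  out
}
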