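# Shared fixtures and independent brute-force oracles. Everything is
# generated in code; no stored data files.

SENSE <- codon_table()$codon
CODON_AA_MAP <- setNames(codon_table()$aa, codon_table()$codon)

genes_tbl <- function(seqs, ids = sprintf("g%02d", seq_along(seqs)),
                      virus = "v", labels = "unlabeled") {
  new_gene_table(ids, virus, seqs, labels)
}

# random stopless coding sequence of n codons (uniform over sense codons)
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    paste(sample(SENSE, n_codons, replace = TRUE), collapse = "")
  })
}

# --- independent naive oracles -------------------------------------------

# codon-pair scores by direct recounting, independent of cps_table()
naive_cps <- function(seqs) {
  codons_of <- function(s) {
    n <- nchar(s)
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    if (length(cods) && cods[length(cods)] %in% c("TAA", "TAG", "TGA")) {
      cods <- cods[-length(cods)]
    }
    cods[cods %in% SENSE]
  }
  all_cods <- unlist(lapply(seqs, codons_of))
  pairs <- do.call(rbind, lapply(seqs, function(s) {
    cods <- codons_of(s)
    if (length(cods) < 2) return(NULL)
    cbind(cods[-length(cods)], cods[-1])
  }))
  n_c <- table(all_cods)
  n_a <- table(CODON_AA_MAP[all_cods])
  key <- paste(pairs[, 1], pairs[, 2])
  n_p <- table(key)
  akey <- paste(CODON_AA_MAP[pairs[, 1]], CODON_AA_MAP[pairs[, 2]])
  n_ap <- table(akey)
  out <- lapply(names(n_p), function(k) {
    cc <- strsplit(k, " ")[[1]]
    x <- CODON_AA_MAP[cc[1]]; y <- CODON_AA_MAP[cc[2]]
    exp_n <- as.numeric(n_c[cc[1]]) * as.numeric(n_c[cc[2]]) /
      (as.numeric(n_a[x]) * as.numeric(n_a[y])) *
      as.numeric(n_ap[paste(x, y)])
    data.frame(codon1 = cc[1], codon2 = cc[2], n = as.integer(n_p[k]),
               cps = log(as.numeric(n_p[k]) / exp_n))
  })
  do.call(rbind, out)
}

naive_cpb <- function(seqs) {
  tab <- naive_cps(seqs)
  sum(tab$n * tab$cps) / sum(tab$n)
}

# dinucleotide scores by direct recounting
naive_dnts <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  mono <- table(factor(unlist(chars), levels = c("A", "C", "G", "T")))
  f1 <- mono / sum(mono)
  dints <- unlist(lapply(chars, function(v) {
    if (length(v) < 2) return(character(0))
    paste0(v[-length(v)], v[-1])
  }))
  dints <- dints[grepl("^[ACGT]{2}$", dints)]
  n2 <- table(dints)
  f2 <- n2 / sum(n2)
  sapply(names(n2), function(d) {
    as.numeric(f2[d]) /
      (as.numeric(f1[substr(d, 1, 1)]) * as.numeric(f1[substr(d, 2, 2)]))
  })
}

naive_dntb <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  dints <- unlist(lapply(chars, function(v) {
    if (length(v) < 2) return(character(0))
    paste0(v[-length(v)], v[-1])
  }))
  dints <- dints[grepl("^[ACGT]{2}$", dints)]
  scores <- naive_dnts(seqs)
  mean(scores[dints])
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random unambiguous protein sequence
random_protein <- function(n, seed) {
  withr::with_seed(seed, paste(sample(AA20, n, replace = TRUE),
                               collapse = ""))
}

# average common-substring length by O(n^2 m) direct scanning
naive_acs <- function(a, b) {
  lens <- unlist(lapply(a, function(s) {
    n <- nchar(s)
    sapply(seq_len(n), function(i) {
      best <- 0L
      for (l in seq_len(n - i + 1L)) {
        sub <- substr(s, i, i + l - 1L)
        if (any(vapply(b, function(t) grepl(sub, t, fixed = TRUE),
                       logical(1)))) best <- l else break
      }
      best
    })
  }))
  mean(lens)
}

# expression-driven host gene set for the tAI calibration tests: codon
# choice within each family follows w^e for a gene-specific intensity e
expression_driven_host <- function(w, n_genes = 80, len = 200, e_max = 6,
                                   seed = 1) {
  wv <- setNames(w$w, w$codon)
  aa_names <- sort(unique(CODON_AA_MAP))
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(g) {
      e <- runif(1, 0, e_max)
      aa <- sample(aa_names, len, replace = TRUE)
      cods <- character(len)
      for (a in unique(aa)) {
        idx <- which(aa == a)
        fam <- names(CODON_AA_MAP)[CODON_AA_MAP == a]
        p <- wv[fam]^e
        p <- p / sum(p)
        cods[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
      }
      paste0(paste(cods, collapse = ""), "TAA")
    }, character(1))
    new_gene_table(sprintf("h%03d", seq_len(n_genes)), "host", seqs)
  })
}
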