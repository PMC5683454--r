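test_that("codon counting excludes the terminal stop and ambiguous triplets", {
  expect_equal(
    dplyr::arrange(codon_counts(genes_tbl("ATGGGCGGC")), codon),
    tibble::tibble(gene_id = "g01", codon = c("ATG", "GGC"),
                   count = c(1L, 2L))
  )
  expect_equal(codon_counts(genes_tbl("ATGTAA"))$codon, "ATG")
  cc <- codon_counts(genes_tbl("ATGNNNGGC"))
  expect_setequal(cc$codon, c("ATG", "GGC"))
})

test_that("RSCF normalizes within synonymous families", {
  r <- rscf(genes_tbl("GGCGGCGGA"))
  expect_equal(r$GGC, 2 / 3)
  expect_equal(r$GGA, 1 / 3)
  expect_equal(r$GGG, 0)
  expect_equal(r$GGT, 0)
  expect_equal(r$AAA, 0)  # absent family, fill = 0

  r <- rscf(genes_tbl("ATGATG"))
  expect_equal(r$ATG, 1)

  # one of each codon of the Ala 4-fold family
  r <- rscf(genes_tbl("GCAGCCGCGGCT"))
  expect_equal(unlist(r[c("GCA", "GCC", "GCG", "GCT")]),
               c(GCA = 0.25, GCC = 0.25, GCG = 0.25, GCT = 0.25))

  # uniform fill policy puts 1/degeneracy on absent families
  r <- rscf(genes_tbl("ATGATG"), fill = "uniform")
  expect_equal(r$GGC, 0.25)
  expect_equal(r$TTA, 1 / 6)
})

test_that("RSCF family sums equal one for present amino acids (property)", {
  ct <- codon_table()
  for (seed in 1:5) {
    g <- genes_tbl(random_cds(120, seed))
    r <- rscf(g)
    present <- unique(ct$aa[ct$codon %in% codon_counts(g)$codon])
    for (a in present) {
      fam <- ct$codon[ct$aa == a]
      expect_equal(sum(unlist(r[fam])), 1, tolerance = 1e-9)
    }
  }
})

test_that("amino-acid frequencies are normalized", {
  f <- aa_frequencies(genes_tbl("GGCGGA"))
  expect_equal(f$G, 1)
  f <- aa_frequencies(genes_tbl("ATGGGC"))
  expect_equal(f$M, 0.5)
  expect_equal(f$G, 0.5)
  f <- aa_frequencies(genes_tbl(random_cds(300, 3)))
  expect_equal(sum(unlist(f[unique(codon_table()$aa)])), 1, tolerance = 1e-9)
})

test_that("Wright's family statistic matches the hand evaluation", {
  # 2-fold family with counts (3,1): F = (4*(9/16 + 1/16) - 1)/3 = 0.5
  expect_equal(codontempo:::wright_f(c(3, 1)), 0.5)
})

test_that("ENC hits its closed-form limits", {
  # one codon per amino acid, every amino acid present, large n -> 20
  ct <- codon_table()
  one_per_aa <- vapply(split(ct$codon, ct$aa), `[`, character(1), 1)
  g <- genes_tbl(paste(rep(paste(one_per_aa, collapse = ""), 20),
                       collapse = ""))
  expect_equal(enc(g)$enc, 20, tolerance = 1e-9)

  # perfectly uniform synonymous usage, large n -> 61
  uniform_gene <- paste(rep(paste(ct$codon, collapse = ""), 40),
                        collapse = "")
  expect_equal(enc(genes_tbl(uniform_gene))$enc, 61, tolerance = 0.01)
})

test_that("ENC is permutation-invariant and decreases with concentration", {
  cods <- withr::with_seed(5, sample(strsplit(random_cds(200, 5), "")[[1]]))
  g1 <- genes_tbl(random_cds(200, 5))
  perm <- withr::with_seed(9, {
    cs <- substring(g1$seq, seq(1, nchar(g1$seq), 3),
                    seq(3, nchar(g1$seq), 3))
    paste(sample(cs), collapse = "")
  })
  expect_equal(enc(g1)$enc, enc(genes_tbl(perm))$enc)

  # 2-fold family (n, 0) is more biased than (n/2, n/2)
  base <- paste(rep("GGC", 30), collapse = "")  # keeps a 4-fold family going
  conc <- genes_tbl(paste0(base, paste(rep("AAA", 20), collapse = "")))
  unif <- genes_tbl(paste0(base, paste(rep(c("AAA", "AAG"), 10),
                                       collapse = "")))
  expect_lt(enc(conc)$enc, enc(unif)$enc)
})

test_that("GC content counts only unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNN"), 0.5)
  expect_error(gc_content("NNN"), "no unambiguous")
})

test_that("entropy bias is the normalized Shannon entropy", {
  expect_equal(entropy_bias(rep(1 / 4, 4)), 1)
  expect_equal(entropy_bias(c(1, 0, 0, 0)), 0)
  expect_equal(entropy_bias(c(0.5, 0.5, 0, 0)), 0.5)
  expect_equal(entropy_bias(rep(1 / 20, 20)), 1)
  expect_error(entropy_bias(c(-0.1, 1.1, 0, 0)), "negative")
  # bounded and 1 only at uniformity
  for (seed in 1:5) {
    p <- withr::with_seed(seed, {x <- rgamma(4, 1); x / sum(x)})
    h <- entropy_bias(p)
    expect_gte(h, 0); expect_lte(h, 1)
    if (max(abs(p - 0.25)) > 0.05) expect_lt(h, 1)
  }
})

test_that("codon-pair scores match the hand-counted toy", {
  tab <- cps_table(genes_tbl("GGCGGCGGAGGC"))
  ggcggc <- tab$cps[tab$codon1 == "GGC" & tab$codon2 == "GGC"]
  expect_equal(ggcggc, log(16 / 27))
  expect_equal(cpb(genes_tbl("GGCGGCGGAGGC")),
               (log(16 / 27) + 2 * log(16 / 9)) / 3)
})

test_that("codon-pair scores equal the brute-force oracle on random corpora", {
  for (seed in 1:4) {
    seqs <- vapply(1:4, function(i) random_cds(40, seed * 10 + i),
                   character(1))
    g <- genes_tbl(seqs)
    got <- as.data.frame(cps_table(g))
    want <- naive_cps(seqs)
    want <- want[order(want$codon1, want$codon2), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(cpb(g), naive_cpb(seqs), tolerance = 1e-12)
  }
})

test_that("codon-pair and dinucleotide bias are gene-order invariant", {
  seqs <- vapply(1:5, function(i) random_cds(30, i), character(1))
  g <- genes_tbl(seqs)
  g_rev <- genes_tbl(rev(seqs), ids = rev(sprintf("g%02d", 1:5)))
  expect_equal(cpb(g), cpb(g_rev))
  expect_equal(dntb(g), dntb(g_rev))
})

test_that("dinucleotide scores match hand counts and the oracle", {
  tab <- dnts(genes_tbl("ACACAC"))
  expect_equal(tab$dnts[tab$dinucleotide == "AC"], 2.4)
  expect_equal(tab$dnts[tab$dinucleotide == "CA"], 1.6)
  expect_equal(dntb(genes_tbl("ACACAC")), 2.08)

  tab <- dnts(genes_tbl("AAAA"))
  expect_equal(tab$dnts[tab$dinucleotide == "AA"], 1)

  for (seed in 1:4) {
    seqs <- vapply(1:3, function(i) random_cds(25, seed * 7 + i),
                   character(1))
    g <- genes_tbl(seqs)
    got <- dnts(g)
    want <- naive_dnts(seqs)
    for (d in names(want)) {
      expect_equal(got$dnts[got$dinucleotide == d], unname(want[d]),
                   tolerance = 1e-12)
    }
    expect_equal(dntb(g), naive_dntb(seqs), tolerance = 1e-12)
  }
})

test_that("dinucleotide scores approach 1 for i.i.d. sequence", {
  s <- withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 60000,
                                        replace = TRUE), collapse = ""))
  tab <- dnts(genes_tbl(substr(s, 1, 59999 - 59999 %% 3)))
  expect_true(all(abs(tab$dnts - 1) < 0.05))
  expect_equal(dntb(genes_tbl(substr(s, 1, 59997))), 1, tolerance = 0.05)
})

test_that("feature tables carry per-gene and pooled per-virus features", {
  v <- synth_virus(synth_config(n_early = 5, n_late = 6, seed = 2))
  gf <- gene_features(v$genes)
  expect_equal(nrow(gf), 11)
  expect_true(all(gf$gc >= 0 & gf$gc <= 1))
  expect_true(all(gf$ntb >= 0 & gf$ntb <= 1))
  expect_true(all(gf$aab >= 0 & gf$aab <= 1))
  expect_true(all(gf$enc >= 1.61 & gf$enc <= 61, na.rm = TRUE))

  vf <- virus_features(v$genes)
  expect_equal(nrow(vf), 1)
  expect_named(vf, c("virus_id", "n_genes", "coding_length", "enc", "cpb",
                     "dntb", "gc", "ntb", "aab"))
  vf2 <- virus_features(v$genes, by_label = TRUE)
  expect_equal(nrow(vf2), 2)
})
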