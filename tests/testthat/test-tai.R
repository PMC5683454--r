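test_that("the pairing table respects amino-acid identity and domain", {
  tab <- wobble_pairing_table("bacteria")
  # Met and Trp are read by their Watson-Crick anticodons only
  expect_equal(tab$class[tab$codon == "ATG"], "WC")
  expect_equal(tab$class[tab$codon == "TGG"], "WC")
  # AUA (Ile) gains the lysidine pairing in bacteria only
  expect_setequal(tab$class[tab$codon == "ATA"], c("WC", "IA", "LA"))
  euk <- wobble_pairing_table("eukaryote")
  expect_setequal(euk$class[euk$codon == "ATA"], c("WC", "IA"))
  # every codon has its Watson-Crick anticodon
  wc <- tab[tab$class == "WC", ]
  expect_equal(nrow(wc), 61)
})

test_that("absolute weights accumulate (1 - s) * copies over cognates", {
  # single Watson-Crick tRNA, copies 2, s = 0 -> W = 2
  pool <- tibble::tibble(anticodon = "CAT", copies = 2L)  # reads ATG
  W <- absolute_weights(pool, domain = "bacteria")
  expect_equal(W$W[W$codon == "ATG"], 2)

  # codon recognized only through a fully penalized wobble class -> W = 0
  s <- default_wobble_penalties(); s["GU"] <- 1
  pool <- tibble::tibble(anticodon = "GAA", copies = 3L)  # WC for TTC
  W <- absolute_weights(pool, s, domain = "bacteria")
  expect_equal(W$W[W$codon == "TTT"], 0)   # TTT only via G:U here
  expect_equal(W$W[W$codon == "TTC"], 3)

  # three-anticodon pool against hand enumeration:
  # GAA: WC->TTC, GU wobble->TTT; TAA: WC->TTA, UG wobble->TTG;
  # CAT: WC->ATG, LA->ATA (bacteria)
  pool <- tibble::tibble(anticodon = c("GAA", "TAA", "CAT"),
                         copies = c(4L, 2L, 5L))
  s <- default_wobble_penalties()
  W <- absolute_weights(pool, s, domain = "bacteria")
  expect_equal(W$W[W$codon == "TTC"], 4)
  expect_equal(W$W[W$codon == "TTT"], (1 - s[["GU"]]) * 4)
  expect_equal(W$W[W$codon == "TTA"], 2)
  expect_equal(W$W[W$codon == "TTG"], (1 - s[["UG"]]) * 2)
  expect_equal(W$W[W$codon == "ATG"], 5)
  expect_equal(W$W[W$codon == "ATA"], (1 - s[["LA"]]) * 5)
})

test_that("weight normalization imputes zero-weight codons geometrically", {
  W <- tibble::tibble(codon = c("AAA", "AAG", "AAT"), W = c(2, 1, 0))
  w <- normalize_weights(W)
  expect_equal(w$w, c(1, 0.5, sqrt(0.5)))

  W$W <- c(3, 3, 3)
  expect_true(all(normalize_weights(W)$w == 1))

  W$W <- c(2, 1, 0) * 10
  expect_equal(normalize_weights(W)$w, c(1, 0.5, sqrt(0.5)))

  expect_error(normalize_weights(tibble::tibble(codon = "AAA", W = 0)),
               "all absolute weights")
})

test_that("gene tAI is the geometric mean of codon weights", {
  w <- tibble::tibble(codon = SENSE, w = 1)
  expect_equal(tai_of_gene(genes_tbl("ATGGGCAAA"), w)$tai, 1)

  w$w[w$codon == "ATG"] <- 0.25
  w$w[w$codon == "GGC"] <- 1
  expect_equal(tai_of_gene(genes_tbl("ATGGGC"), w)$tai, 0.5)

  # permutation invariance
  w2 <- tibble::tibble(codon = SENSE,
                       w = withr::with_seed(4, runif(61, 0.1, 1)))
  g <- genes_tbl("ATGGGCAAATTTCCC")
  g_perm <- genes_tbl("TTTAAAGGCCCCATG")
  expect_equal(tai_of_gene(g, w2)$tai, tai_of_gene(g_perm, w2)$tai)
})

test_that("replacing a codon with a higher-weight synonym never lowers tAI", {
  w <- tibble::tibble(codon = SENSE,
                      w = withr::with_seed(8, runif(61, 0.05, 1)))
  # Lys family: AAA vs AAG
  lo <- if (w$w[w$codon == "AAA"] <= w$w[w$codon == "AAG"]) "AAA" else "AAG"
  hi <- setdiff(c("AAA", "AAG"), lo)
  g_lo <- genes_tbl(paste0("ATGGGC", lo))
  g_hi <- genes_tbl(paste0("ATGGGC", hi))
  expect_gte(tai_of_gene(g_hi, w)$tai, tai_of_gene(g_lo, w)$tai)
})

test_that("fixed published penalties reproduce standard tAI on a small case", {
  # two Phe codons and one Lys codon; pool with WC anticodons only
  pool <- tibble::tibble(anticodon = c("GAA", "TTT"), copies = c(2L, 3L))
  s <- default_wobble_penalties()
  w <- normalize_weights(absolute_weights(pool, s, "bacteria"))
  # hand computation: W(TTC)=2, W(TTT)=0.59*2, W(AAA)=3, W(AAG)=0.32*3
  # max = 3 -> w(TTC)=2/3, w(AAA)=1
  expect_equal(w$w[w$codon == "TTC"], 2 / 3)
  expect_equal(w$w[w$codon == "TTT"], 0.59 * 2 / 3)
  expect_equal(w$w[w$codon == "AAA"], 1)
  expect_equal(w$w[w$codon == "AAG"], 0.32 * 3 / 3)
  g <- genes_tbl("TTCAAA")
  expect_equal(tai_of_gene(g, w)$tai, sqrt(2 / 3), tolerance = 1e-12)
})

test_that("penalty optimization is deterministic and rejects flat objectives", {
  pool <- withr::with_seed(7, {
    wp <- wobble_pairing_table("bacteria")
    tibble::tibble(anticodon = unique(wp$anticodon),
                   copies = sample(1:8, length(unique(wp$anticodon)),
                                   replace = TRUE))
  })
  w_true <- normalize_weights(absolute_weights(pool, domain = "bacteria"))
  host <- expression_driven_host(w_true, n_genes = 60, len = 150, seed = 2)

  o1 <- optimize_penalties(host, pool, free = "GU", n_restarts = 3, seed = 5)
  o2 <- optimize_penalties(host, pool, free = "GU", n_restarts = 3, seed = 5)
  expect_identical(o1$s, o2$s)
  expect_identical(o1$correlation, o2$correlation)

  flat <- genes_tbl(rep("ATGGGCAAATAA", 60),
                    ids = sprintf("f%02d", 1:60))
  expect_error(optimize_penalties(flat, pool), "constant")

  tiny <- host[1:10, ]
  expect_error(optimize_penalties(tiny, pool), "at least 50")
})

test_that("optimization attains a strong correlation on an expression-driven host", {
  pool <- withr::with_seed(7, {
    wp <- wobble_pairing_table("bacteria")
    tibble::tibble(anticodon = unique(wp$anticodon),
                   copies = sample(1:8, length(unique(wp$anticodon)),
                                   replace = TRUE))
  })
  w_true <- normalize_weights(absolute_weights(pool, domain = "bacteria"))
  host <- expression_driven_host(w_true, n_genes = 100, len = 300, seed = 3)
  opt <- optimize_penalties(host, pool, free = c("GU", "UG"),
                            n_restarts = 3, seed = 1)
  expect_gt(opt$correlation, 0.8)

  # the climb never ends below its default start
  cm <- codontempo:::codon_count_matrix(host)
  obj <- directional_codon_bias(host)$bias
  w0 <- normalize_weights(absolute_weights(pool, default_wobble_penalties(),
                                           "bacteria"))
  tai0 <- exp(as.vector(cm %*% log(w0$w)) / rowSums(cm))
  start_cor <- cor(tai0, obj, method = "spearman")
  expect_gte(opt$correlation, start_cor)
})

test_that("tRNA pool tables read and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("anticodon,copies", "GAA,4", "TTT,2"), path)
  pool <- read_trna_pool(path)
  expect_equal(pool$copies, c(4L, 2L))
  writeLines(c("anticodon,copies", "GAX,4"), path)
  expect_error(read_trna_pool(path), "triplets")
})
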