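test_that("gcContent counts unambiguous bases only", {
  expect_equal(gcContent("GGGCCC"), 1.0)
  expect_equal(gcContent("AAATTT"), 0.0)
  expect_equal(gcContent("GCGGCA"), 5 / 6)
  expect_equal(gcContent("GCNNNN"), 1.0)  # ambiguous bases excluded
  expect_error(gcContent(""), "empty")
})

test_that("RSCU matches its definition on hand-computed cases", {
  # uniform 4-fold family: every codon 1.0
  counts <- stats::setNames(integer(64), names(GENCODE11))
  counts[c("GCT", "GCC", "GCA", "GCG")] <- 3L
  r <- rscuValues(counts)
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
  # 2-fold family with one codon used: 2.0 / 0.0
  counts2 <- stats::setNames(integer(64), names(GENCODE11))
  counts2[c("AAA")] <- 7L
  r2 <- rscuValues(counts2)
  expect_equal(unname(r2["AAA"]), 2.0)
  expect_equal(unname(r2["AAG"]), 0.0)
  # Ala (2,1,1,0) -> (2,1,1,0)
  counts3 <- stats::setNames(integer(64), names(GENCODE11))
  counts3[c("GCT", "GCC", "GCA", "GCG")] <- c(2L, 1L, 1L, 0L)
  r3 <- rscuValues(counts3)
  expect_equal(unname(r3[c("GCT", "GCC", "GCA", "GCG")]), c(2, 1, 1, 0))
  # unused families are NA, mean RSCU of a used family is 1
  expect_true(is.na(r3["GGT"]))
  expect_equal(mean(r3[c("GCT", "GCC", "GCA", "GCG")]), 1)
})

test_that("rscuDeviation is 0 under identical usage, 1.5 for all-GCG Ala", {
  pool <- stats::setNames(integer(64), names(GENCODE11))
  pool[c("GCT", "GCC", "GCA", "GCG")] <- 10L
  gene_same <- stats::setNames(integer(64), names(GENCODE11))
  gene_same[c("GCT", "GCC", "GCA", "GCG")] <- 2L
  expect_equal(rscuDeviation(gene_same, pool), 0)
  gene_gcg <- stats::setNames(integer(64), names(GENCODE11))
  gene_gcg["GCG"] <- 5L
  expect_equal(rscuDeviation(gene_gcg, pool), 1.5)  # (|4-1|+1+1+1)/4
  # determinism / duplication invariance
  expect_identical(rscuDeviation(gene_gcg, pool),
                   rscuDeviation(gene_gcg, pool))
  # gene with no degenerate-family codons is undefined
  gene_mw <- stats::setNames(integer(64), names(GENCODE11))
  gene_mw[c("ATG", "TGG")] <- 4L
  expect_true(is.na(rscuDeviation(gene_mw, pool)))
})

test_that("ENC attains its analytic limits", {
  # maximal bias: one codon per family -> 20 exactly
  one_per <- stats::setNames(integer(64), names(GENCODE11))
  for (fam in .syn_families) one_per[fam[1]] <- 50L
  expect_equal(enc(one_per), 20)
  # uniform usage at large counts -> capped at 61
  unif <- stats::setNames(integer(64), names(GENCODE11))
  for (fam in .syn_families) unif[fam] <- 5000L
  expect_equal(enc(unif), 61)
  # missing 2-fold class -> undefined
  no2 <- stats::setNames(integer(64), names(GENCODE11))
  no2[c("GCT", "GCC", "GCA", "GCG")] <- 10L
  expect_true(is.na(enc(no2)))
})

test_that("CAI closed forms and degeneracies hold", {
  ref <- stats::setNames(integer(64), names(GENCODE11))
  ref[c("GCT", "GCC", "GCA", "GCG")] <- c(9L, 0L, 0L, 0L)
  ref[c("AAA", "AAG")] <- c(9L, 4L)
  # gene of only reference-preferred codons -> 1.0
  gene <- stats::setNames(integer(64), names(GENCODE11))
  gene[c("GCT", "AAA")] <- c(5L, 5L)
  expect_equal(cai(gene, ref), 1.0)
  # half preferred (w=1), half w=0.5 -> sqrt(0.5)
  gene2 <- stats::setNames(integer(64), names(GENCODE11))
  gene2[c("AAA", "AAG")] <- c(5L, 5L)
  expect_equal(cai(gene2, ref), exp(0.5 * log(0.5)), tolerance = 1e-12)
  # Met/Trp-only gene undefined
  gene3 <- stats::setNames(integer(64), names(GENCODE11))
  gene3[c("ATG", "TGG")] <- c(3L, 3L)
  expect_true(is.na(cai(gene3, ref)))
})

test_that("all four metrics match the brute-force oracle on random genes", {
  set.seed(42)
  pool <- stats::setNames(integer(64), names(GENCODE11))
  genes <- replicate(20, random_cds(sample(80:200, 1)))
  counts <- lapply(genes, codonCounts)
  for (cc in counts) pool <- pool + cc
  for (k in seq_along(genes)) {
    expect_equal(gcContent(genes[k]), oracle_gc(genes[k]), tolerance = 1e-9)
    expect_identical(counts[[k]], oracle_codon_counts(genes[k]))
    expect_equal(rscuDeviation(counts[[k]], pool),
                 oracle_rscu_dev(counts[[k]], pool), tolerance = 1e-9)
    expect_equal(enc(counts[[k]]), oracle_enc(counts[[k]]), tolerance = 1e-9)
    expect_equal(cai(counts[[k]], pool), oracle_cai(counts[[k]], pool),
                 tolerance = 1e-9)
  }
})

test_that("increasing synonymous bias never increases ENC", {
  # deterministic gradient: Lys family p from 0.5 (uniform) to 1.0
  base <- stats::setNames(integer(64), names(GENCODE11))
  for (fam in .syn_families) base[fam] <- 30L
  encs <- vapply(seq(0, 15, by = 3), function(shift) {
    cc <- base
    cc["AAA"] <- 30L + shift; cc["AAG"] <- 30L - shift
    enc(cc)
  }, numeric(1))
  expect_true(all(diff(encs) <= 1e-12))
})

test_that("reference pool out-scores random genes on CAI", {
  set.seed(99)
  tab <- defaultCodonTable()
  aaf <- defaultAAFreqs()
  joint <- piliscan:::.joint_codon_dist(tab, aaf)
  ref <- stats::setNames(round(joint * 1e5), names(joint))
  ref64 <- stats::setNames(integer(64), names(GENCODE11))
  ref64[names(ref)] <- as.integer(ref)
  ref_cai <- cai(ref64, ref64)
  rand_cais <- replicate(50, cai(codonCounts(random_cds(150)), ref64))
  expect_true(all(ref_cai >= rand_cais))
})

test_that("profileGenome filters flagged genes and ignores gene order", {
  sim <- simulateGenomes(simulationConfig(
    seed = 31, n_genomes = 1, n_background_genes = 40,
    loci_to_embed = list(list(template = "T4aP_nonfunctional",
                              target_identity = 0.9))))
  g <- sim$genomes[[1]]
  fs <- geneFlags(g)$gene_id[geneFlags(g)$frameshifted]
  expect_length(fs, 1L)
  pr <- profileGenome(g)
  expect_false(fs %in% pr$gene_id)
  expect_equal(nrow(pr), nGenes(g) - 1L)
  expect_true(all(is.finite(pr$gc)))
  # order invariance: reversing gene order yields the same profiles
  rc <- reverseComplementGenome(g)  # reverses gene order on the contig
  pr2 <- profileGenome(rc)
  pr2 <- pr2[match(pr$gene_id, pr2$gene_id), ]
  expect_equal(pr$gc, pr2$gc)
  expect_equal(pr$enc, pr2$enc)
  expect_equal(pr$rscu_dev, pr2$rscu_dev)
  expect_equal(pr$cai, pr2$cai)
  # a genome of fewer than 2 usable genes is rejected
  g1 <- toy_genome(list(list(cds = "ATGGCTTAA", strand = "+")))
  expect_error(profileGenome(g1), "at least 2")
})
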