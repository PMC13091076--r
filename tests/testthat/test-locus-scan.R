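fams <- makeReferenceFamilies(42)

test_that("a gene identical to a reference is assigned at identity 1", {
  cds <- as.character(fams$cds[["tadA"]])
  g <- toy_genome(c(list(list(cds = cds, strand = "+")),
                    replicate(3, list(cds = random_cds(120), strand = "+"),
                              simplify = FALSE)))
  asg <- assignFamilies(g, fams)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$family, "tadA")
  expect_equal(asg$identity, 1.0)
  expect_false(asg$pseudo)
})

test_that("random background genes receive no assignment", {
  set.seed(5)
  g <- toy_genome(replicate(10, list(cds = random_cds(150), strand = "+"),
                            simplify = FALSE))
  expect_equal(nrow(assignFamilies(g, fams)), 0L)
})

test_that("mutated genes recover family and realized identity", {
  sim <- simulateGenomes(simulationConfig(
    seed = 14, n_genomes = 1, n_background_genes = 30,
    loci_to_embed = list(list(template = "T4aP_functional",
                              target_identity = 0.8))))
  g <- sim$genomes[[1]]
  man <- sim$manifest$genomes[[1]]$loci[[1]]
  asg <- assignFamilies(g, sim$families)
  for (id in names(man$genes)) {
    row <- asg[asg$gene_id == id, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$family, man$genes[[id]])
    expect_equal(row$identity, 0.8, tolerance = 0.07)
  }
  # best-hit uniqueness: no gene assigned twice
  expect_false(anyDuplicated(asg$gene_id) > 0)
})

test_that("grouping merges runs, attaches distal tadV, counts scattered pilE", {
  sim <- simulateGenomes(simulationConfig(
    seed = 15, n_genomes = 1, n_background_genes = 40,
    loci_to_embed = list(list(template = "T4cP_canonical",
                              target_identity = 0.85),
                         list(template = "T4aP_functional",
                              target_identity = 0.85)),
    scattered_pilE = list(per_genome = 2L, alien_rate = 0)))
  sc <- scanGenome(sim$genomes[[1]], sim$families)
  systems <- vapply(sc$loci, locusSystem, character(1))
  expect_setequal(systems, c("T4cP", "T4aP"))
  t4cp <- sc$loci[[which(systems == "T4cP")]]
  expect_setequal(members(t4cp)$family,
                  c("tadZ", "tadA", "tadB", "tadC", "flp", "tadE", "tadF",
                    "tadV"))
  expect_true(t4cp@tadVDistal)
  t4ap <- sc$loci[[which(systems == "T4aP")]]
  expect_setequal(members(t4ap)$family,
                  c("pilB", "pilT", "pilE", "pilV", "pilW", "pilX", "pilC",
                    "pilD", "pilM", "pilN", "pilO"))
  expect_equal(t4ap@scatteredPrepilins, 2L)
  expect_equal(t4ap@extraPilE, 0L)
  # genome with no assignments yields no loci
  set.seed(2)
  g0 <- toy_genome(replicate(8, list(cds = random_cds(100), strand = "+"),
                             simplify = FALSE))
  expect_length(scanGenome(g0, fams)$loci, 0L)
})

test_that("every template is classified with its own label", {
  expected <- c(T4cP_canonical = "T4cP_canonical",
                T4cP_deltaC_inverted = "T4cP_deltaC_inverted",
                T4cP_deltaV = "T4cP_deltaV",
                T4aP_functional = "T4aP_functional",
                T4aP_nonfunctional = "T4aP_nonfunctional")
  for (tpl in names(expected)) {
    sim <- simulateGenomes(simulationConfig(
      seed = 16, n_genomes = 1, n_background_genes = 40,
      loci_to_embed = list(list(template = tpl, target_identity = 0.85))))
    sc <- scanGenome(sim$genomes[[1]], sim$families)
    sys <- if (grepl("^T4cP", tpl)) "T4cP" else "T4aP"
    loci <- Filter(function(l) locusSystem(l) == sys, sc$loci)
    expect_length(loci, 1L)
    expect_equal(classification(loci[[1]]), unname(expected[tpl]),
                 label = tpl)
  }
})

test_that("nonfunctional T4aP reports the pseudogenized member", {
  sim <- simulateGenomes(simulationConfig(
    seed = 17, n_genomes = 1, n_background_genes = 40,
    loci_to_embed = list(list(template = "T4aP_nonfunctional",
                              target_identity = 0.85))))
  sc <- scanGenome(sim$genomes[[1]], sim$families)
  l <- Filter(function(x) locusSystem(x) == "T4aP", sc$loci)[[1]]
  expect_equal(classification(l), "T4aP_nonfunctional")
  expect_true(any(grepl("^(pseudo|missing):pilC$", l@notes)))
})

test_that("an extra pilE inside the locus is counted", {
  sim <- simulateGenomes(simulationConfig(
    seed = 18, n_genomes = 1, n_background_genes = 40,
    loci_to_embed = list(list(template = "T4aP_functional",
                              target_identity = 0.9))))
  g <- sim$genomes[[1]]
  # duplicate the pilE gene right next to itself
  man <- sim$manifest$genomes[[1]]$loci[[1]]
  pile_id <- names(man$genes)[unlist(man$genes) == "pilE"]
  gr <- genes(g)
  i <- which(S4Vectors::mcols(gr)$gene_id == pile_id)
  specs <- lapply(seq_along(gr), function(k) list(
    cds = as.character(cdsSeqs(g)[[k]]),
    strand = as.character(GenomicRanges::strand(gr)[k])))
  specs <- append(specs, specs[i], after = i)
  g2 <- toy_genome(specs, genome_id = "dup")
  sc <- scanGenome(g2, sim$families)
  l <- Filter(function(x) locusSystem(x) == "T4aP", sc$loci)[[1]]
  expect_equal(l@extraPilE, 1L)
})

test_that("assignments and classifications are strand-invariant", {
  sim <- simulateGenomes(simulationConfig(
    seed = 19, n_genomes = 1, n_background_genes = 40,
    loci_to_embed = list(list(template = "T4cP_deltaC_inverted",
                              target_identity = 0.85))))
  g <- sim$genomes[[1]]
  sc1 <- scanGenome(g, sim$families)
  sc2 <- scanGenome(reverseComplementGenome(g), sim$families)
  a1 <- sc1$assignments[order(sc1$assignments$gene_id), ]
  a2 <- sc2$assignments[order(sc2$assignments$gene_id), ]
  expect_equal(a1$gene_id, a2$gene_id)
  expect_equal(a1$family, a2$family)
  expect_equal(a1$identity, a2$identity, tolerance = 1e-12)
  cls1 <- sort(vapply(sc1$loci, classification, character(1)))
  cls2 <- sort(vapply(sc2$loci, classification, character(1)))
  expect_equal(cls1, cls2)
  mem1 <- sort(members(sc1$loci[[1]])$gene_id)
  mem2 <- sort(members(sc2$loci[[1]])$gene_id)
  expect_equal(mem1, mem2)
})
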