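make_protein_genome <- function(genome_id, prots) {
  tab <- defaultCodonTable()
  specs <- lapply(prots, function(p)
    list(cds = piliscan:::.back_translate(p, tab), strand = "+"))
  toy_genome(specs, genome_id = genome_id)
}

test_that("identical proteins cluster, dissimilar ones stay singletons", {
  set.seed(41)
  shared <- paste0("M", paste(sample(names(defaultAAFreqs()), 199, TRUE),
                              collapse = ""))
  gl <- lapply(c("gA", "gB", "gC"), function(gid)
    make_protein_genome(gid, list(shared, paste0(
      "M", paste(sample(names(defaultAAFreqs()), 149, TRUE), collapse = "")))))
  names(gl) <- c("gA", "gB", "gC")
  ocs <- clusterOrthologs(gl)
  m <- as.data.frame(clusterTable(ocs))
  shared_ids <- m$cluster_id[m$gene_id %in% c("gA_g001", "gB_g001", "gC_g001")]
  expect_equal(length(unique(shared_ids)), 1L)
  expect_equal(sum(m$cluster_id == shared_ids[1]), 3L)
  # genome-private random proteins are singletons
  other <- m[m$gene_id == "gA_g002", "cluster_id"]
  expect_equal(sum(m$cluster_id == other), 1L)
  expect_error(clusterOrthologs(gl[1]), ">= 2 genomes")
})

test_that("family copies at 0.9 identity cluster across genomes", {
  sim <- simulateGenomes(simulationConfig(
    seed = 51, n_genomes = 4, n_background_genes = 30,
    shared_background_fraction = 0,
    loci_to_embed = list(list(template = "T4aP_functional",
                              target_identity = 0.9))))
  ocs <- clusterOrthologs(sim$genomes)
  m <- as.data.frame(clusterTable(ocs))
  # pilB copies of the 4 genomes form one 4-member cluster
  pilB_ids <- vapply(names(sim$genomes), function(gid) {
    man <- sim$manifest$genomes[[gid]]$loci[[1]]$genes
    names(man)[unlist(man) == "pilB"]
  }, character(1))
  cids <- m$cluster_id[m$gene_id %in% pilB_ids]
  expect_equal(length(unique(cids)), 1L)
  expect_equal(sum(m$cluster_id == cids[1]), 4L)
})

test_that("clustering is invariant to genome input order", {
  sim <- simulateGenomes(simulationConfig(
    seed = 52, n_genomes = 3, n_background_genes = 30))
  o1 <- clusterOrthologs(sim$genomes)
  o2 <- clusterOrthologs(rev(sim$genomes))
  key <- function(o) {
    m <- as.data.frame(clusterTable(o))
    grp <- split(paste(m$genome_id, m$gene_id), m$cluster_id)
    sort(vapply(grp, function(x) paste(sort(x), collapse = ";"), character(1)))
  }
  expect_identical(unname(key(o1)), unname(key(o2)))
})

test_that("core families require exactly one member in every genome", {
  mk <- function(cid, gid, gene) data.frame(cluster_id = cid, genome_id = gid,
                                            gene_id = gene)
  m <- rbind(
    mk("c1", "gA", "a1"), mk("c1", "gB", "b1"), mk("c1", "gC", "c1g"),
    mk("c2", "gA", "a2"), mk("c2", "gB", "b2"),                 # missing gC
    mk("c3", "gA", "a3"), mk("c3", "gA", "a3b"),                # paralog pair
    mk("c3", "gB", "b3"), mk("c3", "gC", "c3g"))
  ocs <- new("OrthologClusterSet", membership = S4Vectors::DataFrame(m),
             genomeIds = c("gA", "gB", "gC"))
  expect_equal(coreIds(coreFamilies(ocs)), "c1")
})

test_that("core distances average per-family p-distances", {
  # single family: d = 1 - identity; three families: mean of the three
  f <- makeReferenceFamilies(1)
  pA <- as.character(f$proteins[["tadA"]])
  gl <- list(gA = make_protein_genome("gA", list(pA)),
             gB = make_protein_genome("gB", list(pA)))
  ocs <- coreFamilies(clusterOrthologs(gl))
  d <- coreDistances(ocs, gl)
  expect_equal(unname(d["gA", "gB"]), 0)
  expect_equal(diag(d), c(gA = 0, gB = 0))
  # now three families with known pairwise identities
  set.seed(7)
  prots <- list(as.character(f$proteins[["tadA"]]),
                as.character(f$proteins[["pilB"]]),
                as.character(f$proteins[["pilM"]]))
  muts <- lapply(prots, piliscan:::.mutate_protein, identity = 0.9)
  gl3 <- list(gA = make_protein_genome("gA", prots),
              gB = make_protein_genome("gB", muts))
  ocs3 <- coreFamilies(clusterOrthologs(gl3))
  expect_length(coreIds(ocs3), 3L)
  d3 <- coreDistances(ocs3, gl3)
  per_fam <- vapply(1:3, function(i)
    1 - pairwiseIdentity(prots[[i]], muts[[i]])[["identity"]], numeric(1))
  expect_equal(unname(d3["gA", "gB"]), mean(per_fam), tolerance = 1e-12)
})

test_that("neighbor joining solves the 3-taxon closed form exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- ape::read.tree(text = njTree(d))
  bl <- stats::setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3), tolerance = 1e-12)
})

test_that("two taxa split the distance evenly", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  phy <- ape::read.tree(text = njTree(d))
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(phy$edge.length, c(1, 1))
})

test_that("NJ reconstructs 50 random additive 6-taxon trees exactly", {
  set.seed(77)
  for (k in 1:50) {
    case <- random_additive_case(6)
    mine <- ape::read.tree(text = njTree(case$d))
    expect_equal(ape::dist.topo(ape::unroot(mine), case$tree), 0,
                 ignore_attr = TRUE)
    # branch lengths also recovered (additivity)
    dm <- ape::cophenetic.phylo(mine)
    dm <- dm[rownames(case$d), colnames(case$d)]
    expect_equal(dm, case$d, tolerance = 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on additive input", {
  set.seed(78)
  for (k in 1:10) {
    case <- random_additive_case(7)
    mine <- ape::read.tree(text = njTree(case$d))
    ref <- ape::nj(stats::as.dist(case$d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("outgroup rooting splits the outgroup edge at its midpoint", {
  set.seed(79)
  case <- random_additive_case(6)
  out <- rownames(case$d)[1]
  phy <- ape::read.tree(text = njTree(case$d, outgroup = out))
  expect_true(ape::is.rooted(phy))
  root_children <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  expect_true(which(phy$tip.label == out) %in% root_children)
  e <- phy$edge.length[phy$edge[, 1] == length(phy$tip.label) + 1L]
  expect_equal(e[1], e[2], tolerance = 1e-9)
  expect_error(njTree(case$d, outgroup = "nope"), "not among taxa")
})

test_that("flank conservation returns the planted fraction exactly", {
  sim <- simulateGenomes(simulationConfig(
    seed = 61, n_genomes = 10, n_background_genes = 40,
    flank_conservation = 0.7))
  scans <- lapply(sim$genomes, scanGenome, families = sim$families)
  loci <- unlist(lapply(scans, `[[`, "loci"), recursive = FALSE)
  ocs <- clusterOrthologs(sim$genomes)
  nb <- flankConservation(loci, ocs, sim$genomes, system = "T4cP")
  expect_equal(nb$conservation, 0.7)
  conserved <- vapply(sim$manifest$genomes, function(x)
    x$flank_group == "conserved", logical(1))
  match_modal <- nb$pairs$upstream == nb$modal_pair[1] &
    nb$pairs$downstream == nb$modal_pair[2]
  expect_equal(sort(nb$pairs$genome_id[match_modal]),
               sort(names(conserved)[conserved]))
})

test_that("a locus at the contig edge records a 'none' flank", {
  f <- makeReferenceFamilies(42)
  tab <- defaultCodonTable()
  # locus genes first on the contig, one background gene after
  specs <- c(lapply(c("tadZ", "tadA", "tadB", "tadC", "flp", "tadE", "tadF"),
                    function(fam) list(
                      cds = as.character(f$cds[[fam]]), strand = "+")),
             list(list(cds = random_cds(150), strand = "+")))
  g1 <- toy_genome(specs, genome_id = "edge1")
  g2 <- toy_genome(specs, genome_id = "edge2")
  gl <- list(edge1 = g1, edge2 = g2)
  scans <- lapply(gl, scanGenome, families = f)
  loci <- unlist(lapply(scans, `[[`, "loci"), recursive = FALSE)
  ocs <- clusterOrthologs(gl)
  nb <- flankConservation(loci, ocs, gl, system = "T4cP")
  expect_true(all(nb$pairs$upstream == "none"))
  expect_equal(nb$conservation, 1.0)  # both genomes share (none, <cog>)
})
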