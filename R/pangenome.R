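#' @importFrom igraph graph_from_data_frame components V
NULL

# Markov clustering (expansion 2, configurable inflation) on a weighted
# adjacency matrix of one connected component. Returns an integer cluster
# label per node.
.mcl <- function(adj, inflation = 2, prune = 1e-6, tol = 1e-8,
                 max_iter = 100L) {
  n <- nrow(adj)
  if (n == 1L) return(1L)
  M <- adj
  diag(M) <- 1  # self loops stabilize the flow
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion (power 2)
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # clusters = connected components of the converged flow's support
  g <- igraph::graph_from_adjacency_matrix((M + t(M)) > 0, mode = "undirected")
  igraph::components(g)$membership
}

#' Cluster orthologs across genomes (COGs)
#'
#' All-vs-all global protein identities (with a k-mer prefilter to skip
#' obviously dissimilar pairs) define a similarity graph with edges where
#' identity >= \code{min_identity}; Markov clustering (expansion 2, the given
#' inflation, pruning 1e-6, convergence when the flow matrix changes by less
#' than 1e-8, at most 100 iterations), run per connected component, yields the
#' clusters. Genes joining no edge become singleton clusters. Frameshifted
#' genes are excluded.
#'
#' @param genomes named list of \code{\linkS4class{Genome}} (>= 2).
#' @param min_identity edge threshold (default 0.8).
#' @param inflation MCL inflation (default 2.0).
#' @param min_shared_kmers k-mer prefilter threshold.
#' @return an \code{\linkS4class{OrthologClusterSet}}.
#' @export
clusterOrthologs <- function(genomes, min_identity = 0.8, inflation = 2.0,
                             min_shared_kmers = 3L) {
  if (length(genomes) < 2L) stop("clusterOrthologs needs >= 2 genomes")
  tabs <- lapply(genomes, function(g) {
    fl <- geneFlags(g)
    keep <- !fl$frameshifted
    data.frame(genome_id = genomeId(g), gene_id = fl$gene_id[keep],
               protein = as.character(proteinSeqs(g))[keep],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  # stable gene order regardless of genome/gene input order
  tab <- tab[order(tab$genome_id, tab$gene_id), , drop = FALSE]
  n <- nrow(tab)
  cand <- .kmer_candidate_pairs(tab$protein, min_shared = min_shared_kmers)
  edges <- NULL
  if (nrow(cand) > 0L) {
    w <- .align_pairs(tab$protein[cand[, "i"]],
                      tab$protein[cand[, "j"]])$identity
    keep <- w >= min_identity
    edges <- data.frame(i = cand[keep, "i"], j = cand[keep, "j"],
                        w = w[keep])
  }
  labels <- paste(tab$genome_id, tab$gene_id, sep = "\r")
  cluster_of <- integer(n)
  next_id <- 0L
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = labels[edges$i], to = labels[edges$j],
                 weight = edges$w),
      directed = FALSE, vertices = data.frame(name = labels))
    comp <- igraph::components(g)$membership
    for (cc in sort(unique(comp))) {
      nodes <- which(comp == cc)
      if (length(nodes) == 1L) {
        next_id <- next_id + 1L
        cluster_of[nodes] <- next_id
        next
      }
      adj <- matrix(0, length(nodes), length(nodes))
      sub <- edges[edges$i %in% nodes & edges$j %in% nodes, , drop = FALSE]
      ii <- match(sub$i, nodes); jj <- match(sub$j, nodes)
      adj[cbind(ii, jj)] <- sub$w
      adj[cbind(jj, ii)] <- sub$w
      mem <- .mcl(adj, inflation = inflation)
      cluster_of[nodes] <- next_id + mem
      next_id <- next_id + max(mem)
    }
  } else {
    cluster_of <- seq_len(n)
    next_id <- n
  }
  membership <- DataFrame(
    cluster_id = sprintf("COG%05d", cluster_of),
    genome_id = tab$genome_id,
    gene_id = tab$gene_id)
  new("OrthologClusterSet", membership = membership,
      genomeIds = sort(vapply(genomes, genomeId, character(1),
                              USE.NAMES = FALSE)))
}

#' Single-copy core families
#'
#' Clusters with exactly one member in every genome (the strict single-copy
#' reading of "at least one single protein member for each genome", the usual
#' core-genome convention): a cluster missing a genome, or holding a paralog
#' pair in any genome, is not core.
#'
#' @param ocs an \code{\linkS4class{OrthologClusterSet}}.
#' @return the set with \code{coreIds} filled in.
#' @export
coreFamilies <- function(ocs) {
  m <- as.data.frame(clusterTable(ocs))
  gs <- ocs@genomeIds
  tab <- table(m$cluster_id, m$genome_id)
  ok <- rownames(tab)[apply(tab, 1, function(r)
    all(gs %in% colnames(tab)[r == 1]) && sum(r) == length(gs))]
  ocs@coreIds <- sort(ok)
  validObject(ocs)
  ocs
}

#' Core-genome distance matrix
#'
#' For each pair of genomes, the mean over single-copy core families of the
#' protein p-distance (1 - global pairwise identity). This replaces multiple
#' alignment and concatenation with averaged per-family pairwise distances,
#' an equivalent input to distance-based tree building at this scale.
#'
#' @param ocs an \code{\linkS4class{OrthologClusterSet}} with core families.
#' @param genomes named list of \code{\linkS4class{Genome}}.
#' @return symmetric distance matrix with zero diagonal, genome ids as
#'   dimnames.
#' @export
coreDistances <- function(ocs, genomes) {
  core <- coreIds(ocs)
  if (length(core) == 0L) stop("no core families")
  gs <- ocs@genomeIds
  prots <- lapply(genomes, function(g)
    setNames(as.character(proteinSeqs(g)), geneFlags(g)$gene_id))
  names(prots) <- vapply(genomes, genomeId, character(1))
  m <- as.data.frame(clusterTable(ocs))
  ng <- length(gs)
  d <- matrix(0, ng, ng, dimnames = list(gs, gs))
  fam_seqs <- lapply(core, function(cid) {
    rows <- m[m$cluster_id == cid, , drop = FALSE]
    setNames(vapply(seq_len(nrow(rows)), function(k)
      prots[[rows$genome_id[k]]][[rows$gene_id[k]]], character(1)),
      rows$genome_id)
  })
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    a <- vapply(fam_seqs, `[[`, character(1), gs[i])
    b <- vapply(fam_seqs, `[[`, character(1), gs[j])
    pid <- .align_pairs(a, b)$identity
    d[i, j] <- mean(1 - pid)
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  stopifnot(isSymmetric(d), all(diag(d) == 0))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. Negative branch
#' lengths are clamped to zero with the excess transferred to the sister
#' branch (preserving the pair distance). With 2 taxa the distance is split
#' evenly. When an outgroup is given the unrooted tree is rooted at the
#' midpoint of the outgroup's pendant edge.
#'
#' @param d symmetric distance matrix with taxa as dimnames.
#' @param outgroup optional taxon name to root on.
#' @return Newick string (terminated by \code{;}).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)  # branches 1, 1, 3
#' @export
njTree <- function(d, outgroup = NULL) {
  stopifnot(is.matrix(d), isSymmetric(unname(d)),
            !is.null(rownames(d)))
  taxa <- rownames(d)
  if (!is.null(outgroup) && !outgroup %in% taxa)
    stop("outgroup '", outgroup, "' not among taxa")
  n <- length(taxa)
  if (n < 2L) stop("need >= 2 taxa")
  frag <- taxa
  D <- unname(d)
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (n > 3L) {
    r <- rowSums(D) / (n - 2)
    Q <- D - outer(r, r, `+`)
    diag(Q) <- Inf
    k <- which.min(Q)  # deterministic: first minimum in column-major order
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- 0.5 * D[i, j] + 0.5 * (r[i] - r[j])
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], format(ll[1], digits = 15),
                       frag[j], format(ll[2], digits = 15))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
    n <- n - 1L
  }
  nwk <- if (n == 2L) {
    sprintf("(%s:%s,%s:%s);", frag[1], format(D[1, 2] / 2, digits = 15),
            frag[2], format(D[1, 2] / 2, digits = 15))
  } else {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);",
            frag[1], format(max(l1, 0), digits = 15),
            frag[2], format(max(l2, 0), digits = 15),
            frag[3], format(max(l3, 0), digits = 15))
  }
  if (is.null(outgroup)) return(nwk)
  phy <- ape::read.tree(text = nwk)
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  tipn <- which(rooted$tip.label == outgroup)
  rootn <- length(rooted$tip.label) + 1L
  oge <- which(rooted$edge[, 1] == rootn & rooted$edge[, 2] == tipn)
  sbe <- which(rooted$edge[, 1] == rootn & rooted$edge[, 2] != tipn)
  if (length(oge) == 1L && length(sbe) == 1L) {
    tot <- rooted$edge.length[oge] + rooted$edge.length[sbe]
    rooted$edge.length[oge] <- tot / 2
    rooted$edge.length[sbe] <- tot / 2
  }
  ape::write.tree(rooted)
}

#' Conservation of the genes flanking detected loci
#'
#' For each genome's locus of the queried system, takes the nearest non-locus
#' gene on each side of the contiguous locus extent (distally attached tadV
#' and scattered prepilins are not part of the extent), maps it to its COG,
#' and reports the fraction of genomes whose (upstream, downstream) COG pair
#' equals the modal pair. Pairs are orientation-normalized: for a locus on the
#' minus strand (modal member strand) upstream and downstream are swapped.
#' Contig-edge flanks are recorded as \code{"none"}. Modal-pair ties break to
#' the lexicographically smallest pair.
#'
#' @param loci list of classified \code{\linkS4class{LocusModel}} (all
#'   genomes).
#' @param ocs an \code{\linkS4class{OrthologClusterSet}}.
#' @param genomes named list of \code{\linkS4class{Genome}}.
#' @param system \code{"T4cP"} (default) or \code{"T4aP"}.
#' @return list with \code{pairs} (data.frame genome_id, upstream, downstream),
#'   \code{modal_pair}, and \code{conservation} in [0, 1].
#' @export
flankConservation <- function(loci, ocs, genomes, system = "T4cP") {
  m <- as.data.frame(clusterTable(ocs))
  cog_of <- setNames(m$cluster_id, paste(m$genome_id, m$gene_id, sep = "\r"))
  rows <- list()
  for (g in genomes) {
    gid <- genomeId(g)
    ls <- Filter(function(l) l@genomeId == gid && l@system == system, loci)
    if (length(ls) == 0L) next
    l <- ls[[1]]
    mem <- as.data.frame(members(l))
    mem <- mem[!mem$distal, , drop = FALSE]
    ct <- mem$contig[1]
    gr <- genes(g)
    on_ct <- which(as.character(seqnames(gr)) == ct)
    ids_ct <- geneFlags(g)$gene_id[on_ct]  # genes sorted by start
    idx <- range(mem$gene_index)
    up_i <- idx[1] - 1L; dn_i <- idx[2] + 1L
    cog_at <- function(i) {
      if (i < 1L || i > length(ids_ct)) return("none")
      key <- paste(gid, ids_ct[i], sep = "\r")
      if (is.na(cog_of[key])) "none" else unname(cog_of[key])
    }
    up <- cog_at(up_i); dn <- cog_at(dn_i)
    modal_strand <- names(sort(table(mem$strand), decreasing = TRUE))[1]
    if (modal_strand == "-") { tmp <- up; up <- dn; dn <- tmp }
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = gid, upstream = up, downstream = dn,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no genome has a detected locus of system ", system)
  pairs <- do.call(rbind, rows)
  key <- paste(pairs$upstream, pairs$downstream, sep = "|")
  tb <- table(key)
  best <- sort(names(tb)[tb == max(tb)])[1]
  list(pairs = pairs,
       modal_pair = strsplit(best, "|", fixed = TRUE)[[1]],
       conservation = unname(max(tb)) / nrow(pairs))
}
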