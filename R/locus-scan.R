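.T4CP_CLUSTER <- c("tadZ", "tadA", "tadB", "tadC", "flp", "tadE", "tadF")
.T4AP_FAMILIES <- c("pilT", "pilB", "pilV", "pilW", "pilE", "pilC", "pilX",
                    "pilD", "pilM", "pilN", "pilO")

#' Assign genes to reference T4P families
#'
#' Aligns genome proteins globally (BLOSUM62, affine gaps) against every
#' reference family protein and keeps, per gene, the best-scoring family when
#' identity >= \code{min_id} and reference coverage >= \code{min_cov}.
#' Identity is matches over alignment columns excluding terminal gaps. A
#' candidate k-mer prefilter skips gene/family pairs sharing fewer than
#' \code{min_shared_kmers} distinct 4-mers; detectably similar pairs always
#' share many. Pseudogene status (\code{pseudo}) is propagated from the
#' genome's frameshift/internal-stop flags or set when coverage < 0.5.
#'
#' @param genome a \code{\linkS4class{Genome}}.
#' @param families reference set from \code{\link{makeReferenceFamilies}}, or
#'   any named \code{AAStringSet} (then all families are treated by name).
#' @param min_id minimum identity (default 0.4, tolerant of genus-level
#'   divergence).
#' @param min_cov minimum reference coverage (default 0.6).
#' @param prefilter use the k-mer candidate prefilter (default TRUE).
#' @param min_shared_kmers prefilter threshold.
#' @return data.frame: \code{gene_id}, \code{family}, \code{identity},
#'   \code{coverage}, \code{pseudo}, \code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{gene_index} (rank of the gene along its contig).
#' @export
assignFamilies <- function(genome, families, min_id = 0.4, min_cov = 0.6,
                           prefilter = TRUE, min_shared_kmers = 3L) {
  ref <- if (is(families, "AAStringSet")) families else families$proteins
  stopifnot(length(ref) > 0L, !is.null(names(ref)))
  empty <- data.frame(gene_id = character(0), family = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      pseudo = logical(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), gene_index = integer(0),
                      stringsAsFactors = FALSE)
  if (nGenes(genome) == 0L) return(empty)
  prots <- as.character(proteinSeqs(genome))
  cand <- if (prefilter)
    .kmer_candidates_vs(prots, as.character(ref),
                        min_shared = min_shared_kmers)
  else as.matrix(expand.grid(q = seq_along(prots), r = seq_along(ref)))
  if (nrow(cand) == 0L) return(empty)
  st <- .align_pairs(unname(prots[cand[, "q"]]),
                     as.character(ref)[cand[, "r"]])
  hits <- data.frame(q = cand[, "q"], family = names(ref)[cand[, "r"]],
                     identity = st$identity, coverage = st$coverage,
                     score = st$score, stringsAsFactors = FALSE)
  # best family per gene by alignment score (uniqueness), then thresholds
  hits <- hits[order(hits$q, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(hits$q), , drop = FALSE]
  hits <- hits[hits$identity >= min_id & hits$coverage >= min_cov, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  gr <- genes(genome)
  fl <- geneFlags(genome)
  cn <- as.character(seqnames(gr))
  gene_index <- stats::ave(seq_along(gr), cn, FUN = seq_along)
  i <- hits$q
  out <- data.frame(
    gene_id = fl$gene_id[i],
    family = hits$family,
    identity = hits$identity,
    coverage = hits$coverage,
    pseudo = fl$frameshifted[i] | fl$pseudogenized[i] | hits$coverage < 0.5,
    contig = cn[i],
    start = start(gr)[i],
    end = end(gr)[i],
    strand = as.character(strand(gr))[i],
    gene_index = gene_index[i],
    stringsAsFactors = FALSE)
  out[order(out$contig, out$start), , drop = FALSE]
}

.system_of <- function(family) ifelse(grepl("^pil", family), "T4aP", "T4cP")

.new_locus <- function(genome_id, system, member_rows, idx) {
  m <- member_rows[order(member_rows$start), , drop = FALSE]
  m$system <- NULL
  new("LocusModel",
      locusId = sprintf("%s_%s_%02d", genome_id, system, idx),
      genomeId = genome_id, system = system,
      members = DataFrame(m),
      extraPilE = max(0L, sum(m$family == "pilE") - 1L))
}

#' Group family assignments into loci
#'
#' Same-system assignments on one contig separated by at most
#' \code{max_gap_genes} intervening unassigned genes are merged into one
#' locus. Two special rules reflect the observed architectures: tadV is exempt
#' from the proximity rule and is attached to the nearest T4cP locus on its
#' contig, with \code{tadVDistal} TRUE when more than \code{max_gap_genes}
#' genes intervene (the prepilin peptidase is consistently encoded outside the
#' Tad cluster); and pilE assignments farther than \code{max_gap_genes} from
#' any T4aP locus are not loci of their own but are counted as scattered
#' prepilins on the nearest T4aP locus of the genome.
#'
#' @param assignments data.frame from \code{\link{assignFamilies}}.
#' @param genome the corresponding \code{\linkS4class{Genome}}.
#' @param max_gap_genes locus adjacency threshold (default 5).
#' @return list of unclassified \code{\linkS4class{LocusModel}}.
#' @export
groupLoci <- function(assignments, genome, max_gap_genes = 5L) {
  gid <- genomeId(genome)
  loci <- list()
  if (nrow(assignments) == 0L) return(loci)
  a <- assignments
  a$system <- .system_of(a$family)
  a$distal <- FALSE
  core <- a[!(a$family == "tadV"), , drop = FALSE]
  scattered <- list(T4aP = 0L)
  counter <- list(T4cP = 0L, T4aP = 0L)
  pend_scattered <- 0L
  for (ct in unique(core$contig)) {
    for (sys in c("T4cP", "T4aP")) {
      sel <- core[core$contig == ct & core$system == sys, , drop = FALSE]
      if (nrow(sel) == 0L) next
      sel <- sel[order(sel$gene_index), , drop = FALSE]
      run <- cumsum(c(1L, diff(sel$gene_index) > max_gap_genes + 1L))
      for (rr in unique(run)) {
        rows <- sel[run == rr, , drop = FALSE]
        if (sys == "T4aP" && all(rows$family == "pilE")) {
          pend_scattered <- pend_scattered + nrow(rows)
          next
        }
        counter[[sys]] <- counter[[sys]] + 1L
        loci[[length(loci) + 1L]] <-
          .new_locus(gid, sys, rows, counter[[sys]])
      }
    }
  }
  # attach tadV to the nearest T4cP locus on the same contig
  tadv <- a[a$family == "tadV", , drop = FALSE]
  if (nrow(tadv) > 0L && length(loci) > 0L) {
    for (k in seq_len(nrow(tadv))) {
      t4cp <- which(vapply(loci, function(l)
        l@system == "T4cP" && members(l)$contig[1] == tadv$contig[k],
        logical(1)))
      if (length(t4cp) == 0L) next
      gaps <- vapply(t4cp, function(j) {
        idx <- members(loci[[j]])$gene_index
        min(abs(tadv$gene_index[k] - range(idx))) - 1L
      }, numeric(1))
      j <- t4cp[which.min(gaps)]
      row <- tadv[k, , drop = FALSE]
      row$distal <- gaps[which.min(gaps)] > max_gap_genes
      m <- rbind(as.data.frame(members(loci[[j]])), row[, colnames(row) !=
                 "system", drop = FALSE])
      loci[[j]]@members <- DataFrame(m[order(m$start), , drop = FALSE])
      loci[[j]]@tadVDistal <- any(loci[[j]]@members$distal)
    }
  }
  # scattered pilE attributed to the nearest T4aP locus of the genome
  if (pend_scattered > 0L) {
    t4ap <- which(vapply(loci, function(l) l@system == "T4aP", logical(1)))
    if (length(t4ap) > 0L)
      loci[[t4ap[1]]]@scatteredPrepilins <- as.integer(pend_scattered)
  }
  loci
}

#' Classify a T4cP (Tad) locus architecture
#'
#' \code{T4cP_canonical}: tadZ, tadA, tadB, tadC, flp, tadE and tadF all
#' present. \code{T4cP_deltaC_inverted}: tadC absent and the prepilin/
#' pseudopilin sub-cluster (flp, tadE, tadF) inverted -- opposite strand or
#' reversed order -- relative to the tadZ/tadA/tadB sub-cluster.
#' \code{T4cP_deltaV}: no tadV attached to the locus (the peptidase is absent
#' genome-wide, since tadV is attached regardless of distance). When the tadC
#' and tadV variants co-occur the deltaC label wins and \code{deltaV} is
#' recorded in \code{notes}.
#'
#' @param locus a T4cP \code{\linkS4class{LocusModel}}.
#' @return the locus with \code{classification} and \code{notes} filled in.
#' @export
classifyT4cP <- function(locus) {
  if (locus@system != "T4cP") stop("classifyT4cP expects a T4cP locus")
  m <- as.data.frame(members(locus))
  fams <- m$family
  notes <- character(0)
  missing7 <- setdiff(.T4CP_CLUSTER, fams)
  if (length(missing7))
    notes <- c(notes, paste0("missing:", missing7))
  has_tadC <- "tadC" %in% fams
  has_tadV <- "tadV" %in% fams
  zab <- m[m$family %in% c("tadZ", "tadA", "tadB"), , drop = FALSE]
  pp <- m[m$family %in% c("flp", "tadE", "tadF"), , drop = FALSE]
  inverted <- FALSE
  if (nrow(zab) > 0L && nrow(pp) > 0L) {
    modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    s_zab <- modal(zab$strand); s_pp <- modal(pp$strand)
    if (s_zab != s_pp) inverted <- TRUE
    else if (nrow(pp) >= 2L) {
      ord <- pp$family[order(pp$start)]
      if (s_zab == "-") ord <- rev(ord)
      expected <- intersect(c("flp", "tadE", "tadF"), ord)
      if (identical(ord, rev(expected)) && !identical(ord, expected))
        inverted <- TRUE
    }
  }
  if (inverted) notes <- c(notes, "inverted_prepilin_cluster")
  if (!has_tadV) notes <- c(notes, "deltaV")
  cls <- if (!has_tadC && inverted) "T4cP_deltaC_inverted"
         else if (!has_tadV) "T4cP_deltaV"
         else "T4cP_canonical"
  locus@classification <- cls
  locus@notes <- notes
  validObject(locus)
  locus
}

#' Classify a T4aP locus architecture
#'
#' \code{T4aP_functional} requires all 11 families present, no pseudogenized
#' member, and the observed strand layout: pilB and pilT together on one
#' strand and the remaining nine genes on the opposite strand.
#' Otherwise \code{T4aP_nonfunctional}, with the reasons (missing families,
#' pseudogenes, strand layout) listed in \code{notes}. \code{extraPilE}
#' reports pilE copies in the locus beyond the first.
#'
#' @param locus a T4aP \code{\linkS4class{LocusModel}}.
#' @return the locus with \code{classification} and \code{notes} filled in.
#' @export
classifyT4aP <- function(locus) {
  if (locus@system != "T4aP") stop("classifyT4aP expects a T4aP locus")
  m <- as.data.frame(members(locus))
  notes <- character(0)
  missing11 <- setdiff(.T4AP_FAMILIES, m$family)
  if (length(missing11)) notes <- c(notes, paste0("missing:", missing11))
  ps <- m$family[m$pseudo]
  if (length(ps)) notes <- c(notes, paste0("pseudo:", sort(unique(ps))))
  motor <- m$strand[m$family %in% c("pilB", "pilT")]
  rest <- m$strand[!m$family %in% c("pilB", "pilT")]
  layout_ok <- length(motor) > 0L && length(rest) > 0L &&
    length(unique(motor)) == 1L && length(unique(rest)) == 1L &&
    motor[1] != rest[1]
  if (!layout_ok) notes <- c(notes, "strand_layout")
  locus@classification <- if (length(missing11) == 0L && length(ps) == 0L &&
                              layout_ok) "T4aP_functional"
                          else "T4aP_nonfunctional"
  locus@notes <- notes
  validObject(locus)
  locus
}

#' Detect and classify all T4P loci of a genome
#'
#' Runs \code{\link{assignFamilies}}, \code{\link{groupLoci}} and the two
#' architecture classifiers.
#'
#' @inheritParams assignFamilies
#' @inheritParams groupLoci
#' @return list with \code{assignments} (data.frame) and \code{loci}
#'   (classified \code{\linkS4class{LocusModel}} list).
#' @export
scanGenome <- function(genome, families, min_id = 0.4, min_cov = 0.6,
                       max_gap_genes = 5L, prefilter = TRUE) {
  asg <- assignFamilies(genome, families, min_id = min_id, min_cov = min_cov,
                        prefilter = prefilter)
  loci <- groupLoci(asg, genome, max_gap_genes = max_gap_genes)
  loci <- lapply(loci, function(l)
    if (l@system == "T4cP") classifyT4cP(l) else classifyT4aP(l))
  list(assignments = asg, loci = loci)
}
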