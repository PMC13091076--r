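#' @importFrom Biostrings oligonucleotideFrequency letterFrequency
NULL

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguous bases are excluded from both
#' numerator and denominator. Computed on the full CDS (all three codon
#' positions).
#'
#' @param cds_nt nucleotide sequence (character or \code{DNAString}).
#' @return fraction in [0, 1].
#' @examples
#' gcContent("GCGGCC")  # 5/6
#' @export
gcContent <- function(cds_nt) {
  s <- DNAString(as.character(cds_nt))
  if (length(s) == 0L) stop("empty sequence")
  counts <- letterFrequency(s, c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((counts["G"] + counts["C"]) / denom)
}

#' Codon counts of a CDS
#'
#' Counts the \code{floor(length/3)} codons of a CDS (incomplete terminal
#' codons of frameshifted records are dropped). Stop codons are counted here
#' but excluded from every downstream metric.
#'
#' @param cds_nt nucleotide sequence.
#' @return named integer vector over the 64 codons.
#' @export
codonCounts <- function(cds_nt) {
  s <- DNAString(as.character(cds_nt))
  usable <- (length(s) %/% 3L) * 3L
  if (usable == 0L)
    return(setNames(integer(64), names(.code11())))
  cc <- oligonucleotideFrequency(subseq(s, 1L, usable), width = 3L, step = 3L)
  cc[names(.code11())]
}

#' Relative synonymous codon usage
#'
#' For codon j of amino acid i with synonymous family size n_i >= 2,
#' RSCU_ij = X_ij / ((1/n_i) * sum_k X_ik): the observed count over the count
#' expected under uniform synonymous usage. Met, Trp and stop codons are
#' excluded; families with zero total usage get NA.
#'
#' @param counts codon counts (see \code{\link{codonCounts}}); any gene or
#'   pooled gene set.
#' @return named numeric vector over the 59 degenerate-family codons.
#' @export
rscuValues <- function(counts) {
  info <- .codon_info()
  out <- numeric(0)
  for (a in info$degenerate_aas) {
    cs <- info$families[[a]]
    tot <- sum(counts[cs])
    out[cs] <- if (tot == 0) NA_real_
               else counts[cs] / (tot / length(cs))
  }
  out
}

#' Per-gene RSCU deviation from the genome background
#'
#' Scalarizes codon-usage atypicality as the mean absolute difference between
#' the gene's RSCU and the genome pool's RSCU, averaged over the codons of
#' the degenerate amino-acid families actually present in the gene. A gene
#' whose usage matches the genome exactly scores 0.
#'
#' @param gene_counts codon counts of the gene.
#' @param pool_counts summed codon counts of the genome's usable genes.
#' @return non-negative scalar, or NA if the gene uses no degenerate family.
#' @export
rscuDeviation <- function(gene_counts, pool_counts) {
  info <- .codon_info()
  rg <- rscuValues(gene_counts)
  rp <- rscuValues(pool_counts)
  # codons of degenerate families present in the gene; families unused in the
  # pool (possible only when the gene itself is outside the pool) are skipped
  cods <- character(0)
  for (a in info$degenerate_aas) {
    cs <- info$families[[a]]
    if (sum(gene_counts[cs]) > 0 && sum(pool_counts[cs]) > 0)
      cods <- c(cods, cs)
  }
  if (length(cods) == 0L) return(NA_real_)
  mean(abs(rg[cods] - rp[cods]))
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator of codon-usage bias: for each amino acid with total
#' count n >= 2, the homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1); F
#' values are averaged within degeneracy classes k in {2, 3, 4, 6} (families
#' with F = 0, possible at very small n, are treated as unobserved), and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61. A missing 3-fold class
#' (isoleucine absent) is imputed as (F2 + F4)/2; if the 2-, 4- or 6-fold
#' class is missing the estimate is undefined (NA).
#'
#' @param counts codon counts of one gene.
#' @return ENC in [20, 61], or NA when undefined.
#' @export
enc <- function(counts) {
  info <- .codon_info()
  Fhat <- c(); ksz <- c()
  for (a in info$degenerate_aas) {
    cs <- info$families[[a]]
    x <- counts[cs]
    ntot <- sum(x)
    if (ntot < 2) next
    p <- x / ntot
    f <- (ntot * sum(p^2) - 1) / (ntot - 1)
    if (f <= 0) next
    Fhat <- c(Fhat, f); ksz <- c(ksz, length(cs))
  }
  Fbar <- function(k) if (any(ksz == k)) mean(Fhat[ksz == k]) else NA_real_
  F2 <- Fbar(2); F3 <- Fbar(3); F4 <- Fbar(4); F6 <- Fbar(6)
  if (is.na(F2) || is.na(F4) || is.na(F6)) return(NA_real_)
  if (is.na(F3)) F3 <- (F2 + F4) / 2
  val <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(val, 61)
}

#' Codon adaptation index
#'
#' Relative adaptiveness of codon j of amino acid i is
#' w_ij = (X_ij + 1) / (X_imax + 1) computed from the reference pool (the
#' pseudocount avoids log(0) for codons unseen in the reference); the CAI of
#' a gene is the geometric mean of w over its codons in degenerate families.
#' Met, Trp and stops are excluded. A gene with no such codons is undefined.
#'
#' @param counts codon counts of the gene.
#' @param reference_counts summed codon counts of the reference pool (by
#'   default the whole genome's CDS pool, see \code{\link{profileGenome}}).
#' @return CAI in (0, 1], or NA when undefined.
#' @export
cai <- function(counts, reference_counts) {
  info <- .codon_info()
  lw_sum <- 0; L <- 0L
  for (a in info$degenerate_aas) {
    cs <- info$families[[a]]
    x <- counts[cs]
    if (sum(x) == 0) next
    w <- (reference_counts[cs] + 1) / (max(reference_counts[cs]) + 1)
    lw_sum <- lw_sum + sum(x * log(w))
    L <- L + sum(x)
  }
  if (L == 0L) return(NA_real_)
  exp(lw_sum / L)
}

#' Per-gene codon profiles for a genome
#'
#' Computes GC content, RSCU deviation, ENC and CAI for every non-frameshifted
#' gene, against a genome background pool that excludes frameshifted and
#' pseudogenized records. The CAI reference is that same pool (no curated
#' highly-expressed set is assumed; pass \code{reference_pool} to override).
#'
#' @param genome a \code{\linkS4class{Genome}} with at least 2 usable genes.
#' @param reference_pool optional codon-count vector to use as CAI reference.
#' @return \code{data.frame} with columns \code{gene_id}, \code{gc},
#'   \code{rscu_dev}, \code{enc}, \code{cai}.
#' @export
profileGenome <- function(genome, reference_pool = NULL) {
  stopifnot(is(genome, "Genome"))
  fl <- genome@geneFlags
  usable <- !fl$frameshifted & !fl$pseudogenized
  if (sum(usable) < 2L)
    stop("profileGenome needs at least 2 usable (non-flagged) genes")
  keep <- !fl$frameshifted
  cds <- genome@cds
  counts <- lapply(as.character(cds), codonCounts)
  names(counts) <- names(cds)
  pool <- Reduce(`+`, counts[fl$gene_id[usable]])
  ref <- if (is.null(reference_pool)) pool else reference_pool
  ids <- fl$gene_id[keep]
  data.frame(
    gene_id = ids,
    gc = vapply(as.character(cds[ids]), gcContent, numeric(1),
                USE.NAMES = FALSE),
    rscu_dev = vapply(ids, function(i) rscuDeviation(counts[[i]], pool),
                      numeric(1), USE.NAMES = FALSE),
    enc = vapply(ids, function(i) enc(counts[[i]]), numeric(1),
                 USE.NAMES = FALSE),
    cai = vapply(ids, function(i) cai(counts[[i]], ref), numeric(1),
                 USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
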