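# Independent brute-force oracles and tiny fixture builders. The oracles are
# deliberately naive (explicit loops over the genetic code, no shared helpers
# with the package) so they constitute an independent computation path.

GENCODE11 <- Biostrings::getGeneticCode("11")

# --- naive codon-metric oracles ---------------------------------------------

oracle_codon_counts <- function(cds) {
  n <- floor(nchar(cds) / 3)
  counts <- stats::setNames(integer(64), names(GENCODE11))
  for (i in seq_len(n)) {
    cod <- substr(cds, 3 * i - 2, 3 * i)
    counts[cod] <- counts[cod] + 1L
  }
  counts
}

oracle_gc <- function(cds) {
  ch <- strsplit(cds, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

.syn_families <- local({
  aa <- GENCODE11
  fam <- split(names(aa)[aa != "*"], aa[aa != "*"])
  fam[vapply(fam, length, integer(1)) >= 2]
})

oracle_rscu <- function(counts) {
  out <- numeric(0)
  for (fam in .syn_families) {
    tot <- sum(counts[fam])
    for (cod in fam)
      out[cod] <- if (tot == 0) NA_real_ else
        counts[cod] / (tot / length(fam))
  }
  out
}

oracle_rscu_dev <- function(gene_counts, pool_counts) {
  rg <- oracle_rscu(gene_counts); rp <- oracle_rscu(pool_counts)
  total <- 0; nc <- 0
  for (fam in .syn_families) {
    if (sum(gene_counts[fam]) == 0 || sum(pool_counts[fam]) == 0) next
    for (cod in fam) {
      total <- total + abs(rg[cod] - rp[cod])
      nc <- nc + 1
    }
  }
  if (nc == 0) NA_real_ else unname(total / nc)
}

oracle_enc <- function(counts) {
  Fs <- list()
  for (fam in .syn_families) {
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    Fv <- (n * sum(p^2) - 1) / (n - 1)
    if (Fv <= 0) next
    k <- as.character(length(fam))
    Fs[[k]] <- c(Fs[[k]], Fv)
  }
  Fbar <- function(k) if (is.null(Fs[[k]])) NA_real_ else mean(Fs[[k]])
  F2 <- Fbar("2"); F3 <- Fbar("3"); F4 <- Fbar("4"); F6 <- Fbar("6")
  if (is.na(F2) || is.na(F4) || is.na(F6)) return(NA_real_)
  if (is.na(F3)) F3 <- (F2 + F4) / 2
  min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
}

oracle_cai <- function(counts, ref) {
  s <- 0; L <- 0
  for (fam in .syn_families) {
    if (sum(counts[fam]) == 0) next
    wmax <- max(ref[fam]) + 1
    for (cod in fam) {
      w <- (ref[cod] + 1) / wmax
      s <- s + counts[cod] * log(w)
      L <- L + counts[cod]
    }
  }
  if (L == 0) NA_real_ else unname(exp(s / L))
}

# random in-frame CDS (ATG ... TAA, no internal stop) of n codons
random_cds <- function(n_codons) {
  sense <- names(GENCODE11)[GENCODE11 != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

# --- tiny genome builders ----------------------------------------------------

# Build a single-contig Genome from a list of list(cds=, strand=) specs with
# fixed 20 nt spacers.
toy_genome <- function(gene_specs, genome_id = "toy", spacer = 20L) {
  set_piece <- function(n) paste(rep("T", n), collapse = "")
  pos <- 0L; pieces <- character(0)
  starts <- integer(0); ends <- integer(0)
  for (sp in gene_specs) {
    placed <- if (identical(sp$strand, "-"))
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp$cds)))
    else sp$cds
    pieces <- c(pieces, set_piece(spacer), placed)
    starts <- c(starts, pos + spacer + 1L)
    ends <- c(ends, pos + spacer + nchar(sp$cds))
    pos <- pos + spacer + nchar(sp$cds)
  }
  pieces <- c(pieces, set_piece(spacer))
  contig <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(contig) <- paste0(genome_id, "_c1")
  gr <- GenomicRanges::GRanges(
    seqnames = names(contig),
    ranges = IRanges::IRanges(starts, ends),
    strand = vapply(gene_specs, function(s)
      if (is.null(s$strand)) "+" else s$strand, character(1)),
    gene_id = sprintf("%s_g%03d", genome_id, seq_along(gene_specs)))
  newGenome(genome_id, contig, gr)
}

# --- random additive trees for the NJ oracle --------------------------------

# Random binary tree over n taxa with positive branch lengths, returned as an
# ape::phylo, plus its exact additive (patristic) distance matrix.
random_additive_case <- function(n_taxa) {
  phy <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  phy <- ape::unroot(phy)
  dm <- ape::cophenetic.phylo(phy)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = phy, d = dm)
}
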