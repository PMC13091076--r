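#' @importFrom Biostrings readDNAStringSet writeXStringSet translate
#'   reverseComplement getGeneticCode subseq width
#' @importFrom GenomicRanges GRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo Seqinfo
#' @importFrom rtracklayer import export.gff3
NULL

# Bacterial / archaeal genetic code used throughout the package.
.pkg_cache <- new.env(parent = emptyenv())

.code11 <- function() {
  if (is.null(.pkg_cache$code11))
    .pkg_cache$code11 <- Biostrings::getGeneticCode("11")
  .pkg_cache$code11
}

#' Assemble a Genome from contigs and CDS coordinates
#'
#' Extracts every CDS from the contig sequences (reverse-complementing
#' minus-strand records into coding orientation), translates with translation
#' table 11, removes the terminal stop from the protein, and flags records
#' that are frameshifted (CDS length not a multiple of 3; translation
#' truncated at the first incomplete codon) or pseudogenized (internal stop in
#' the translation). This is the single coordinate/translation path shared by
#' \code{\link{readGenome}} and the simulator.
#'
#' @param genome_id single string.
#' @param contigs named \link[Biostrings]{DNAStringSet}.
#' @param gene_ranges \link[GenomicRanges]{GRanges} with metadata column
#'   \code{gene_id}; coordinates 1-based inclusive.
#' @return a \code{\linkS4class{Genome}}.
#' @export
newGenome <- function(genome_id, contigs, gene_ranges) {
  stopifnot(is(contigs, "DNAStringSet"), !is.null(names(contigs)))
  gr <- gene_ranges
  if (length(gr) > 0L) {
    cn <- as.character(seqnames(gr))
    if (!all(cn %in% names(contigs)))
      stop("coordinate error: gene contig not present in contigs")
    lens <- width(contigs)[match(cn, names(contigs))]
    if (any(start(gr) < 1L) || any(end(gr) > lens))
      stop("coordinate error: CDS outside contig bounds")
    o <- order(cn, start(gr))
    gr <- gr[o]
  }
  ids <- as.character(mcols(gr)$gene_id)
  n <- length(gr)
  cds <- DNAStringSet(rep("", n))
  cn <- as.character(seqnames(gr))
  for (ct in unique(cn)) {
    idx <- which(cn == ct)
    cds[idx] <- DNAStringSet(contigs[[ct]], start = start(gr)[idx],
                             end = end(gr)[idx])
  }
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) cds[neg] <- reverseComplement(cds[neg])
  names(cds) <- ids
  frameshifted <- (width(cds) %% 3L) != 0L
  usable <- pmax((width(cds) %/% 3L) * 3L, 0L)
  prot <- character(n)
  nz <- usable > 0L
  if (any(nz)) {
    trimmed <- subseq(cds[nz], 1L, usable[nz])
    prot[nz] <- sub("\\*$", "",
                    as.character(translate(trimmed,
                                           genetic.code = .code11(),
                                           if.fuzzy.codon = "solve")))
  }
  proteins <- AAStringSet(prot)
  names(proteins) <- ids
  pseudo <- grepl("*", prot, fixed = TRUE)
  flags <- DataFrame(gene_id = ids,
                     frameshifted = frameshifted,
                     pseudogenized = pseudo)
  new("Genome", genomeId = genome_id, contigs = contigs, genes = gr,
      cds = cds, proteins = proteins, geneFlags = flags)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Parses the nucleotide FASTA and the CDS features of the GFF3 (1-based
#' inclusive coordinates, phase 0 assumed), derives strand-corrected coding
#' sequences and protein translations (table 11), and returns a
#' \code{\linkS4class{Genome}} with genes sorted by (contig, start).
#'
#' A CDS outside its contig raises a coordinate error. A CDS whose length is
#' not a multiple of 3 is kept and flagged \code{frameshifted}, with the
#' translation truncated at the first incomplete codon; broken genes are data,
#' not errors, because nonfunctional loci must be representable.
#'
#' @param fasta_path path to a nucleotide FASTA.
#' @param gff3_path path to a GFF3 with CDS features carrying \code{ID} (or
#'   \code{locus_tag}) attributes.
#' @return a \code{\linkS4class{Genome}}.
#' @examples
#' g <- simulateGenomes(simulationConfig(seed = 1, n_genomes = 1,
#'                                       n_background_genes = 20))$genomes[[1]]
#' d <- tempfile(); dir.create(d)
#' paths <- writeGenome(g, d)
#' g2 <- readGenome(paths["fasta"], paths["gff3"])
#' identical(as.character(cdsSeqs(g)), as.character(cdsSeqs(g2)))
#' @export
readGenome <- function(fasta_path, gff3_path) {
  contigs <- readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  feats <- rtracklayer::import(gff3_path)
  if (length(feats) > 0L)
    feats <- feats[!is.na(feats$type) & feats$type == "CDS"]
  if (length(feats) == 0L) {
    genome_id <- sub("\\.[^.]*$", "", basename(fasta_path))
    return(newGenome(genome_id, contigs, GRanges(gene_id = character(0))))
  }
  ids <- feats$ID
  if (is.null(ids) || anyNA(ids)) {
    lt <- feats$locus_tag
    if (!is.null(lt)) ids <- ifelse(is.na(ids), lt, ids)
  }
  if (is.null(ids) || anyNA(ids))
    stop("GFF3 CDS features must carry ID (or locus_tag) attributes")
  gr <- GRanges(seqnames = as.character(seqnames(feats)),
                ranges = IRanges(start(feats), end(feats)),
                strand = as.character(strand(feats)),
                gene_id = as.character(ids))
  genome_id <- sub("\\.[^.]*$", "", basename(fasta_path))
  newGenome(genome_id, contigs, gr)
}

#' Write a Genome as FASTA + GFF3
#'
#' Emits \code{<genome_id>.fna} and \code{<genome_id>.gff3} into
#' \code{out_dir}. \code{readGenome(writeGenome(g))} reproduces \code{g}
#' gene-for-gene (gene_id, coordinates, strand, CDS).
#'
#' @param genome a \code{\linkS4class{Genome}}.
#' @param out_dir output directory (created if missing).
#' @return named character vector with elements \code{fasta} and \code{gff3}.
#' @export
writeGenome <- function(genome, out_dir) {
  stopifnot(is(genome, "Genome"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fa <- file.path(out_dir, paste0(genome@genomeId, ".fna"))
  gf <- file.path(out_dir, paste0(genome@genomeId, ".gff3"))
  writeXStringSet(genome@contigs, fa)
  gr <- genome@genes
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", gf)
    return(c(fasta = fa, gff3 = gf))
  }
  out <- GRanges(seqnames = as.character(seqnames(gr)),
                 ranges = IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  GenomeInfoDb::seqlevels(out) <- names(genome@contigs)
  GenomeInfoDb::seqlengths(out) <- width(genome@contigs)
  mcols(out)$source <- rep("piliscan", length(gr))
  mcols(out)$type <- rep("CDS", length(gr))
  mcols(out)$phase <- rep(0L, length(gr))
  mcols(out)$ID <- mcols(gr)$gene_id
  rtracklayer::export.gff3(out, gf)
  c(fasta = fa, gff3 = gf)
}

#' Validate a FASTA + GFF3 pair
#'
#' Reads the pair through \code{\link{readGenome}} and reports basic
#' statistics; raises the same errors a full read would.
#'
#' @inheritParams readGenome
#' @return invisibly, a list with counts of contigs, genes and flagged genes.
#' @export
validateGenomeFiles <- function(fasta_path, gff3_path) {
  g <- readGenome(fasta_path, gff3_path)
  res <- list(genome_id = g@genomeId,
              n_contigs = length(g@contigs),
              n_genes = length(g@genes),
              n_frameshifted = sum(g@geneFlags$frameshifted),
              n_pseudogenized = sum(g@geneFlags$pseudogenized))
  message(sprintf("%s: %d contig(s), %d gene(s), %d frameshifted, %d pseudogenized",
                  res$genome_id, res$n_contigs, res$n_genes,
                  res$n_frameshifted, res$n_pseudogenized))
  invisible(res)
}

#' Reverse-complement an entire genome
#'
#' Reverse-complements every contig and remaps all gene coordinates and
#' strands accordingly. Coding sequences and translations are unchanged, which
#' makes this the strand-handling oracle for downstream stages.
#'
#' @param genome a \code{\linkS4class{Genome}}.
#' @return a \code{\linkS4class{Genome}} on the opposite strand.
#' @export
reverseComplementGenome <- function(genome) {
  ctg <- reverseComplement(genome@contigs)
  names(ctg) <- names(genome@contigs)
  gr <- genome@genes
  cn <- as.character(seqnames(gr))
  L <- width(genome@contigs)[match(cn, names(genome@contigs))]
  ns <- L - end(gr) + 1L
  ne <- L - start(gr) + 1L
  st <- ifelse(as.character(strand(gr)) == "+", "-", "+")
  out <- GRanges(seqnames = cn, ranges = IRanges(ns, ne), strand = st,
                 gene_id = mcols(gr)$gene_id)
  newGenome(genome@genomeId, ctg, out)
}
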