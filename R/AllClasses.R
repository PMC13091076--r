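#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
NULL

#' Genome: an annotated bacterial genome
#'
#' Container for one genome: contig sequences, CDS coordinates as a
#' \link[GenomicRanges]{GRanges} (1-based, inclusive, GFF3 convention), the
#' strand-corrected coding sequences and their translations (bacterial code,
#' translation table 11).
#'
#' CDS whose length is not a multiple of 3 are accepted but flagged
#' \code{frameshifted}; their translation is truncated at the first incomplete
#' codon. Records whose translation retains an internal stop (\code{*}) are
#' flagged \code{pseudogenized}. Both flags are carried in \code{geneFlags()}
#' and drive downstream pseudogene handling.
#'
#' @slot genomeId single character identifier.
#' @slot contigs named \link[Biostrings]{DNAStringSet} of contig sequences.
#' @slot genes \link[GenomicRanges]{GRanges} with one range per CDS, sorted by
#'   (contig, start); metadata column \code{gene_id} (unique).
#' @slot cds named \link[Biostrings]{DNAStringSet}, coding-orientation CDS
#'   (minus-strand records already reverse-complemented).
#' @slot proteins named \link[Biostrings]{AAStringSet}; terminal stop removed,
#'   internal stops retained as \code{*}.
#' @slot geneFlags \link[S4Vectors]{DataFrame} with columns \code{gene_id},
#'   \code{frameshifted}, \code{pseudogenized}.
#'
#' @seealso \code{\link{readGenome}}, \code{\link{writeGenome}},
#'   \code{\link{simulateGenomes}}
#' @export
setClass("Genome",
  representation(
    genomeId  = "character",
    contigs   = "DNAStringSet",
    genes     = "GRanges",
    cds       = "DNAStringSet",
    proteins  = "AAStringSet",
    geneFlags = "DataFrame"
  )
)

setValidity("Genome", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-NA string")
  gr <- object@genes
  ids <- mcols(gr)$gene_id
  if (length(gr) > 0L) {
    if (is.null(ids)) return("genes must carry a gene_id metadata column")
    if (anyDuplicated(ids)) msg <- c(msg, "gene_ids must be unique")
    cn <- as.character(seqnames(gr))
    if (!all(cn %in% names(object@contigs)))
      msg <- c(msg, "every gene's contig must exist in contigs")
    else {
      lens <- width(object@contigs)[match(cn, names(object@contigs))]
      if (any(start(gr) < 1L) || any(end(gr) > lens))
        msg <- c(msg, "gene interval outside contig bounds")
    }
    if (any(end(gr) < start(gr))) msg <- c(msg, "end must be >= start")
    if (!identical(names(object@cds), ids) ||
        !identical(names(object@proteins), ids))
      msg <- c(msg, "cds/proteins must be named by gene_id in gene order")
    if (!all(width(object@cds) == width(gr)))
      msg <- c(msg, "cds length must equal end - start + 1")
    o <- order(cn, start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "genes must be sorted by (contig, start)")
  }
  if (length(msg)) msg else TRUE
})

#' LocusModel: one detected type IV pilus locus
#'
#' Ordered, family-assigned member genes of one detected locus, its system
#' (T4cP = tight-adherence / Tad; T4aP = type IVa) and the architecture
#' classification assigned by \code{\link{classifyT4cP}} /
#' \code{\link{classifyT4aP}}.
#'
#' @slot locusId single character identifier.
#' @slot genomeId genome of origin.
#' @slot system \code{"T4cP"} or \code{"T4aP"}.
#' @slot members \link[S4Vectors]{DataFrame} sorted by \code{start}, columns
#'   \code{gene_id}, \code{family}, \code{identity}, \code{coverage},
#'   \code{pseudo}, \code{contig}, \code{start}, \code{end}, \code{strand},
#'   \code{gene_index} (rank of the gene along its contig),
#'   \code{distal} (TRUE for a tadV attached from outside the cluster).
#' @slot classification one of \code{T4cP_canonical},
#'   \code{T4cP_deltaC_inverted}, \code{T4cP_deltaV}, \code{T4aP_functional},
#'   \code{T4aP_nonfunctional}, or \code{NA} before classification.
#' @slot tadVDistal TRUE when the attached tadV lies outside the gene cluster.
#' @slot extraPilE number of pilE copies in the locus beyond the first.
#' @slot scatteredPrepilins pilE genes elsewhere in the genome attributed to
#'   this locus.
#' @slot notes character vector of classifier remarks (e.g. \code{pseudo:pilC},
#'   \code{deltaV}).
#' @export
setClass("LocusModel",
  representation(
    locusId            = "character",
    genomeId           = "character",
    system             = "character",
    members            = "DataFrame",
    classification     = "character",
    tadVDistal         = "logical",
    extraPilE          = "integer",
    scatteredPrepilins = "integer",
    notes              = "character"
  ),
  prototype(
    classification = NA_character_,
    tadVDistal = FALSE,
    extraPilE = 0L,
    scatteredPrepilins = 0L,
    notes = character(0)
  )
)

setValidity("LocusModel", function(object) {
  msg <- character(0)
  if (!object@system %in% c("T4cP", "T4aP"))
    msg <- c(msg, "system must be 'T4cP' or 'T4aP'")
  m <- object@members
  if (nrow(m) > 0L) {
    if (is.unsorted(m$start)) msg <- c(msg, "members must be sorted by start")
    pref <- if (object@system == "T4cP") "^(tad|flp)" else "^pil"
    if (!all(grepl(pref, m$family)))
      msg <- c(msg, "member families inconsistent with system")
  }
  if (length(msg)) msg else TRUE
})

#' OrthologClusterSet: cross-genome gene families
#'
#' Result of \code{\link{clusterOrthologs}}: clusters of orthologous genes
#' (COGs) spanning genomes, with the single-copy core subset filled in by
#' \code{\link{coreFamilies}}.
#'
#' @slot membership \link[S4Vectors]{DataFrame} with columns
#'   \code{cluster_id}, \code{genome_id}, \code{gene_id}; each gene appears in
#'   at most one cluster.
#' @slot coreIds character vector of cluster_ids with exactly one member in
#'   every genome (empty until \code{coreFamilies} is called).
#' @slot genomeIds genomes that entered the clustering.
#' @export
setClass("OrthologClusterSet",
  representation(
    membership = "DataFrame",
    coreIds    = "character",
    genomeIds  = "character"
  ),
  prototype(coreIds = character(0))
)

setValidity("OrthologClusterSet", function(object) {
  m <- object@membership
  msg <- character(0)
  if (!all(c("cluster_id", "genome_id", "gene_id") %in% colnames(m)))
    msg <- c(msg, "membership needs cluster_id, genome_id, gene_id")
  else {
    key <- paste(m$genome_id, m$gene_id)
    if (anyDuplicated(key)) msg <- c(msg, "each gene may join at most one cluster")
    if (length(object@coreIds) &&
        !all(object@coreIds %in% m$cluster_id))
      msg <- c(msg, "coreIds must be existing cluster_ids")
  }
  if (length(msg)) msg else TRUE
})
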