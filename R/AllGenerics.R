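#' @rdname Genome-class
#' @param object,x a \code{Genome}, \code{LocusModel} or
#'   \code{OrthologClusterSet} object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname Genome-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname Genome-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname Genome-class
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @rdname Genome-class
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' @rdname Genome-class
#' @export
setGeneric("geneFlags", function(x) standardGeneric("geneFlags"))

#' @rdname Genome-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname LocusModel-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname LocusModel-class
#' @export
setGeneric("locusSystem", function(x) standardGeneric("locusSystem"))

#' @rdname LocusModel-class
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname OrthologClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname OrthologClusterSet-class
#' @export
setGeneric("coreIds", function(x) standardGeneric("coreIds"))

#' @rdname Genome-class
setMethod("genomeId", "Genome", function(x) x@genomeId)
#' @rdname Genome-class
setMethod("contigs", "Genome", function(x) x@contigs)
#' @rdname Genome-class
setMethod("genes", "Genome", function(x) x@genes)
#' @rdname Genome-class
setMethod("cdsSeqs", "Genome", function(x) x@cds)
#' @rdname Genome-class
setMethod("proteinSeqs", "Genome", function(x) x@proteins)
#' @rdname Genome-class
setMethod("geneFlags", "Genome", function(x) x@geneFlags)
#' @rdname Genome-class
setMethod("nGenes", "Genome", function(x) length(x@genes))

#' @rdname LocusModel-class
setMethod("genomeId", "LocusModel", function(x) x@genomeId)
#' @rdname LocusModel-class
setMethod("members", "LocusModel", function(x) x@members)
#' @rdname LocusModel-class
setMethod("locusSystem", "LocusModel", function(x) x@system)
#' @rdname LocusModel-class
setMethod("classification", "LocusModel", function(x) x@classification)

#' @rdname OrthologClusterSet-class
setMethod("clusterTable", "OrthologClusterSet", function(x) x@membership)
#' @rdname OrthologClusterSet-class
setMethod("coreIds", "OrthologClusterSet", function(x) x@coreIds)

setMethod("show", "Genome", function(object) {
  cat("Genome object '", object@genomeId, "'\n", sep = "")
  cat("  contigs: ", length(object@contigs), " (",
      sum(width(object@contigs)), " nt)\n", sep = "")
  fl <- object@geneFlags
  cat("  genes:   ", length(object@genes),
      " (", sum(fl$frameshifted), " frameshifted, ",
      sum(fl$pseudogenized), " pseudogenized)\n", sep = "")
})

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel '", object@locusId, "' [", object@system, "] in ",
      object@genomeId, "\n", sep = "")
  cat("  classification: ", object@classification, "\n", sep = "")
  cat("  members: ", paste(object@members$family, collapse = " "), "\n",
      sep = "")
  if (object@system == "T4cP")
    cat("  tadV distal: ", object@tadVDistal, "\n", sep = "")
  if (object@system == "T4aP")
    cat("  extra pilE in locus: ", object@extraPilE,
        "; scattered prepilins: ", object@scatteredPrepilins, "\n", sep = "")
  if (length(object@notes))
    cat("  notes: ", paste(object@notes, collapse = "; "), "\n", sep = "")
})

setMethod("show", "OrthologClusterSet", function(object) {
  m <- object@membership
  cat("OrthologClusterSet:", length(unique(m$cluster_id)), "clusters over",
      length(object@genomeIds), "genomes;",
      length(object@coreIds), "single-copy core\n")
})
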