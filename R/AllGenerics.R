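#' Accessors for cogsr classes
#'
#' Slot access for the package's S4 containers. Each accessor returns the
#' underlying Bioconductor object (`GRanges`, `DataFrame`, matrix) so that
#' standard range/table machinery can be applied downstream.
#'
#' @param x a cogsr object.
#' @name cogsr-accessors
NULL

#' @rdname cogsr-accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname cogsr-accessors
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)

#' @rdname cogsr-accessors
#' @export
setGeneric("ldBlocks", function(x) standardGeneric("ldBlocks"))
#' @rdname cogsr-accessors
#' @export
setMethod("ldBlocks", "LdBlockSet", function(x) x@blocks)

#' @rdname cogsr-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname cogsr-accessors
#' @export
setMethod("geneTable", "GeneModelSet", function(x) x@genes)

#' @rdname cogsr-accessors
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))
#' @rdname cogsr-accessors
#' @export
setMethod("tssSites", "GeneModelSet", function(x) x@tss)

#' @rdname cogsr-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname cogsr-accessors
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname cogsr-accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname cogsr-accessors
#' @export
setMethod("interactions", "InteractionTable", function(x) x@interactions)

#' @rdname cogsr-accessors
#' @export
setGeneric("chicagoScores", function(x) standardGeneric("chicagoScores"))
#' @rdname cogsr-accessors
#' @export
setMethod("chicagoScores", "InteractionTable", function(x) x@scores)

#' @rdname cogsr-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname cogsr-accessors
#' @export
setMethod("cellTypes", "InteractionTable", function(x) x@cellTypes)

#' @rdname cogsr-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname cogsr-accessors
#' @export
setMethod("regions", "GeneRegions", function(x) x@regions)

#' @rdname cogsr-accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))
#' @rdname cogsr-accessors
#' @export
setMethod("geneScores", "CogsResult", function(x) x@geneScores)

#' @rdname cogsr-accessors
#' @export
setGeneric("blockScores", function(x) standardGeneric("blockScores"))
#' @rdname cogsr-accessors
#' @export
setMethod("blockScores", "CogsResult", function(x) x@blockScores)

#' @rdname cogsr-accessors
#' @export
setGeneric("truthEntries", function(x) standardGeneric("truthEntries"))
#' @rdname cogsr-accessors
#' @export
setMethod("truthEntries", "TruthSet", function(x) x@entries)
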