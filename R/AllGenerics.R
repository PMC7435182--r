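#' @rdname PooledVariants-class
#' @param x,object A package object.
#' @export
setGeneric("mutDepth", function(x) standardGeneric("mutDepth"))

#' @rdname PooledVariants-class
#' @export
setGeneric("wtDepth", function(x) standardGeneric("wtDepth"))

#' @rdname MarkerGenotypeTable-class
#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))

#' @rdname MarkerGenotypeTable-class
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' @rdname MarkerGenotypeTable-class
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneRange", function(x) standardGeneric("geneRange"))

#' @rdname GeneModel-class
#' @export
setGeneric("cdsSegments", function(x) standardGeneric("cdsSegments"))

#' @rdname SnpEffect-class
#' @export
setGeneric("effectClass", function(x) standardGeneric("effectClass"))

#' @rdname F2Population-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname F2Population-class
#' @export
setGeneric("causalLocus", function(x) standardGeneric("causalLocus"))

#' @rdname BsaScanResult-class
#' @export
setGeneric("scanRecords", function(x) standardGeneric("scanRecords"))

#' @rdname BsaScanResult-class
#' @export
setGeneric("scanThreshold", function(x) standardGeneric("scanThreshold"))

#' @rdname BsaScanResult-class
#' @export
setGeneric("scanRegions", function(x) standardGeneric("scanRegions"))

#' @rdname BsaScanResult-class
#' @export
setGeneric("selectedVariants", function(x) standardGeneric("selectedVariants"))

#' @rdname FineMapResult-class
#' @export
setGeneric("mappedInterval", function(x) standardGeneric("mappedInterval"))

#' @rdname FineMapResult-class
#' @export
setGeneric("markerResults", function(x) standardGeneric("markerResults"))

## accessor implementations -------------------------------------------------

#' @rdname PooledVariants-class
#' @export
setMethod("mutDepth", "PooledVariants", function(x)
    mcols(x)$mutRef + mcols(x)$mutAlt)

#' @rdname PooledVariants-class
#' @export
setMethod("wtDepth", "PooledVariants", function(x)
    mcols(x)$wtRef + mcols(x)$wtAlt)

#' @rdname MarkerGenotypeTable-class
#' @export
setMethod("markerCalls", "MarkerGenotypeTable", function(x) x@calls)

#' @rdname MarkerGenotypeTable-class
#' @export
setMethod("markerRanges", "MarkerGenotypeTable", function(x) x@markers)

#' @rdname MarkerGenotypeTable-class
#' @export
setMethod("individuals", "MarkerGenotypeTable", function(x)
    rownames(x@calls))

#' @rdname GeneModel-class
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname GeneModel-class
#' @export
setMethod("geneRange", "GeneModel", function(x) x@gene)

#' @rdname GeneModel-class
#' @export
setMethod("cdsSegments", "GeneModel", function(x) x@cds)

#' @rdname SnpEffect-class
#' @export
setMethod("effectClass", "SnpEffect", function(x) x@effectClass)

#' @rdname F2Population-class
#' @export
setMethod("phenotypes", "F2Population", function(x) x@phenotype)

#' @rdname F2Population-class
#' @export
setMethod("causalLocus", "F2Population", function(x) x@causal)

#' @rdname BsaScanResult-class
#' @export
setMethod("scanRecords", "BsaScanResult", function(x) x@records)

#' @rdname BsaScanResult-class
#' @export
setMethod("scanThreshold", "BsaScanResult", function(x) x@threshold)

#' @rdname BsaScanResult-class
#' @export
setMethod("scanRegions", "BsaScanResult", function(x) x@regions)

#' @rdname BsaScanResult-class
#' @export
setMethod("selectedVariants", "BsaScanResult", function(x)
    x@records[mcols(x@records)$selected])

#' @rdname FineMapResult-class
#' @export
setMethod("mappedInterval", "FineMapResult", function(x) x@interval)

#' @rdname FineMapResult-class
#' @export
setMethod("markerResults", "FineMapResult", function(x) x@markerResults)
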