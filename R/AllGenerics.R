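#' @rdname CdsSet-class
#' @param x,object A famevol S4 object.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname CdsSet-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname CdsSet-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname CdsSet-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("codonMatrix", function(x) standardGeneric("codonMatrix"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("nCodonColumns", function(x) standardGeneric("nCodonColumns"))

#' @rdname ReferenceIndex-class
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname ReferenceIndex-class
#' @export
setGeneric("columnToResidue", function(x) standardGeneric("columnToResidue"))

#' @rdname RegionMap-class
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname CodonUsageTable-class
#' @export
setGeneric("usageTable", function(x) standardGeneric("usageTable"))
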