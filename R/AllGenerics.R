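#' @include AllClasses.R
NULL

#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @export
setGeneric("geneIds", function(x, species = NULL) standardGeneric("geneIds"))
#' @export
setGeneric("nGenes", function(x, species = NULL) standardGeneric("nGenes"))
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))
#' @export
setGeneric("itemCatalog", function(x, species = NULL)
  standardGeneric("itemCatalog"))
#' @export
setGeneric("annotationValues", function(x, item, species = NULL)
  standardGeneric("annotationValues"))
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @export
setGeneric("networkScope", function(x) standardGeneric("networkScope"))
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))
#' @export
setGeneric("unitMembers", function(x) standardGeneric("unitMembers"))
#' @export
setGeneric("unitSeed", function(x) standardGeneric("unitSeed"))
#' @export
setGeneric("unitScore", function(x) standardGeneric("unitScore"))
#' @export
setGeneric("unitDensity", function(x) standardGeneric("unitDensity"))
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @export
setGeneric("modelUnits", function(x) standardGeneric("modelUnits"))
#' @export
setGeneric("modelUnitEdges", function(x) standardGeneric("modelUnitEdges"))
#' @export
setGeneric("modelOverlay", function(x) standardGeneric("modelOverlay"))
#' @export
setGeneric("modelTallies", function(x) standardGeneric("modelTallies"))
#' @export
setGeneric("cogNodes", function(x) standardGeneric("cogNodes"))
#' @export
setGeneric("cogEdges", function(x) standardGeneric("cogEdges"))
#' @export
setGeneric("writeGraphML", function(x, file, ...)
  standardGeneric("writeGraphML"))
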