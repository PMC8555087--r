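#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' @export
setGeneric("truePas", function(x) standardGeneric("truePas"))

#' @export
setGeneric("artifactSites", function(x) standardGeneric("artifactSites"))

#' @export
setGeneric("switchGenes", function(x) standardGeneric("switchGenes"))

#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))

#' @export
setGeneric("redMax", function(x) standardGeneric("redMax"))

#' @export
setGeneric("greenSplit", function(x) standardGeneric("greenSplit"))

#' @export
setGeneric("minEvents", function(x) standardGeneric("minEvents"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("apaGenes", function(x) standardGeneric("apaGenes"))
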