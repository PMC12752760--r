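#' @export
setGeneric("mutantAffinities", function(x) standardGeneric("mutantAffinities"))

#' @export
setGeneric("wildtypeAffinities",
           function(x) standardGeneric("wildtypeAffinities"))

#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))

#' @export
setGeneric("variantLabel", function(x) standardGeneric("variantLabel"))

#' @export
setGeneric("freqTable", function(x) standardGeneric("freqTable"))

#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @export
setGeneric("computeMAS", function(x, cutoff = 500) standardGeneric("computeMAS"))

#' @export
setGeneric("computeHCS", function(x, cutoff = 500) standardGeneric("computeHCS"))

#' @export
setGeneric("computeAMS",
           function(x, cutoff = 500, inverted = FALSE)
             standardGeneric("computeAMS"))

#' @export
setGeneric("responsiveAlleles",
           function(x, cutoff = 500) standardGeneric("responsiveAlleles"))
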