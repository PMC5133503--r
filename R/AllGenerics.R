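#' @export
setGeneric("kinshipMatrix", function(x, ...) standardGeneric("kinshipMatrix"))

#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))

#' @export
setGeneric("pedData", function(x) standardGeneric("pedData"))

#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))

#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))
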