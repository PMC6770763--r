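#' @rdname NetworkModel-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("outputSpecies", function(x) standardGeneric("outputSpecies"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("outputSpecies<-",
           function(x, value) standardGeneric("outputSpecies<-"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("initialState", function(x, ...) standardGeneric("initialState"))

#' @rdname exprScale
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
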