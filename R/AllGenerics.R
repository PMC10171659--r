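#' @rdname SharingNetwork-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname SharingNetwork-accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname SharingNetwork-accessors
#' @export
setGeneric("hunters", function(x) standardGeneric("hunters"))

#' @rdname SharingNetwork-accessors
#' @export
setGeneric("nHunters", function(x) standardGeneric("nHunters"))

#' @rdname visitProbabilities
#' @export
setGeneric("visitProbabilities",
           function(net, params) standardGeneric("visitProbabilities"))

#' @rdname eatingProbabilities
#' @export
setGeneric("eatingProbabilities",
           function(net, params) standardGeneric("eatingProbabilities"))

#' @rdname simulateEvents
#' @export
setGeneric("simulateEvents",
           function(net, params, nEvents, seed = 1L)
             standardGeneric("simulateEvents"))

#' @rdname costVector
#' @export
setGeneric("costVector", function(net, params) standardGeneric("costVector"))

#' @rdname canonicalReduce
#' @export
setGeneric("canonicalReduce",
           function(net, params) standardGeneric("canonicalReduce"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
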