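#' Accessors for SharingNetwork objects
#'
#' `nNodes()` returns the number of nodes, `arcs()` the two-column arc matrix
#' (0-based ids), `hunters()` the sorted hunter ids and `nHunters()` their
#' number.
#'
#' @param x a [SharingNetwork-class].
#' @return See individual descriptions.
#' @examples
#' net <- fixtureSevenNode()
#' nNodes(net)
#' hunters(net)
#' @name SharingNetwork-accessors
NULL

#' @rdname SharingNetwork-accessors
#' @export
setMethod("nNodes", "SharingNetwork", function(x) x@nNodes)

#' @rdname SharingNetwork-accessors
#' @export
setMethod("arcs", "SharingNetwork", function(x) x@arcs)

#' @rdname SharingNetwork-accessors
#' @export
setMethod("hunters", "SharingNetwork", function(x) x@hunters)

#' @rdname SharingNetwork-accessors
#' @export
setMethod("nHunters", "SharingNetwork", function(x) length(x@hunters))

setMethod("show", "SharingNetwork", function(object) {
  cat(sprintf("SharingNetwork: %d nodes, %d arcs, %d hunter%s {%s}\n",
              object@nNodes, nrow(object@arcs), length(object@hunters),
              if (length(object@hunters) == 1L) "" else "s",
              paste(object@hunters, collapse = ", ")))
  if (nrow(object@arcs) > 0L) {
    shown <- head(object@arcs, 12L)
    cat("  arcs:", paste(sprintf("%d->%d", shown[, 1L], shown[, 2L]),
                         collapse = " "),
        if (nrow(object@arcs) > 12L) "..." else "", "\n")
  }
  invisible(NULL)
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams: ph = %g, F = %d, n = %d, k = %d\n",
              object@ph, object@F, object@n, object@k))
  invisible(NULL)
})

setMethod("show", "RunCountDistribution", function(object) {
  m <- runCountMoments(object)
  cat(sprintf(
    "RunCountDistribution: n = %d, k = %d, pe = %g (support 0..%d)\n",
    object@n, object@k, object@pe, length(object@pmf) - 1L))
  cat(sprintf("  E = %.6g, sigma = %.6g\n", m[["E"]], m[["sigma"]]))
  invisible(NULL)
})

setMethod("show", "EvolutionConfig", function(object) {
  cat(sprintf(
    "EvolutionConfig: mu = %d, lambda/mu = %d, t = %d, generations = %d\n",
    object@mu, object@lambdaRatio, object@tournamentSize,
    object@generations))
  cat(sprintf("  N = %d, nh = %d, seed = %d\n", object@N, object@nh,
              object@seed))
  invisible(NULL)
})

#' Validate a sharing network
#'
#' Checks every structural invariant (loop-free, simple, hunter ids inside
#' the node range, non-empty hunter set) and errors if any is violated.
#' Validation also runs automatically on construction; this function is the
#' explicit entry point for networks assembled slot-wise or read from disk.
#'
#' @param net a [SharingNetwork-class].
#' @return `net`, invisibly unchanged, if valid; otherwise an error.
#' @examples
#' validateNetwork(fixtureSevenNode())
#' @export
validateNetwork <- function(net) {
  if (!is(net, "SharingNetwork"))
    stop("'net' must be a SharingNetwork")
  validObject(net)
  net
}

#' Convert a SharingNetwork to an igraph object
#'
#' The result is a directed igraph graph whose vertices carry `name`
#' (the 0-based node id as character) and logical `hunter` attributes.
#'
#' @param x a [SharingNetwork-class].
#' @return An [igraph::igraph] object.
#' @examples
#' asIgraph(fixtureSevenNode())
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "SharingNetwork", function(x) {
  g <- igraph::make_empty_graph(n = x@nNodes, directed = TRUE)
  if (nrow(x@arcs) > 0L)
    g <- igraph::add_edges(g, as.vector(t(x@arcs + 1L)))
  igraph::V(g)$name <- as.character(seq_len(x@nNodes) - 1L)
  igraph::V(g)$hunter <- (seq_len(x@nNodes) - 1L) %in% x@hunters
  g
})

# internal light-weight representation used by the numeric core:
# adjacency 0/1 matrix (1-based indexing) plus 1-based hunter indices
.asCore <- function(net) {
  N <- net@nNodes
  adj <- matrix(0L, N, N)
  if (nrow(net@arcs) > 0L)
    adj[cbind(net@arcs[, 1L] + 1L, net@arcs[, 2L] + 1L)] <- 1L
  list(adj = adj, hunters = net@hunters + 1L)
}

.fromCore <- function(adj, huntersIdx) {
  w <- which(adj == 1L, arr.ind = TRUE)
  a <- cbind(from = w[, 1L] - 1L, to = w[, 2L] - 1L)
  a <- a[order(a[, 1L], a[, 2L]), , drop = FALSE]
  SharingNetwork(nrow(adj), a, huntersIdx - 1L)
}
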