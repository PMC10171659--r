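#' Seven-node worked-example network with two hunters
#'
#' The small network used throughout as a worked example: 7 nodes, hunters
#' `{0, 4}`, arcs `0->1, 0->3, 1->2, 2->3, 3->1, 4->5, 5->6, 6->1`. With
#' `ph = 0.2` its exact eating profile is known for `F = 2..5` (28 values),
#' including `pe(1) = 0.36` at `F = 4` from the inclusion-exclusion of the
#' two hunters' walks.
#'
#' @return A [SharingNetwork-class].
#' @examples
#' eatingProbabilities(fixtureSevenNode(), ModelParams(0.2, 4))
#' @export
fixtureSevenNode <- function() {
  SharingNetwork(7L,
    rbind(c(0L, 1L), c(0L, 3L), c(1L, 2L), c(2L, 3L), c(3L, 1L),
          c(4L, 5L), c(5L, 6L), c(6L, 1L)),
    hunters = c(0L, 4L))
}

#' Five-node star network around one hunter
#'
#' One hunter (node 0) with arcs to the four consumers and no other arcs.
#' At `ph = 0.08`, `F = 4` every non-hunter eats with equiprobability 0.02
#' and the cost vector is `(rv, wef) = (0.261, 0.024)` at `n = 1000`,
#' `k = 10`.
#'
#' @return A [SharingNetwork-class].
#' @examples
#' costVector(fixtureHunterStar(), ModelParams(0.08, 4))
#' @export
fixtureHunterStar <- function() {
  SharingNetwork(5L,
    cbind(from = rep(0L, 4L), to = 1:4),
    hunters = 0L)
}

#' Seeded random sharing network
#'
#' Each ordered pair `(u, v)`, `u != v`, receives an arc independently with
#' probability `arcProb`; the hunters are the first `nh` nodes after a
#' seeded shuffle of the node labels. Reproducible for a fixed seed.
#'
#' @param N number of nodes.
#' @param arcProb arc inclusion probability in `[0, 1]`; 0.5 makes the draw
#'   uniform over all loop-free simple digraphs.
#' @param nh number of hunters, `1 <= nh <= N`.
#' @param seed integer seed.
#' @return A [SharingNetwork-class].
#' @examples
#' randomNetwork(6, 0.3, nh = 2, seed = 42)
#' @export
randomNetwork <- function(N, arcProb, nh, seed = 1L) {
  N <- as.integer(N); nh <- as.integer(nh)
  if (is.na(N) || N < 1L)
    stop("invalid argument: 'N' must be a positive integer")
  if (!is.numeric(arcProb) || is.na(arcProb) || arcProb < 0 || arcProb > 1)
    stop("invalid argument: 'arcProb' must be a probability")
  if (is.na(nh) || nh < 1L || nh > N)
    stop("invalid argument: need 1 <= nh <= N")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  adj <- matrix(runif(N * N) < arcProb, N, N)
  diag(adj) <- FALSE
  h <- sample.int(N, N)[seq_len(nh)]
  w <- which(adj, arr.ind = TRUE)
  SharingNetwork(N, cbind(from = w[, 1L] - 1L, to = w[, 2L] - 1L),
                 hunters = h - 1L)
}
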