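# Network file formats: tab-separated edge lists (header "source\ttarget",
# 0-based ids, hunters in a one-id-per-line sidecar file) and GraphML with a
# boolean "hunter" node attribute (via igraph).

#' Read a sharing network from disk
#'
#' Two dialects are supported. `"edgelist"`: a TSV with header columns
#' `source` and `target` holding 0-based node ids, plus a sidecar file of
#' hunter ids (one per line), by default `<path>.hunters`. `"graphml"`:
#' GraphML with a boolean node attribute `hunter`. Node ids are normalized
#' to `0..N-1` preserving input order.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param huntersPath sidecar path for the edge-list dialect; default
#'   `paste0(path, ".hunters")`.
#' @param nNodes optional node count for edge lists whose trailing nodes are
#'   isolated (an edge list alone cannot express them).
#' @return A validated [SharingNetwork-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeNetwork(fixtureSevenNode(), tf, format = "edgelist")
#' readNetwork(tf, format = "edgelist")
#' @export
readNetwork <- function(path, format = c("edgelist", "graphml"),
                        huntersPath = NULL, nNodes = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- tryCatch(read.delim(path, colClasses = "integer"),
                   error = function(e)
                     stop(sprintf("parse error in '%s': %s", path,
                                  conditionMessage(e))))
    if (!all(c("source", "target") %in% names(df)))
      stop(sprintf("parse error in '%s': expected columns 'source' and 'target'",
                   path))
    bad <- which(df$source == df$target)
    if (length(bad))
      stop(sprintf("parse error in '%s' at data line %d: self-loop", path,
                   bad[1L]))
    if (is.null(huntersPath)) huntersPath <- paste0(path, ".hunters")
    if (!file.exists(huntersPath))
      stop(sprintf("invalid model: hunter sidecar '%s' not found",
                   huntersPath))
    h <- as.integer(readLines(huntersPath))
    N <- if (is.null(nNodes))
      max(c(df$source, df$target, h)) + 1L else as.integer(nNodes)
    validateNetwork(SharingNetwork(N, cbind(df$source, df$target), h))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    hunterAttr <- igraph::vertex_attr(g, "hunter")
    if (is.null(hunterAttr))
      stop(sprintf("invalid model: GraphML '%s' has no 'hunter' node attribute",
                   path))
    isH <- if (is.logical(hunterAttr)) hunterAttr
           else tolower(as.character(hunterAttr)) %in% c("true", "1", "yes")
    el <- igraph::as_edgelist(g, names = FALSE)
    validateNetwork(SharingNetwork(igraph::vcount(g),
                                   cbind(el[, 1L] - 1L, el[, 2L] - 1L),
                                   which(isH) - 1L))
  }
}

#' Write a sharing network to disk
#'
#' The inverse of [readNetwork()]; the edge-list dialect writes the hunter
#' sidecar `<path>.hunters` alongside the TSV.
#'
#' @param net a [SharingNetwork-class].
#' @param path destination path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param huntersPath sidecar path (edge-list dialect only).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "graphml"),
                         huntersPath = NULL) {
  format <- match.arg(format)
  validObject(net)
  if (format == "edgelist") {
    df <- data.frame(source = net@arcs[, 1L], target = net@arcs[, 2L])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(huntersPath)) huntersPath <- paste0(path, ".hunters")
    writeLines(as.character(net@hunters), huntersPath)
  } else {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Write an eating profile (plus parameter echo) as JSON
#'
#' @param pe named eating profile as returned by [eatingProbabilities()].
#' @param params the [ModelParams-class] used.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeProfileJSON <- function(pe, params, path) {
  obj <- list(
    params = list(ph = params@ph, F = params@F, n = params@n, k = params@k),
    pe = as.list(setNames(unname(pe), names(pe))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
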