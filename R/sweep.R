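#' Sweep the evolutionary searches over a parameter grid
#'
#' Runs, for every grid cell `(ph, F, nh)` and every seed, the
#' single-criterion searches (both criteria) and the multi-objective search,
#' and collects the deduplicated optima as records together with an
#' aggregate feature table. Cells are labelled by the food-abundance split
#' `F * nh <= N` versus `> N`. The default grid mirrors the model's working
#' sweep: `ph` in {0.02, 0.08, 0.15, 0.3, 0.6}, `F` in 2..6, `nh` in 1..6 on
#' `N = 12` nodes; pass a smaller grid (and budget) for desk-scale runs.
#'
#' @param grid `data.frame` with columns `ph`, `F`, `nh`; default the full
#'   working grid.
#' @param config an [EvolutionConfig-class] providing `N` and the budgets;
#'   its `nh` and `seed` are overridden per cell/seed.
#' @param n,k survival-window parameters (defaults 1000 and 10).
#' @param criteria subset of `c("rv", "wef", "pareto")`.
#' @param seeds integer vector of seeds per cell.
#' @param outPrefix optional path prefix; if given, writes
#'   `<prefix>-records.jsonl` (one JSON record per optimum: arcs, hunters,
#'   params, costs, type, seed) and `<prefix>-features.csv`.
#' @param verbose print one progress line per cell.
#' @return Invisibly, a list with `records`, `features` (a `data.frame`) and
#'   the labelled `grid`.
#' @examples
#' \donttest{
#' cfg <- EvolutionConfig(mu = 10, generations = 10, N = 4, tournamentSize = 6)
#' runSweep(data.frame(ph = 0.3, F = 3, nh = 1), cfg, seeds = 1)
#' }
#' @export
runSweep <- function(grid = expand.grid(ph = c(0.02, 0.08, 0.15, 0.3, 0.6),
                                        F = 2:6, nh = 1:6),
                     config = EvolutionConfig(),
                     n = 1000L, k = 10L,
                     criteria = c("rv", "wef", "pareto"),
                     seeds = 1L, outPrefix = NULL, verbose = FALSE) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  stopifnot(all(c("ph", "F", "nh") %in% names(grid)))
  if (any(grid$F < 1L) || any(grid$nh > config@N))
    stop("invalid argument: every cell must satisfy F >= 1 and nh <= N")
  grid$abundance <- ifelse(grid$F * grid$nh <= config@N,
                           "F*nh<=N", "F*nh>N")
  if (!is.null(outPrefix)) {
    jsonPath <- paste0(outPrefix, "-records.jsonl")
    ok <- tryCatch({ file.create(jsonPath); TRUE },
                   warning = function(w) FALSE)
    if (!ok) stop(sprintf("I/O error: cannot write to '%s'", jsonPath))
  }
  records <- list()
  nets <- list()
  cells <- list()
  for (i in seq_len(nrow(grid))) {
    params <- ModelParams(grid$ph[i], grid$F[i], n, k)
    for (s in seeds) {
      cfg <- EvolutionConfig(mu = config@mu, lambdaRatio = config@lambdaRatio,
                             tournamentSize = config@tournamentSize,
                             generations = config@generations,
                             seed = s, N = config@N, nh = grid$nh[i])
      found <- list()
      for (crit in intersect(criteria, c("rv", "wef"))) {
        for (ind in evolveSingle(params, cfg, crit))
          found[[length(found) + 1L]] <- c(ind, list(type = crit))
      }
      if ("pareto" %in% criteria) {
        for (ind in evolveMulti(params, cfg)$individuals)
          found[[length(found) + 1L]] <- c(ind, list(type = "pf"))
      }
      for (ind in found) {
        a <- arcs(ind$network)
        rec <- list(
          arcs = lapply(seq_len(nrow(a)), function(r) unname(a[r, ])),
          hunters = hunters(ind$network),
          params = list(ph = params@ph, F = params@F, n = params@n,
                        k = params@k, N = cfg@N, nh = cfg@nh),
          costs = as.list(ind$costs),
          type = ind$type,
          seed = s)
        records[[length(records) + 1L]] <- rec
        nets[[length(nets) + 1L]] <- ind$network
        cells[[length(cells) + 1L]] <-
          data.frame(ph = params@ph, F = params@F, nh = cfg@nh, seed = s,
                     type = ind$type, abundance = grid$abundance[i])
      }
    }
    if (verbose)
      message(sprintf("cell %d/%d (ph=%g F=%d nh=%d): %d records so far",
                      i, nrow(grid), grid$ph[i], grid$F[i], grid$nh[i],
                      length(records)))
  }
  features <- NULL
  if (length(nets)) {
    byCell <- do.call(rbind, cells)
    feats <- do.call(rbind, lapply(seq_along(nets), function(j) {
      p <- records[[j]]$params
      networkFeatures(nets[[j]], ModelParams(p$ph, p$F, p$n, p$k))
    }))
    features <- cbind(byCell, feats)
  }
  if (!is.null(outPrefix)) {
    con <- file(paste0(outPrefix, "-records.jsonl"), open = "w")
    for (rec in records)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    close(con)
    if (!is.null(features))
      write.table(features, paste0(outPrefix, "-features.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
  }
  invisible(list(records = records, features = features, grid = grid))
}
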