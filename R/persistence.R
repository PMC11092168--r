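#' Save and load a fitted ensemble
#'
#' `saveEnsemble` writes the fitted model to `dir` as a versioned archive:
#' a JSON manifest (`manifest.json`, carrying the format version, bandit
#' parameters, label encoding, winner counts and the per-round view, edge
#' and vote weight), the bandit trace as TSV (`trace.tsv`), and the fitted
#' base models in R's serialization format (`rounds.rds`). The text parts
#' are sufficient to audit a run (e.g. replay the forecaster with
#' [replayBanditTrace()]) without deserializing any model.
#'
#' @param ens an [Ensemble-class].
#' @param dir output directory (created if needed).
#' @return `saveEnsemble`: the directory, invisibly; `loadEnsemble`: the
#'   restored [Ensemble-class].
#' @export
saveEnsemble <- function(ens, dir) {
  stopifnot(is(ens, "Ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(
    format = "irboostSH-ensemble/1",
    type = ens@type, nClasses = ens@nClasses,
    classLevels = ens@encoding@levels, viewIds = ens@viewIds,
    T = ens@T, sigma = ens@sigma, gamma = ens@gamma,
    winnerCounts = as.list(ens@winnerCounts),
    rounds = lapply(ens@rounds, function(r)
      list(t = r@t, view = r@viewId, edge = r@edge, alpha = r@alpha)))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(ens@trace, file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  saveRDS(ens, file.path(dir, "rounds.rds"))
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyDataFrame = FALSE)
  if (!identical(man$format, "irboostSH-ensemble/1"))
    stop("unrecognized model archive format: ", man$format)
  ens <- readRDS(file.path(dir, "rounds.rds"))
  validObject(ens)
  ens
}
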