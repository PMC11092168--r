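#' Construct a feature-filtering specification
#'
#' @param mode `"frequency"` (minimum number of samples in which a feature
#'   must be present), `"prevalence"` (minimum fraction of samples, in
#'   (0, 1]) or `"none"`.
#' @param threshold positive number; omitted for `mode = "none"`.
#' @return a [FilterSpec-class].
#' @export
filterSpec <- function(mode = c("frequency", "prevalence", "none"),
                       threshold = NA_real_) {
  mode <- match.arg(mode)
  new("FilterSpec", mode = mode, threshold = as.numeric(threshold))
}

setMethod("show", "FilterSpec", function(object) {
  if (object@mode == "none") cat("FilterSpec: unfiltered\n")
  else cat(sprintf("FilterSpec: %s >= %s\n", object@mode, object@threshold))
})

#' Filter the features of a view by presence across samples
#'
#' A feature is "present" in a sample when its value is strictly positive
#' (OTU tables are count/abundance tables). `mode = "frequency"` keeps
#' features present in at least `threshold` samples; `mode = "prevalence"`
#' keeps features present in at least a fraction `threshold` of the samples
#' (inclusive comparison). The sample set and the relative feature order are
#' unchanged.
#'
#' @param table a [ViewTable-class].
#' @param spec a [FilterSpec-class].
#' @param newId optional view id for the result (default: input id with the
#'   filter configuration appended).
#' @return a [ViewTable-class] with the surviving features.
#' @examples
#' m <- matrix(c(0, 3, 0, 0, 1, 2, 5, 0), 4,
#'             dimnames = list(paste0("s", 1:4), c("otuA", "otuB")))
#' v <- ViewTable("raw", m)
#' featureIds(filterFeatures(v, filterSpec("frequency", 2)))
#' @export
filterFeatures <- function(table, spec, newId = NULL) {
  stopifnot(is(table, "ViewTable"), is(spec, "FilterSpec"))
  validObject(spec)
  m <- featureMatrix(table)
  if (nrow(m) == 0L) stop("cannot filter an empty view")
  tag <- switch(spec@mode,
    none = "raw",
    frequency = paste0("freq", spec@threshold),
    prevalence = paste0("prev", spec@threshold))
  if (is.null(newId)) newId <- paste(viewId(table), tag, sep = ".")
  if (spec@mode == "none")
    return(new("ViewTable", viewId = newId, features = m))
  presence <- colSums(m > 0)
  keep <- switch(spec@mode,
    frequency = presence >= spec@threshold,
    prevalence = presence / nrow(m) >= spec@threshold)
  if (!any(keep))
    stop("filter '", tag, "' removes every feature of view '",
         viewId(table), "'; use a weaker threshold")
  new("ViewTable", viewId = newId, features = m[, keep, drop = FALSE])
}

#' Build a grid of filtered views from one feature table
#'
#' Applies every frequency threshold, every prevalence threshold, and
#' optionally no filter at all, to the same input table, yielding one view
#' per configuration. With the default thresholds (frequency 2, 5, 10, 50;
#' prevalence 2\%, 5\%, 10\%, 20\%, 50\%; plus the unfiltered table) each
#' input table yields exactly 10 views, so four tables — e.g. one per OTU
#' clustering similarity threshold — yield 40. Configurations that would
#' remove every feature are skipped with a warning instead of aborting the
#' grid.
#'
#' @param table a [ViewTable-class].
#' @param freqThresholds integer vector of frequency thresholds.
#' @param prevThresholds numeric vector of prevalence thresholds in (0, 1].
#' @param includeUnfiltered also emit the unfiltered table as a view.
#' @return named list of [ViewTable-class], ids encoding the configuration.
#' @export
buildViewGrid <- function(table,
                          freqThresholds = c(2, 5, 10, 50),
                          prevThresholds = c(0.02, 0.05, 0.10, 0.20, 0.50),
                          includeUnfiltered = TRUE) {
  stopifnot(is(table, "ViewTable"))
  if (!length(freqThresholds) && !length(prevThresholds) &&
      !includeUnfiltered)
    stop("no filter configuration requested")
  specs <- c(
    lapply(freqThresholds, function(t) filterSpec("frequency", t)),
    lapply(prevThresholds, function(t) filterSpec("prevalence", t)),
    if (includeUnfiltered) list(filterSpec("none")))
  out <- list()
  for (sp in specs) {
    v <- tryCatch(filterFeatures(table, sp), error = function(e) {
      warning("skipping one grid configuration: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(v)) out[[viewId(v)]] <- v
  }
  out
}
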