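#' Read a per-view feature table
#'
#' Reads a samples-by-features table from TSV, CSV or BIOM. For text
#' dialects the first column holds identifiers and the header row the other
#' dimension's identifiers; `orientation` says whether rows are samples
#' (`"samples_as_rows"`) or features (`"features_as_rows"`, the BIOM and
#' QIIME convention, transposed on read). Values are passed through
#' unchanged — no abundance transformation is applied. Non-numeric cells and
#' duplicated sample identifiers are errors, never coerced.
#'
#' @param path file path.
#' @param viewId view identifier to attach; defaults to the file base name.
#' @param dialect `"tsv"`, `"csv"` or `"biom"` (requires the biomformat
#'   package).
#' @param orientation `"samples_as_rows"` or `"features_as_rows"`; ignored
#'   for BIOM, whose matrix is defined features-by-samples.
#' @return a [ViewTable-class].
#' @export
readViewTable <- function(path, viewId = NULL,
                          dialect = c("tsv", "csv", "biom"),
                          orientation = c("samples_as_rows",
                                          "features_as_rows")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(viewId))
    viewId <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # features x samples
    m <- t(m)
  } else {
    sep <- if (dialect == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = NULL, check.names = FALSE,
                            colClasses = "character",
                            comment.char = "", quote = "\"")
    ids <- df[[1L]]
    body <- df[-1L]
    m <- matrix(NA_real_, nrow(df), ncol(body),
                dimnames = list(ids, colnames(body)))
    for (j in seq_along(body)) {
      v <- suppressWarnings(as.numeric(body[[j]]))
      bad <- which(is.na(v) & !is.na(body[[j]]))
      if (length(bad))
        stop(sprintf(
          "non-numeric value '%s' at row '%s', column '%s' of %s",
          body[[j]][bad[1L]], ids[bad[1L]], colnames(body)[j], path))
      m[, j] <- v
    }
    if (orientation == "features_as_rows") m <- t(m)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample identifier(s) in ", path, ": ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  ViewTable(viewId, m)
}

#' Write a view table as TSV or CSV
#'
#' Inverse of [readViewTable()] for the text dialects: round-trips a
#' [ViewTable-class] up to float formatting (15 significant digits).
#'
#' @param view a [ViewTable-class].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
writeViewTable <- function(view, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  m <- featureMatrix(view)
  df <- data.frame(sample_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with columns `sample_id` and `label` (header optional but
#'   recommended).
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("label table must have two columns")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample identifier(s) in label table")
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname readLabels
#' @param labels named vector of labels.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a view manifest and assemble the dataset it describes
#'
#' The manifest is a JSON or YAML document with a `views` array of entries
#' `{view_id, path, dialect, orientation}` (paths relative to the manifest)
#' and a `labels` path. `readManifest` parses it; `readDataset` loads all
#' views and labels and assembles the [MultiViewDataset-class].
#'
#' @param path manifest path (`.json`, `.yml` or `.yaml`).
#' @return `readManifest`: a list; `readDataset`: a `MultiViewDataset`.
#' @export
readManifest <- function(path) {
  man <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(man$views) || !length(man$views))
    stop("manifest field 'views' is missing or empty")
  for (i in seq_along(man$views)) {
    v <- man$views[[i]]
    for (fld in c("view_id", "path"))
      if (is.null(v[[fld]]))
        stop("manifest views[", i, "] is missing field '", fld, "'")
    if (is.null(v$dialect)) man$views[[i]]$dialect <- "tsv"
    if (is.null(v$orientation))
      man$views[[i]]$orientation <- "samples_as_rows"
  }
  if (is.null(man$labels)) stop("manifest field 'labels' is missing")
  man
}

#' @rdname readManifest
#' @export
readDataset <- function(path) {
  man <- readManifest(path)
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  views <- lapply(man$views, function(v)
    readViewTable(rel(v$path), viewId = v$view_id, dialect = v$dialect,
                  orientation = v$orientation))
  labels <- readLabels(rel(man$labels))
  assembleDataset(views, labels)
}

#' Write a dataset as per-view TSVs, a label table and a manifest
#'
#' @param ds a [MultiViewDataset-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(views(ds), function(v) {
    f <- paste0(viewId(v), ".tsv")
    writeViewTable(v, file.path(dir, f))
    list(view_id = viewId(v), path = f, dialect = "tsv",
         orientation = "samples_as_rows")
  })
  writeLabels(sampleLabels(ds, external = TRUE), file.path(dir, "labels.tsv"))
  man <- list(views = entries, labels = "labels.tsv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
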