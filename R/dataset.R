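#' Construct a ViewTable
#'
#' @param viewId single string identifying the view.
#' @param features numeric matrix, samples as rows; rownames are the sample
#'   identifiers, colnames the feature identifiers. If colnames are missing
#'   they are generated as `F1..Fq`.
#' @return a [ViewTable-class].
#' @examples
#' m <- matrix(rpois(6, 5), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("otu1", "otu2")))
#' ViewTable("v1", m)
#' @export
ViewTable <- function(viewId, features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  new("ViewTable", viewId = as.character(viewId), features = features)
}

#' Accessors for ViewTable
#'
#' @param x a [ViewTable-class].
#' @return `viewId`: the view identifier; `sampleIds`/`featureIds`: character
#'   vectors; `featureMatrix`: the numeric samples-by-features matrix.
#' @name ViewTable-accessors
NULL

#' @rdname ViewTable-accessors
#' @export
setMethod("viewId", "ViewTable", function(x) x@viewId)

#' @rdname ViewTable-accessors
#' @export
setMethod("sampleIds", "ViewTable", function(x)
  if (is.null(rownames(x@features))) character(0) else rownames(x@features))

#' @rdname ViewTable-accessors
#' @export
setMethod("featureIds", "ViewTable", function(x) colnames(x@features))

#' @rdname ViewTable-accessors
#' @export
setMethod("featureMatrix", "ViewTable", function(x) x@features)

#' @export
setMethod("dim", "ViewTable", function(x) dim(x@features))

setMethod("show", "ViewTable", function(object) {
  cat(sprintf("ViewTable '%s': %d samples x %d features\n",
              object@viewId, nrow(object@features), ncol(object@features)))
})

#' Encode and decode class labels
#'
#' `encodeLabels` builds a [LabelEncoding-class] from a vector of external
#' labels (ordered by `sort(unique(...))`); `encode` maps external labels to
#' internal codes 1..C and `decode` maps codes back, with the artificial
#' code 0 decoding to `NA` (it is never a real class).
#'
#' @param labels vector of external class labels.
#' @param enc a [LabelEncoding-class].
#' @param x labels (for `encode`) or integer codes (for `decode`).
#' @return `encodeLabels`: a `LabelEncoding`; `encode`: integer codes;
#'   `decode`: external labels.
#' @export
encodeLabels <- function(labels) {
  new("LabelEncoding", levels = as.character(sort(unique(labels))))
}

#' @rdname encodeLabels
#' @export
encode <- function(enc, x) {
  code <- match(as.character(x), enc@levels)
  if (anyNA(code))
    stop("unknown class label(s): ",
         paste(unique(as.character(x)[is.na(code)]), collapse = ", "))
  code
}

#' @rdname encodeLabels
#' @export
decode <- function(enc, x) {
  out <- rep(NA_character_, length(x))
  real <- x >= 1L
  out[real] <- enc@levels[x[real]]
  out
}

#' Assemble a multi-view dataset from views and labels
#'
#' Computes the full sample set N as the union of the views' sample sets
#' (first-appearance order across views) and encodes the labels as 1..C.
#' Every sample appearing in any view must be labeled; views may cover
#' arbitrary, possibly disjoint, subsets of N.
#'
#' @param views list of [ViewTable-class] objects (non-empty, unique ids).
#' @param labels vector of class labels named by sample id, covering at
#'   least every sample that appears in some view.
#' @param metadata optional list of annotations.
#' @return a [MultiViewDataset-class].
#' @examples
#' v1 <- ViewTable("a16S", matrix(1:6, 3, dimnames = list(c("s1","s2","s3"),
#'                                                        c("f1","f2"))))
#' v2 <- ViewTable("wgs",  matrix(1:4, 2, dimnames = list(c("s2","s4"),
#'                                                        c("g1","g2"))))
#' ds <- assembleDataset(list(v1, v2),
#'                       c(s1 = "TD", s2 = "ASD", s3 = "TD", s4 = "ASD"))
#' allSamples(ds)
#' @export
assembleDataset <- function(views, labels, metadata = list()) {
  if (!length(views)) stop("at least one view is required")
  for (v in views) if (nrow(v@features) == 0L)
    stop("view '", v@viewId, "' is empty")
  all_s <- unique(unlist(lapply(views, sampleIds)))
  if (is.null(names(labels))) stop("'labels' must be named by sample id")
  missing_lab <- setdiff(all_s, names(labels))
  if (length(missing_lab))
    stop("unlabeled sample(s): ", paste(missing_lab, collapse = ", "))
  labels <- labels[all_s]
  enc <- encodeLabels(labels)
  code <- stats::setNames(encode(enc, labels), all_s)
  new("MultiViewDataset", views = views, labels = code, encoding = enc,
      metadata = metadata)
}

#' Accessors for MultiViewDataset
#'
#' @param x a [MultiViewDataset-class].
#' @param external for `sampleLabels`: return external labels rather than
#'   internal codes 1..C.
#' @return `views`: list of `ViewTable`; `viewNames`: character view ids;
#'   `nViews`: K; `allSamples`: the ordered union N of all views' samples;
#'   `sampleLabels`: named label vector over N; `membershipMask`: K x |N|
#'   logical matrix of per-view sample presence.
#' @name MultiViewDataset-accessors
NULL

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("views", "MultiViewDataset", function(x) x@views)

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("viewNames", "MultiViewDataset",
  function(x) vapply(x@views, viewId, character(1)))

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("nViews", "MultiViewDataset", function(x) length(x@views))

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("allSamples", "MultiViewDataset", function(x) names(x@labels))

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("sampleLabels", "MultiViewDataset",
  function(x, external = FALSE) {
    if (external) stats::setNames(decode(x@encoding, x@labels),
                                  names(x@labels))
    else x@labels
  })

#' @rdname MultiViewDataset-accessors
#' @export
setMethod("membershipMask", "MultiViewDataset", function(x) {
  n <- allSamples(x)
  m <- vapply(x@views, function(v) n %in% sampleIds(v), logical(length(n)))
  m <- matrix(m, nrow = length(n),
              dimnames = list(n, viewNames(x)))
  t(m)
})

#' Extract one view by id or index
#'
#' @param x a [MultiViewDataset-class].
#' @param which view id (character) or index.
#' @return a [ViewTable-class].
#' @export
getView <- function(x, which) {
  stopifnot(is(x, "MultiViewDataset"))
  if (is.character(which)) {
    i <- match(which, viewNames(x))
    if (is.na(i)) stop("no view named '", which, "'")
  } else i <- which
  x@views[[i]]
}

#' Number of classes in a dataset
#' @param x a [MultiViewDataset-class].
#' @export
nClasses <- function(x) length(x@encoding@levels)

setMethod("show", "MultiViewDataset", function(object) {
  mask <- membershipMask(object)
  cat(sprintf(
    "MultiViewDataset: %d samples, %d view(s), %d class(es)\n",
    length(object@labels), length(object@views),
    length(object@encoding@levels)))
  for (v in object@views) {
    n_j <- nrow(v@features)
    cat(sprintf("  %s: %d/%d samples, %d features%s\n", v@viewId,
                n_j, length(object@labels), ncol(v@features),
                if (n_j == length(object@labels)) " (complete)"
                else " (incomplete)"))
  }
})

#' Restrict a dataset to a subset of samples
#'
#' Intersects every view with `keep` (preserving each view's internal sample
#' order) and drops labels outside `keep`. Views whose intersection with
#' `keep` is empty are retained as empty views (0-row feature matrix) and
#' flagged via a message, so cross-validation folds and subsetting
#' constructions never silently change K. The label encoding is preserved
#' even if some classes disappear from the subset.
#'
#' @param ds a [MultiViewDataset-class].
#' @param keep character vector of sample ids (must intersect the dataset).
#' @return a [MultiViewDataset-class] over `keep` (in original N order).
#' @export
restrictToSamples <- function(ds, keep) {
  stopifnot(is(ds, "MultiViewDataset"))
  keep <- intersect(allSamples(ds), keep)
  if (!length(keep)) stop("'keep' shares no samples with the dataset")
  views <- lapply(ds@views, function(v) {
    rows <- intersect(sampleIds(v), keep)
    if (!length(rows))
      message("view '", v@viewId, "' is empty after restriction")
    new("ViewTable", viewId = v@viewId,
        features = v@features[rows, , drop = FALSE])
  })
  new("MultiViewDataset", views = views, labels = ds@labels[keep],
      encoding = ds@encoding, metadata = ds@metadata)
}
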