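#' @rdname ViewTable-accessors
#' @export
setGeneric("viewId", function(x) standardGeneric("viewId"))

#' @rdname ViewTable-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ViewTable-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname ViewTable-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("views", function(x) standardGeneric("views"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("allSamples", function(x) standardGeneric("allSamples"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("sampleLabels", function(x, external = FALSE)
  standardGeneric("sampleLabels"))

#' @rdname MultiViewDataset-accessors
#' @export
setGeneric("membershipMask", function(x) standardGeneric("membershipMask"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("winnerCounts", function(x) standardGeneric("winnerCounts"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("banditTrace", function(x) standardGeneric("banditTrace"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))
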