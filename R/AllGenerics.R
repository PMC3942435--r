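#' @rdname cellTable
#' @export
setGeneric("cellTable", function(x, ...) standardGeneric("cellTable"))

#' @rdname screenLayout
#' @export
setGeneric("screenLayout", function(x, ...) standardGeneric("screenLayout"))

#' @rdname truthTable
#' @export
setGeneric("truthTable", function(x, ...) standardGeneric("truthTable"))

#' @rdname featureFamily
#' @export
setGeneric("featureFamily", function(x, ...) standardGeneric("featureFamily"))

#' @rdname zScores
#' @export
setGeneric("zScores", function(x, ...) standardGeneric("zScores"))

#' @rdname heldOutWells
#' @export
setGeneric("heldOutWells", function(x, ...) standardGeneric("heldOutWells"))
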