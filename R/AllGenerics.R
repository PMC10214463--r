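#' @rdname DepthRecord-class
#' @param x,object a `DepthRecord`.
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname DepthRecord-class
#' @export
setGeneric("recordTime", function(x) standardGeneric("recordTime"))

#' @rdname DepthRecord-class
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' @rdname DiveTable-class
#' @param x,object a `DiveTable`.
#' @export
setGeneric("diveData", function(x) standardGeneric("diveData"))

#' @rdname DiveTable-class
#' @export
setGeneric("nDives", function(x) standardGeneric("nDives"))

#' @rdname Track-class
#' @param x a `Track`.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
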