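#' @rdname SiteTable-class
#' @param x a [SiteTable-class] object.
#' @export
setGeneric("derivedFreq", function(x) standardGeneric("derivedFreq"))

#' @rdname SiteTable-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname DStatResult-class
#' @param object an object.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname DStatResult-class
#' @export
setGeneric("rotated", function(object) standardGeneric("rotated"))
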