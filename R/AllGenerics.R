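#' @rdname CoverageTrack-class
#' @export
setGeneric("trackDepths", function(x) standardGeneric("trackDepths"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname FrapFit-class
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname FrapFit-class
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))

#' @rdname FrapFit-class
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))

#' @rdname FrapFit-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname GenomeSpec-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname RibbonProfile-class
#' @export
setGeneric("ribbonWindows", function(x) standardGeneric("ribbonWindows"))

#' @rdname FrapTrace-class
#' @export
setGeneric("normalizeTrace",
    function(trace, mode = c("subtracted", "literal"))
        standardGeneric("normalizeTrace"))
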