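#' @export
setGeneric("profileName", function(x) standardGeneric("profileName"))

#' @export
setGeneric("truePositives", function(x) standardGeneric("truePositives"))

#' @export
setGeneric("falsePositives", function(x) standardGeneric("falsePositives"))

#' @export
setGeneric("totalWeeds", function(x) standardGeneric("totalWeeds"))

#' @export
setGeneric("precision", function(x) standardGeneric("precision"))

#' @export
setGeneric("recall", function(x) standardGeneric("recall"))

#' @export
setGeneric("sceneFrame", function(x) standardGeneric("sceneFrame"))

#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @export
setGeneric("sceneSeed", function(x) standardGeneric("sceneSeed"))

#' @export
setGeneric("zoneWidthGround", function(x) standardGeneric("zoneWidthGround"))
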