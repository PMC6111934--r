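#' @rdname AttributeSchema-class
#' @param x an object
#' @export
setGeneric("schemaDim", function(x) standardGeneric("schemaDim"))

#' @rdname AttributeSchema-class
#' @export
setGeneric("jointNames", function(x) standardGeneric("jointNames"))

#' @rdname AttributeSchema-class
#' @export
setGeneric("jointKinds", function(x) standardGeneric("jointKinds"))

#' @rdname AttributeSchema-class
#' @export
setGeneric("wrcWeights", function(x) standardGeneric("wrcWeights"))

#' @rdname AttributeSet-class
#' @param x an object
#' @export
setGeneric("attrValues", function(x) standardGeneric("attrValues"))

#' @rdname AttributeSet-class
#' @export
setGeneric("poseLabels", function(x) standardGeneric("poseLabels"))

#' @rdname AttributeSet-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname PrototypeSet-class
#' @param x an object
#' @export
setGeneric("protoLabels", function(x) standardGeneric("protoLabels"))

#' @rdname PrototypeSet-class
#' @export
setGeneric("protoVectors", function(x) standardGeneric("protoVectors"))

#' @rdname EvalResult-class
#' @param x an object
#' @export
setGeneric("perClassF", function(x) standardGeneric("perClassF"))

#' @rdname EvalResult-class
#' @export
setGeneric("averageF", function(x) standardGeneric("averageF"))

#' @rdname EvalResult-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
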