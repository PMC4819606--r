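#' @name panelGMLVQ-generics
#' @title Generics for panel containers and models
#' @description Accessor and analysis generics; see the class and method
#'   pages for details.
#' @param x,object,model an object of the documented class
#' @param ... passed to methods
#' @keywords internal
NULL

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("valueScale", function(x) standardGeneric("valueScale"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("preprocessingRecord", function(x) standardGeneric("preprocessingRecord"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("relevanceMatrix", function(object) standardGeneric("relevanceMatrix"))

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("trainingTrace", function(object) standardGeneric("trainingTrace"))

#' Extract the per-gene relevance profile of a trained model
#'
#' @param model a trained [GMLVQModel-class]
#' @param ... unused
#' @return a [RelevanceProfile-class]
#' @export
setGeneric("relevanceProfile", function(model, ...) standardGeneric("relevanceProfile"))

#' Train a GMLVQ classifier
#'
#' @param x samples x features numeric matrix, or a [CytokinePanel-class]
#'   on the `logrq` scale
#' @param ... see the matrix method for the full argument list
#' @export
setGeneric("trainGMLVQ", function(x, ...) standardGeneric("trainGMLVQ"))
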