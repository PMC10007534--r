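#' @name strokegcn-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the package's classes.
#' @param x an object
#' @keywords internal
NULL

#' @rdname strokegcn-generics
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname strokegcn-generics
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname strokegcn-generics
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname strokegcn-generics
#' @export
setGeneric("normalizedAdjacency", function(x) standardGeneric("normalizedAdjacency"))

#' @rdname strokegcn-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname strokegcn-generics
#' @export
setGeneric("classId", function(x) standardGeneric("classId"))

#' @rdname strokegcn-generics
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname strokegcn-generics
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
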