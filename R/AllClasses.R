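#' MarkerSet: an ordered, labelled set of motion-capture markers
#'
#' Holds the ordered marker labels that define node indexing everywhere in
#' the package, together with a grouping of each label into a body segment
#' (or `"racket"`). The order is stable: it fixes the rows of every
#' adjacency matrix and the layout of every trained weight matrix.
#'
#' @slot labels ordered character vector of unique marker labels
#' @slot groups named character vector mapping label -> segment name
#' @export
setClass("MarkerSet",
  representation(labels = "character", groups = "character"))

setValidity("MarkerSet", function(object) {
  msgs <- character()
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "marker labels must be unique")
  if (length(object@groups) != length(object@labels) ||
      !identical(names(object@groups), object@labels))
    msgs <- c(msgs, "groups must be named exactly by the labels, in order")
  if (length(msgs)) msgs else TRUE
})

#' SkeletonGraph: marker graph with normalized adjacency
#'
#' The marker graph G = (V, E) used by the spatial graph convolution. Stores
#' the raw binary adjacency O, the self-looped adjacency O + I, the degree
#' diagonal of the self-looped adjacency, and the symmetrically normalized
#' adjacency D^(-1/2) (O + I) D^(-1/2) that the convolution multiplies by.
#'
#' @slot nodeOrder ordered node labels (length M)
#' @slot O M x M binary symmetric adjacency, zero diagonal
#' @slot Otilde O + I
#' @slot Ttilde degree vector: row sums of Otilde (diagonal of the degree matrix)
#' @slot Ahat symmetrically normalized adjacency
#' @export
setClass("SkeletonGraph",
  representation(nodeOrder = "character", O = "matrix", Otilde = "matrix",
                 Ttilde = "numeric", Ahat = "matrix"))

setValidity("SkeletonGraph", function(object) {
  msgs <- character()
  M <- length(object@nodeOrder)
  if (!all(dim(object@O) == c(M, M)))
    msgs <- c(msgs, "O must be M x M")
  else {
    if (!isSymmetric(unname(object@O))) msgs <- c(msgs, "O must be symmetric")
    if (any(diag(object@O) != 0)) msgs <- c(msgs, "O must have zero diagonal")
    if (!all(object@O %in% c(0, 1))) msgs <- c(msgs, "O must be binary")
    if (any(object@Ttilde <= 0)) msgs <- c(msgs, "degrees must be positive")
    if (max(abs(object@Otilde - (object@O + diag(M)))) > 0)
      msgs <- c(msgs, "Otilde must equal O + I")
    if (max(abs(rowSums(object@Otilde) - object@Ttilde)) > 0)
      msgs <- c(msgs, "Ttilde must be the row sums of Otilde")
  }
  if (length(msgs)) msgs else TRUE
})

#' Trial: one recorded (or synthesized) stroke
#'
#' @slot coords numeric array frames x markers x 3, millimetres
#' @slot label integer class id in 0..3
#'   (0 forehand, 1 backhand, 2 volley forehand, 3 volley backhand)
#' @slot markerNames marker labels in coordinate column order
#' @slot subjectId subject identifier
#' @slot handedness "left" or "right"
#' @slot rate capture rate in Hz
#' @slot source file path or "synthetic"
#' @export
setClass("Trial",
  representation(coords = "array", label = "integer", markerNames = "character",
                 subjectId = "character", handedness = "character",
                 rate = "numeric", source = "character"))

setValidity("Trial", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    msgs <- c(msgs, "coords must be a frames x markers x 3 array")
  else {
    if (d[1] < 1) msgs <- c(msgs, "trial must have at least one frame")
    if (d[2] != length(object@markerNames))
      msgs <- c(msgs, "marker dimension must match markerNames")
    if (!all(is.finite(object@coords)))
      msgs <- c(msgs, "coords must be finite")
  }
  if (!(object@label %in% 0:3)) msgs <- c(msgs, "label must be in 0..3")
  if (!(object@handedness %in% c("left", "right")))
    msgs <- c(msgs, "handedness must be 'left' or 'right'")
  if (object@rate <= 0) msgs <- c(msgs, "rate must be positive")
  if (length(msgs)) msgs else TRUE
})

#' TrialSet: a labelled collection of trials sharing one marker set
#'
#' @slot trials list of [Trial-class] objects
#' @slot markerNames common marker order
#' @slot classNames the four stroke class names, indexed by label + 1
#' @export
setClass("TrialSet",
  representation(trials = "list", markerNames = "character",
                 classNames = "character"))

setValidity("TrialSet", function(object) {
  msgs <- character()
  if (length(object@classNames) != 4)
    msgs <- c(msgs, "classNames must have length 4")
  for (tr in object@trials) {
    if (!is(tr, "Trial")) { msgs <- c(msgs, "trials must contain Trial objects"); break }
    if (!identical(tr@markerNames, object@markerNames)) {
      msgs <- c(msgs, "all trials must share the TrialSet marker order"); break
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---- constructors -------------------------------------------------------

MarkerSet <- function(labels, groups) {
  new("MarkerSet", labels = labels, groups = setNames(groups, labels))
}

Trial <- function(coords, label, markerNames, subjectId = "unknown",
                  handedness = "right", rate = 100, source = "synthetic") {
  dimnames(coords) <- NULL
  new("Trial", coords = coords, label = as.integer(label),
      markerNames = markerNames, subjectId = subjectId,
      handedness = handedness, rate = rate, source = source)
}

TrialSet <- function(trials, markerNames, classNames = CLASS_NAMES) {
  new("TrialSet", trials = trials, markerNames = markerNames,
      classNames = classNames)
}

## ---- accessors ----------------------------------------------------------

#' @rdname strokegcn-generics
#' @export
setMethod("markerNames", "MarkerSet", function(x) x@labels)
#' @rdname strokegcn-generics
#' @export
setMethod("markerNames", "SkeletonGraph", function(x) x@nodeOrder)
#' @rdname strokegcn-generics
#' @export
setMethod("markerNames", "Trial", function(x) x@markerNames)
#' @rdname strokegcn-generics
#' @export
setMethod("markerNames", "TrialSet", function(x) x@markerNames)

#' @rdname strokegcn-generics
#' @export
setMethod("nMarkers", "MarkerSet", function(x) length(x@labels))
#' @rdname strokegcn-generics
#' @export
setMethod("nMarkers", "SkeletonGraph", function(x) length(x@nodeOrder))
#' @rdname strokegcn-generics
#' @export
setMethod("nMarkers", "Trial", function(x) dim(x@coords)[2])
#' @rdname strokegcn-generics
#' @export
setMethod("nMarkers", "TrialSet", function(x) length(x@markerNames))

#' @rdname strokegcn-generics
#' @export
setMethod("adjacency", "SkeletonGraph", function(x) {
  m <- x@O
  dimnames(m) <- list(x@nodeOrder, x@nodeOrder)
  m
})

#' @rdname strokegcn-generics
#' @export
setMethod("normalizedAdjacency", "SkeletonGraph", function(x) x@Ahat)

#' @rdname strokegcn-generics
#' @export
setMethod("nFrames", "Trial", function(x) dim(x@coords)[1])

#' Maximum frame count over a trial set
#'
#' The corpus-wide maximum number of frames, to which [padToMax()] pads.
#' @param x a [TrialSet-class]
#' @return integer
#' @rdname strokegcn-generics
#' @export
setMethod("nFrames", "TrialSet", function(x) {
  if (!length(x@trials)) return(0L)
  max(vapply(x@trials, nFrames, integer(1)))
})

#' @rdname strokegcn-generics
#' @export
setMethod("classId", "Trial", function(x) x@label)

#' @rdname strokegcn-generics
#' @export
setMethod("trials", "TrialSet", function(x) x@trials)

#' @rdname strokegcn-generics
#' @export
setMethod("classCounts", "TrialSet", function(x) {
  labs <- vapply(x@trials, classId, integer(1))
  cnt <- vapply(0:3, function(k) sum(labs == k), integer(1))
  setNames(cnt, x@classNames)
})

#' Number of trials in a set
#' @param x a [TrialSet-class]
#' @export
setMethod("length", "TrialSet", function(x) length(x@trials))

#' Extract a subset of trials
#' @param x a [TrialSet-class]
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  TrialSet(x@trials[i], x@markerNames, x@classNames)
})

#' Extract one trial
#' @param x a [TrialSet-class]
#' @param i index
#' @param j,... ignored
#' @export
setMethod("[[", "TrialSet", function(x, i, j, ...) x@trials[[i]])

## ---- show ---------------------------------------------------------------

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet with %d markers (%s)\n", length(object@labels),
              paste(unique(object@groups), collapse = ", ")))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph with %d nodes, %d edges\n",
              length(object@nodeOrder), sum(object@O) / 2))
})

setMethod("show", "Trial", function(object) {
  cat(sprintf("Trial: %s, %d frames x %d markers @ %g Hz (%s-handed, %s)\n",
              CLASS_NAMES[object@label + 1L], nFrames(object),
              nMarkers(object), object@rate, object@handedness,
              object@subjectId))
})

setMethod("show", "TrialSet", function(object) {
  cnt <- classCounts(object)
  cat(sprintf("TrialSet: %d trials x %d markers, nf = %d\n",
              length(object@trials), length(object@markerNames),
              nFrames(object)))
  cat("  ", paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", "), "\n")
})
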