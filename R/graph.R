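## Marker graph construction and symmetric normalization.
##
## The spatial convolution multiplies node features by
## Ahat = D^(-1/2) (O + I) D^(-1/2), where O is the binary marker adjacency
## and D the degree diagonal of O + I. Two presets are shipped: the
## 39-marker Plug-in Gait body graph and its 46-node extension with a
## rigid 7-marker racket.

extdataFile <- function(name) {
  p <- system.file("extdata", name, package = "strokegcn")
  if (!nzchar(p)) stop("shipped data file not found: ", name)
  p
}

readTokenFile <- function(path, ncol) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, length, integer(1)) < ncol
  if (any(bad))
    stop("line with fewer than ", ncol, " fields in ", path)
  do.call(rbind, lapply(toks, function(x) x[seq_len(ncol)]))
}

#' Load a marker set
#'
#' Loads one of the shipped marker presets, or a user label file with one
#' `label [group]` pair per line (`#` comments allowed). The returned order
#' is stable across calls and defines node indexing throughout the package.
#'
#' @param preset `"plug_in_gait_39"` (the 39-marker Plug-in Gait body
#'   model), `"racket_7"` (the 7-marker rigid racket), or a path to a
#'   readable label file.
#' @return a [MarkerSet-class]
#' @examples
#' body <- loadMarkerSet("plug_in_gait_39")
#' nMarkers(body)  # 39
#' @export
loadMarkerSet <- function(preset) {
  path <- switch(preset,
    plug_in_gait_39 = extdataFile("plug_in_gait_39.txt"),
    racket_7 = extdataFile("racket_7.txt"),
    {
      if (!file.exists(preset))
        stop("unknown marker preset or unreadable file: ", preset)
      preset
    })
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  labels <- vapply(parts, `[`, character(1), 1)
  groups <- vapply(parts, function(x) if (length(x) >= 2) x[2] else "unassigned",
                   character(1))
  if (anyDuplicated(labels))
    stop("duplicate marker label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  MarkerSet(labels, groups)
}

#' Read an edge table
#'
#' One unordered label pair per line, `#` comments allowed.
#'
#' @param path file path
#' @return two-column character matrix of label pairs
#' @export
readEdgeTable <- function(path) {
  m <- readTokenFile(path, 2)
  colnames(m) <- c("from", "to")
  m
}

#' The shipped anatomical edge table for the Plug-in Gait body graph
#'
#' The Plug-in Gait marker model does not define a graph topology; this table chains
#' markers along body segments and joins segments at shared landmarks. It
#' is the package's own construction and can be replaced by any edge file
#' via [readEdgeTable()].
#'
#' @return two-column character matrix of label pairs
#' @export
defaultBodyEdges <- function() readEdgeTable(extdataFile("plug_in_gait_edges.txt"))

#' Symmetrically normalize an adjacency matrix
#'
#' Computes `Ahat = D^(-1/2) (O + I) D^(-1/2)` where `D` is the degree
#' diagonal of the self-looped adjacency `O + I`. For a binary `O` every
#' entry of the result lies in `[0, 1]` and `Ahat` is symmetric.
#'
#' @param O square symmetric non-negative adjacency matrix
#' @return normalized adjacency matrix of the same dimension
#' @examples
#' normalizeAdjacency(matrix(0, 1, 1))          # [[1]]
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2)) # all entries 0.5
#' @export
normalizeAdjacency <- function(O) {
  if (!is.matrix(O) || nrow(O) != ncol(O))
    stop("adjacency must be a square matrix")
  if (!isSymmetric(unname(O)))
    stop("adjacency must be symmetric")
  if (any(O < 0)) stop("adjacency must be non-negative")
  Ot <- O + diag(nrow(O))
  d <- rowSums(Ot)
  s <- 1 / sqrt(d)
  # D^(-1/2) Otilde D^(-1/2) without forming diagonal matrices
  Ot * tcrossprod(s)
}

newSkeletonGraph <- function(nodeOrder, O) {
  dimnames(O) <- NULL
  Ot <- O + diag(nrow(O))
  new("SkeletonGraph", nodeOrder = nodeOrder, O = O, Otilde = Ot,
      Ttilde = rowSums(Ot), Ahat = normalizeAdjacency(O))
}

#' Build the body marker graph
#'
#' @param markers a [MarkerSet-class]
#' @param edges two-column character matrix of unordered label pairs
#'   (default: the shipped anatomical table for the 39-marker body)
#' @return a [SkeletonGraph-class]
#' @examples
#' g <- buildBodyGraph(loadMarkerSet("plug_in_gait_39"))
#' nMarkers(g)  # 39
#' @export
buildBodyGraph <- function(markers, edges = defaultBodyEdges()) {
  labs <- markerNames(markers)
  M <- length(labs)
  O <- matrix(0, M, M)
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges[, 1], edges[, 2]), labs)
    if (length(unknown))
      stop("edge references unknown label(s): ",
           paste(unique(unknown), collapse = ", "))
    i <- match(edges[, 1], labs); j <- match(edges[, 2], labs)
    if (any(i == j)) stop("self-edges are not allowed")
    O[cbind(i, j)] <- 1
    O[cbind(j, i)] <- 1
  }
  newSkeletonGraph(labs, O)
}

#' Attach the rigid racket to a body graph
#'
#' Appends the 7 racket nodes after the body nodes. The racket markers form
#' a complete subgraph (a rigid body: all pairwise distances are constant,
#' so every racket marker is informative about every other), and the
#' handle-bottom marker is connected to the dominant-hand wrist and finger
#' markers. Normalization is recomputed for the 46-node graph.
#'
#' @param body a 39-node body [SkeletonGraph-class]
#' @param racket the racket [MarkerSet-class] (labels disjoint from the body)
#' @param attachment two-column matrix of racket-to-body label pairs, or
#'   `NULL` for the shipped default; an empty matrix yields a valid but
#'   disconnected graph (a warning is issued)
#' @param hand dominant hand, `"right"` or `"left"`; flips the `R*`/`L*`
#'   labels of the default attachment
#' @return a [SkeletonGraph-class] with `M = 46`
#' @export
attachRacket <- function(body, racket = loadMarkerSet("racket_7"),
                         attachment = NULL, hand = c("right", "left")) {
  hand <- match.arg(hand)
  if (nMarkers(body) != 39)
    stop("body graph must have 39 nodes, got ", nMarkers(body))
  rlabs <- markerNames(racket)
  blabs <- markerNames(body)
  if (length(intersect(rlabs, blabs)))
    stop("racket labels collide with body labels")
  if (is.null(attachment)) {
    attachment <- readEdgeTable(extdataFile("racket_attachment.txt"))
    if (hand == "left") {
      swp <- attachment[, 2]
      attachment[, 2] <- ifelse(substr(swp, 1, 1) == "R",
                                sub("^R", "L", swp), sub("^L", "R", swp))
    }
  }
  labs <- c(blabs, rlabs)
  M <- length(labs)
  O <- matrix(0, M, M)
  O[seq_along(blabs), seq_along(blabs)] <- body@O
  # rigid body: complete subgraph among racket markers
  ridx <- length(blabs) + seq_along(rlabs)
  O[ridx, ridx] <- 1
  diag(O)[ridx] <- 0
  if (nrow(attachment) == 0) {
    warning("empty attachment: racket subgraph is disconnected from the body")
  } else {
    unknown <- setdiff(c(attachment[, 1], attachment[, 2]), labs)
    if (length(unknown))
      stop("attachment references unknown label(s): ",
           paste(unique(unknown), collapse = ", "))
    i <- match(attachment[, 1], labs); j <- match(attachment[, 2], labs)
    O[cbind(i, j)] <- 1
    O[cbind(j, i)] <- 1
  }
  newSkeletonGraph(labs, O)
}

#' Export a graph adjacency as labelled CSV
#'
#' @param graph a [SkeletonGraph-class]
#' @param path output file
#' @export
exportAdjacency <- function(graph, path) {
  write.csv(adjacency(graph), path)
  invisible(path)
}
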