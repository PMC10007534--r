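## Dataset assembly, padding, racket stripping, mirroring, and the
## coordinate preprocessing the classifier consumes.

#' Assemble a labelled trial set from a directory of C3D files
#'
#' The label map is a CSV with columns `filename,label,subject,handedness`;
#' `label` is one of the four class names (or an id 0..3). Per-class counts
#' are reported via `message()`.
#'
#' @param root directory containing the C3D files
#' @param labelMap path to the label CSV
#' @param markers the expected [MarkerSet-class] (order is enforced)
#' @return a [TrialSet-class]
#' @export
assembleDataset <- function(root, labelMap, markers) {
  map <- read.csv(labelMap, stringsAsFactors = FALSE)
  need <- c("filename", "label", "subject", "handedness")
  if (!all(need %in% names(map)))
    stop("label map must have columns: ", paste(need, collapse = ", "))
  if (nrow(map) == 0) stop("label map is empty")
  labs <- map$label
  if (is.character(labs)) {
    idx <- match(labs, CLASS_NAMES) - 1L
    if (anyNA(idx))
      stop("label(s) outside the four-class set: ",
           paste(unique(labs[is.na(idx)]), collapse = ", "))
    labs <- idx
  } else if (!all(labs %in% 0:3)) {
    stop("numeric labels must be in 0..3")
  }
  trialList <- vector("list", nrow(map))
  for (k in seq_len(nrow(map))) {
    path <- file.path(root, map$filename[k])
    if (!file.exists(path)) stop("listed file does not exist: ", path)
    trialList[[k]] <- readC3D(path, markers, label = labs[k],
                              subjectId = as.character(map$subject[k]),
                              handedness = map$handedness[k])
  }
  set <- TrialSet(trialList, markerNames(markers))
  cnt <- classCounts(set)
  message("assembled ", length(set), " trials: ",
          paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  set
}

#' Zero-pad all trials to the corpus-wide maximum frame count
#'
#' Trial `i` occupies frames `1..T_i` unchanged; frames `T_i+1..nf` are
#' exactly zero (trailing padding, after the movement).
#'
#' @param set a non-empty [TrialSet-class]
#' @param nf pad target; defaults to the set's maximum frame count
#' @return list with `tensor` (N x nf x M x 3 array) and `lengths`
#'   (integer vector of original frame counts)
#' @export
padToMax <- function(set, nf = NULL) {
  if (!length(set)) stop("cannot pad an empty trial set")
  lens <- vapply(trials(set), nFrames, integer(1))
  if (is.null(nf)) nf <- max(lens)
  if (nf < max(lens)) stop("nf is smaller than the longest trial")
  M <- nMarkers(set)
  out <- array(0, dim = c(length(set), nf, M, 3))
  for (i in seq_along(trials(set)))
    out[i, seq_len(lens[i]), , ] <- set[[i]]@coords
  list(tensor = out, lengths = lens)
}

#' Remove the racket channels from a 46-marker trial set
#'
#' Keeps the 39 body markers bit-identical and preserves labels and order;
#' this is the "player silhouette only" experimental condition.
#'
#' @param set a 46-marker [TrialSet-class]
#' @return a 39-marker [TrialSet-class]
#' @export
stripRacket <- function(set) {
  if (nMarkers(set) != 46)
    stop("stripRacket expects a 46-marker set, got ", nMarkers(set))
  keep <- !startsWith(markerNames(set), "RKT_")
  if (sum(keep) != 39) stop("could not identify 39 body markers")
  newTrials <- lapply(trials(set), function(tr) {
    Trial(tr@coords[, keep, , drop = FALSE], tr@label,
          tr@markerNames[keep], tr@subjectId, tr@handedness, tr@rate,
          tr@source)
  })
  TrialSet(newTrials, markerNames(set)[keep], set@classNames)
}

# left<->right label partner; labels without a contralateral partner
# (RBAK, racket midline markers) map to themselves
mirrorLabel <- function(labels) {
  out <- labels
  for (k in seq_along(labels)) {
    l <- labels[k]
    cand <- if (startsWith(l, "RKT_SIDE_L")) sub("_L", "_R", l, fixed = TRUE)
      else if (startsWith(l, "RKT_SIDE_R")) sub("_R", "_L", l, fixed = TRUE)
      else if (startsWith(l, "RKT_")) l
      else if (l == "RBAK") l
      else if (startsWith(l, "L")) sub("^L", "R", l)
      else if (startsWith(l, "R")) sub("^R", "L", l)
      else l
    out[k] <- if (cand %in% labels) cand else l
  }
  out
}

#' Mirror a trial left-right
#'
#' Reflects the x (lateral) axis and swaps left/right marker labels, so a
#' left-handed stroke becomes its right-handed image. An involution, and an
#' isometry: inter-marker distances are preserved. The RBAK scapula marker
#' has no left counterpart in Plug-in Gait, so only its coordinates are
#' reflected.
#'
#' @param trial a [Trial-class]
#' @return the mirrored [Trial-class], with handedness flipped
#' @export
mirrorTrial <- function(trial) {
  labs <- markerNames(trial)
  partner <- mirrorLabel(labs)
  idx <- match(partner, labs)
  coords <- trial@coords[, idx, , drop = FALSE]
  coords[, , 1] <- -coords[, , 1]
  Trial(coords, trial@label, labs, trial@subjectId,
        if (trial@handedness == "left") "right" else "left",
        trial@rate, trial@source)
}

#' Standardize handedness across a trial set
#'
#' Mirrors every left-handed trial into the right-handed convention, so the
#' minority left-handed players (about 1 in 10) do not act as label noise
#' for the classifier.
#'
#' @param set a [TrialSet-class]
#' @return a [TrialSet-class] with all trials right-handed
#' @export
standardizeHandedness <- function(set) {
  newTrials <- lapply(trials(set), function(tr)
    if (tr@handedness == "left") mirrorTrial(tr) else tr)
  TrialSet(newTrials, markerNames(set), set@classNames)
}

#' Center and scale trial coordinates for the network
#'
#' Translates each trial so that the first frame's mid-pelvis point (mean
#' of LASI, RASI, LPSI, RPSI) is the origin, and rescales millimetres to
#' metres. Both steps are configurable; without them raw mm-scale inputs
#' saturate the sigmoid stages of the graph convolution.
#'
#' @param trial a [Trial-class]
#' @param center,scale logical switches
#' @return a [Trial-class]
#' @export
normalizeTrial <- function(trial, center = TRUE, scale = TRUE) {
  coords <- trial@coords
  if (center) {
    pelvis <- match(c("LASI", "RASI", "LPSI", "RPSI"), trial@markerNames)
    pelvis <- pelvis[!is.na(pelvis)]
    origin <- if (length(pelvis)) colMeans(trial@coords[1, pelvis, , drop = FALSE][1, , ])
              else colMeans(trial@coords[1, , ])
    coords <- sweep(coords, 3, origin)
  }
  if (scale) coords <- coords / 1000
  Trial(coords, trial@label, trial@markerNames, trial@subjectId,
        trial@handedness, trial@rate, trial@source)
}

# TrialSet -> list(inputs = list of nf x M x 3 arrays, labels = int vector)
# applying handedness standardization, centring/scaling, trailing padding
prepareInputs <- function(set, nf = NULL, center = TRUE, scale = TRUE,
                          standardize = TRUE) {
  if (standardize) set <- standardizeHandedness(set)
  set <- TrialSet(lapply(trials(set), normalizeTrial, center = center,
                         scale = scale),
                  markerNames(set), set@classNames)
  padded <- padToMax(set, nf)
  N <- length(set)
  inputs <- lapply(seq_len(N), function(i)
    array(padded$tensor[i, , , ], dim = dim(padded$tensor)[2:4]))
  list(inputs = inputs,
       labels = vapply(trials(set), classId, integer(1)),
       lengths = padded$lengths,
       nf = dim(padded$tensor)[2])
}
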