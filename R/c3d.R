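## Minimal C3D reader/writer.
##
## C3D is the binary interchange format for 3D marker trajectories in
## biomechanics: a 512-byte header block, a parameter section of
## group/parameter records, and a data section of per-frame point samples.
## The writer emits Intel (little-endian) files with floating-point point
## data, POINT:UNITS = "mm" by default and no analog channels. The reader
## accepts Intel and big-endian (SGI/MIPS) IEEE files with float or
## scaled-integer point data; DEC-float files are rejected. Analog data,
## if present, is ignored.

C3D_BLOCK <- 512L

rawInt <- function(r, at, size, endian, signed = TRUE) {
  readBin(r[at:(at + size - 1L)], "integer", n = 1L, size = size,
          endian = endian, signed = signed)
}

rawFloat <- function(r, at, n, endian) {
  readBin(r[at:(at + 4L * n - 1L)], "numeric", n = n, size = 4L,
          endian = endian)
}

## ---- writer -------------------------------------------------------------

c3dParamBytes <- function(name, type, dims, data, groupId) {
  nameRaw <- charToRaw(name)
  dataRaw <- switch(as.character(type),
    `-1` = charToRaw(paste(data, collapse = "")),
    `2`  = writeBin(as.integer(data), raw(), size = 2L, endian = "little"),
    `4`  = writeBin(as.numeric(data), raw(), size = 4L, endian = "little"),
    stop("unsupported parameter type"))
  body <- c(as.raw(if (type < 0) 256L + type else type),
            as.raw(length(dims)),
            as.raw(dims),
            dataRaw,
            as.raw(0L))                       # description length 0
  offset <- 2L + length(body)
  c(as.raw(length(nameRaw)), as.raw(groupId), nameRaw,
    writeBin(offset, raw(), size = 2L, endian = "little"), body)
}

c3dGroupBytes <- function(name, groupId) {
  nameRaw <- charToRaw(name)
  body <- as.raw(0L)                          # description length 0
  offset <- 2L + length(body)
  c(as.raw(length(nameRaw)), as.raw(256L - groupId), nameRaw,  # negative id
    writeBin(offset, raw(), size = 2L, endian = "little"), body)
}

#' Write a trial to a C3D file
#'
#' Emits a standard little-endian C3D file with floating-point point data:
#' POINT:USED, FRAMES, RATE, SCALE (-1), UNITS and LABELS are written, all
#' residuals are zero and there are no analog channels.
#'
#' @param trial a [Trial-class]
#' @param path output file path
#' @param units coordinate units to declare, `"mm"` (default) or `"m"`;
#'   coordinates are stored as-is, the declaration tells readers how to
#'   interpret them
#' @return `path`, invisibly
#' @export
writeC3D <- function(trial, path, units = "mm") {
  stopifnot(is(trial, "Trial"))
  nf <- nFrames(trial); np <- nMarkers(trial)
  if (nf < 1) stop("cannot write an empty trial")
  labels <- markerNames(trial)
  width <- max(nchar(labels), nchar(units), 4L)
  padTo <- function(x) formatC(x, width = width, flag = "-")

  params <- c(
    c3dGroupBytes("POINT", 1L),
    c3dParamBytes("USED", 2L, integer(0), np, 1L),
    c3dParamBytes("FRAMES", 2L, integer(0), nf, 1L),
    c3dParamBytes("RATE", 4L, integer(0), trial@rate, 1L),
    c3dParamBytes("SCALE", 4L, integer(0), -1, 1L),
    c3dParamBytes("UNITS", -1L, width, padTo(units), 1L),
    c3dParamBytes("LABELS", -1L, c(width, np), padTo(labels), 1L))
  # DATA_START written after sizing the parameter section
  nParamBlocks <- ceiling((length(params) + 4L + 13L + 2L + 4L + 3L) / C3D_BLOCK)
  dataStart <- 2L + nParamBlocks
  params <- c(params,
              c3dParamBytes("DATA_START", 2L, integer(0), dataStart, 1L))
  paramSection <- c(as.raw(c(0x01, 0x50)), as.raw(nParamBlocks), as.raw(84L),
                    params)
  paramSection <- c(paramSection,
                    raw(nParamBlocks * C3D_BLOCK - length(paramSection)))

  # header block: 256 little-endian int16 words
  hdr <- raw(C3D_BLOCK)
  putI <- function(h, word, val)
    { h[(2L*word-1L):(2L*word)] <- writeBin(as.integer(val), raw(), size = 2L,
                                            endian = "little"); h }
  putF <- function(h, word, val)
    { h[(2L*word-1L):(2L*word+2L)] <- writeBin(as.numeric(val), raw(),
                                               size = 4L, endian = "little"); h }
  hdr[1] <- as.raw(2L); hdr[2] <- as.raw(0x50)
  hdr <- putI(hdr, 2L, np)      # points per frame
  hdr <- putI(hdr, 3L, 0L)      # analog measurements per frame
  hdr <- putI(hdr, 4L, 1L)      # first frame
  hdr <- putI(hdr, 5L, nf)      # last frame
  hdr <- putI(hdr, 6L, 10L)     # max interpolation gap
  hdr <- putF(hdr, 7L, -1)      # scale: negative => float data
  hdr <- putI(hdr, 9L, dataStart)
  hdr <- putI(hdr, 10L, 0L)     # analog samples per frame
  hdr <- putF(hdr, 11L, trial@rate)

  # data: per frame, per point: x y z residual as float
  vals <- array(0, dim = c(4L, np, nf))
  vals[1:3, , ] <- aperm(trial@coords, c(3, 2, 1))
  dataRaw <- writeBin(as.numeric(vals), raw(), size = 4L, endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(paramSection, con)
  writeBin(dataRaw, con)
  invisible(path)
}

## ---- reader -------------------------------------------------------------

parseC3DParams <- function(r, paramStart, endian) {
  pos <- paramStart + 4L
  groups <- list()   # id -> name
  params <- list()   # "id:NAME" -> value list
  repeat {
    if (pos > length(r)) break
    nname <- rawInt(r, pos, 1L, endian)
    if (nname == 0L) break
    id <- rawInt(r, pos + 1L, 1L, endian)
    name <- rawToChar(r[(pos + 2L):(pos + 1L + abs(nname))])
    offPos <- pos + 2L + abs(nname)
    offset <- rawInt(r, offPos, 2L, endian)
    if (id < 0) {                              # group record
      groups[[as.character(-id)]] <- name
    } else {                                   # parameter record
      type <- rawInt(r, offPos + 2L, 1L, endian)
      ndim <- rawInt(r, offPos + 3L, 1L, endian)
      dims <- if (ndim > 0)
        vapply(seq_len(ndim), function(k)
          rawInt(r, offPos + 3L + k, 1L, endian, signed = FALSE), integer(1))
      else integer(0)
      n <- prod(c(1L, dims))
      dpos <- offPos + 4L + ndim
      value <- switch(as.character(type),
        `-1` = rawToChar(r[dpos:(dpos + n - 1L)]),
        `1`  = vapply(seq_len(n) - 1L, function(k)
                 rawInt(r, dpos + k, 1L, endian), integer(1)),
        `2`  = readBin(r[dpos:(dpos + 2L * n - 1L)], "integer", n = n,
                       size = 2L, endian = endian),
        `4`  = rawFloat(r, dpos, n, endian),
        stop("unsupported C3D parameter type: ", type))
      params[[paste0(id, ":", toupper(name))]] <- list(value = value,
                                                       dims = dims)
    }
    if (offset == 0L) break
    pos <- offPos + offset
  }
  pointId <- names(groups)[toupper(unlist(groups)) == "POINT"]
  getp <- function(name) {
    if (!length(pointId)) return(NULL)
    params[[paste0(pointId[1], ":", name)]]
  }
  list(get = getp)
}

interpolateInvalid <- function(coords, invalid, maxGap = 10L) {
  # invalid: frames x markers logical; linear interpolation across interior
  # gaps of at most maxGap frames, otherwise the trial is rejected
  nf <- dim(coords)[1]
  for (m in which(colSums(invalid) > 0)) {
    bad <- invalid[, m]
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      if (starts[k] == 1L || ends[k] == nf)
        stop("invalid samples at trial boundary for marker index ", m)
      if (runs$lengths[k] > maxGap)
        stop("gap of ", runs$lengths[k], " invalid frames exceeds ", maxGap,
             " for marker index ", m)
    }
    ok <- which(!bad)
    for (d in 1:3)
      coords[bad, m, d] <- approx(ok, coords[ok, m, d], xout = which(bad))$y
  }
  coords
}

#' Read a C3D trial
#'
#' Reads point trajectories from a C3D file, reorders markers to the
#' expected order, converts metres to millimetres when the file declares
#' metres, and linearly interpolates samples flagged invalid (negative
#' residual) across interior gaps of at most `maxGap` frames.
#'
#' @param path C3D file
#' @param expectedMarkers a [MarkerSet-class]; every label must be present
#'   in the file's POINT labels
#' @param label class id 0..3 to attach (C3D carries no class label)
#' @param subjectId,handedness trial metadata
#' @param maxGap largest interior invalid-sample gap to interpolate
#' @return a [Trial-class] with coordinates in mm
#' @export
readC3D <- function(path, expectedMarkers, label = 0L, subjectId = "unknown",
                    handedness = "right", maxGap = 10L) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < C3D_BLOCK || r[2] != as.raw(0x50))
    stop("not a C3D file: ", path)
  paramBlock <- as.integer(r[1])
  paramStart <- (paramBlock - 1L) * C3D_BLOCK + 1L
  proc <- as.integer(r[paramStart + 3L])
  endian <- switch(as.character(proc),
    `84` = "little",
    `85` = stop("DEC floating point C3D files are not supported"),
    `86` = "big",
    stop("unknown C3D processor type: ", proc))

  np <- rawInt(r, 3L, 2L, endian)
  firstFrame <- rawInt(r, 7L, 2L, endian)
  lastFrame <- rawInt(r, 9L, 2L, endian)
  hdrScale <- rawFloat(r, 13L, 1L, endian)
  hdrDataStart <- rawInt(r, 17L, 2L, endian)
  hdrRate <- rawFloat(r, 21L, 1L, endian)

  pp <- parseC3DParams(r, paramStart, endian)
  used <- pp$get("USED"); if (!is.null(used)) np <- used$value[1]
  frames <- pp$get("FRAMES")
  nf <- if (!is.null(frames)) frames$value[1] else lastFrame - firstFrame + 1L
  if (nf < 1L) stop("C3D file has zero frames: ", path)
  ratep <- pp$get("RATE")
  rate <- if (!is.null(ratep)) ratep$value[1] else hdrRate
  scalep <- pp$get("SCALE")
  scale <- if (!is.null(scalep)) scalep$value[1] else hdrScale
  dsp <- pp$get("DATA_START")
  dataStart <- if (!is.null(dsp)) dsp$value[1] else hdrDataStart
  unitsP <- pp$get("UNITS")
  units <- if (!is.null(unitsP)) trimws(substr(unitsP$value, 1L,
             if (length(unitsP$dims)) unitsP$dims[1] else nchar(unitsP$value)))
           else "mm"
  labP <- pp$get("LABELS")
  if (is.null(labP)) stop("C3D file has no POINT:LABELS: ", path)
  w <- labP$dims[1]
  labels <- trimws(vapply(seq_len(np), function(k)
    substr(labP$value, (k - 1L) * w + 1L, k * w), character(1)))

  at <- (dataStart - 1L) * C3D_BLOCK + 1L
  if (scale < 0) {
    vals <- rawFloat(r, at, 4L * np * nf, endian)
  } else {
    iv <- readBin(r[at:(at + 2L * 4L * np * nf - 1L)], "integer",
                  n = 4L * np * nf, size = 2L, endian = endian)
    vals <- iv * scale
    # residual words keep their sign for validity flags
    vals[seq(4L, length(vals), by = 4L)] <- iv[seq(4L, length(iv), by = 4L)]
  }
  arr <- array(vals, dim = c(4L, np, nf))
  coords <- aperm(arr[1:3, , , drop = FALSE], c(3, 2, 1))
  invalid <- t(matrix(arr[4L, , ], nrow = np) < 0)

  want <- markerNames(expectedMarkers)
  idx <- match(want, labels)
  if (anyNA(idx))
    stop("C3D file is missing marker label(s): ",
         paste(want[is.na(idx)], collapse = ", "))
  coords <- coords[, idx, , drop = FALSE]
  invalid <- invalid[, idx, drop = FALSE]
  if (identical(tolower(units), "m")) coords <- coords * 1000
  if (any(invalid)) coords <- interpolateInvalid(coords, invalid, maxGap)
  Trial(coords, label, want, subjectId = subjectId, handedness = handedness,
        rate = rate, source = path)
}
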