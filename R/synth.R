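## Synthetic stroke generator.
##
## Emulates the statistical structure the classifier assumes: four stroke
## classes with distinct arm/racket kinematics, per-frame 3D marker
## coordinates in mm at 100 Hz, variable trial length, a rigid 7-marker
## racket moved by a single per-frame rigid transform, additive Gaussian
## marker jitter, and a mostly right-handed subject pool. Drive/volley
## pairs share their trajectory shape and differ mainly in amplitude, with
## per-trial amplitude jitter that overlaps the two classes, so the body
## alone does not separate a pair perfectly; the racket orientation
## profiles differ strongly per class. Where the class signal lives is
## controllable (`racketInformative`), which turns the with/without-racket
## ablation into a designed ground truth.

# Approximate standing pose, mm; x lateral (+ right), y anterior, z up.
basePose <- function() {
  pose <- rbind(
    LFHD = c(-70,   90, 1700), RFHD = c(70,   90, 1700),
    LBHD = c(-80,  -90, 1710), RBHD = c(80,  -90, 1710),
    C7   = c(0,    -80, 1530), T10  = c(0,  -110, 1260),
    CLAV = c(0,     60, 1480), STRN = c(0,    90, 1300),
    RBAK = c(90,  -120, 1420),
    LSHO = c(-190, -20, 1500), LUPA = c(-230, -30, 1370),
    LELB = c(-260, -40, 1250), LFRM = c(-270, -20, 1130),
    LWRA = c(-280,  10, 1020), LWRB = c(-300, -30, 1020),
    LFIN = c(-290,  30,  940),
    RSHO = c(190,  -20, 1500), RUPA = c(230,  -30, 1370),
    RELB = c(260,  -40, 1250), RFRM = c(270,  -20, 1130),
    RWRA = c(280,   10, 1020), RWRB = c(300,  -30, 1020),
    RFIN = c(290,   30,  940),
    LASI = c(-110,  80, 1000), RASI = c(110,   80, 1000),
    LPSI = c(-50, -140, 1040), RPSI = c(50,  -140, 1040),
    LTHI = c(-130,  20,  700), LKNE = c(-110,   0,  520),
    LTIB = c(-100,  20,  320), LANK = c(-90,    0,   90),
    LHEE = c(-85,  -60,   40), LTOE = c(-95,  140,   40),
    RTHI = c(130,   20,  700), RKNE = c(110,    0,  520),
    RTIB = c(100,   20,  320), RANK = c(90,     0,   90),
    RHEE = c(85,   -60,   40), RTOE = c(95,   140,   40))
  pose[match(markerNames(loadMarkerSet("plug_in_gait_39")), rownames(pose)), ]
}

# Racket marker template in racket-local coordinates, mm; handle bottom at
# the origin, long axis along z.
racketTemplate <- function() {
  rbind(
    RKT_TOP        = c(0,    0, 680),
    RKT_SIDE_L1    = c(-130, 0, 520),
    RKT_SIDE_L2    = c(-110, 0, 380),
    RKT_SIDE_R1    = c(130,  0, 520),
    RKT_SIDE_R2    = c(110,  0, 380),
    RKT_HEAD_BOT   = c(0,    0, 300),
    RKT_HANDLE_BOT = c(0,    0,   0))
}

# Dominant-hand displacement over normalized time s in [0,1], mm.
# Drive strokes sweep across the body; volleys are the same shape scaled
# down (a short punch) with a small extra lift. A backhand mirrors the
# forehand sweep direction.
handDisplacement <- function(classId, s) {
  sm <- (1 - cos(pi * s)) / 2         # smooth 0 -> 1 sweep
  b <- sin(pi * s)                    # bell
  drive <- cbind(250 - 700 * sm, 450 * b, 150 * b)
  out <- switch(as.character(classId),
    `0` = drive,
    `1` = cbind(-250 + 700 * sm, 450 * b, 150 * b),
    `2` = 0.85 * drive + cbind(0, 0, 30 * b),
    `3` = 0.85 * cbind(-250 + 700 * sm, 450 * b, 150 * b) + cbind(0, 0, 30 * b),
    stop("invalid class id: ", classId))
  out
}

# Racket orientation profile (degrees) over normalized time: volleys hold
# an open face with almost no roll, drives roll through a large angle.
racketAngles <- function(classId, s) {
  sm <- (1 - cos(pi * s)) / 2
  b <- sin(pi * s)
  switch(as.character(classId),
    `0` = cbind(yaw = -40 + 140 * sm, pitch = 20 * b, roll = -70 + 120 * sm),
    `1` = cbind(yaw = 40 - 140 * sm,  pitch = 20 * b, roll = 70 - 120 * sm),
    `2` = cbind(yaw = -10 + 40 * sm,  pitch = 55 + 10 * b, roll = rep(10, length(s))),
    `3` = cbind(yaw = 10 - 40 * sm,   pitch = 55 + 10 * b, roll = rep(-10, length(s))),
    stop("invalid class id: ", classId))
}

eulerRotation <- function(yawDeg, pitchDeg, rollDeg) {
  a <- yawDeg * pi / 180; b <- pitchDeg * pi / 180; c <- rollDeg * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3)
  Rz %*% Ry %*% Rx
}

#' Synthetic corpus configuration
#'
#' Defaults mirror the real acquisition: class counts 197/212/180/180
#' (forehand/backhand/volley forehand/volley backhand, i.e. backhand 212
#' and forehand 197), 100 Hz, roughly 1 in 10 players left-handed, 2 mm
#' Gaussian marker jitter (typical optical mocap noise), trial durations
#' uniform on 60-180 frames so padding is exercised.
#'
#' @param counts per-class trial counts, indexed by class id 0..3
#' @param noiseSd additive Gaussian marker noise, mm
#' @param durationRange inclusive frame-count range trials are drawn from
#' @param nSubjects size of the synthetic subject pool
#' @param nLeftHanded how many of the subjects are left-handed
#' @param rate capture rate, Hz
#' @param amplitudeJitterSd per-trial multiplicative amplitude jitter (sd
#'   of a unit-mean Gaussian, clamped to `[0.6, 1.4]`)
#' @param racketInformative where the class signal lives: `"both"` (racket
#'   rigidly follows the class-specific swing), `"body_only"` (the racket
#'   transform is drawn independently of the class, so racket channels
#'   carry no class information), or `"racket_only"` (the body swing is
#'   drawn independently of the class)
#' @param seed RNG seed for [generateDataset()]
#' @return a named list of settings
#' @export
synthConfig <- function(counts = c(197L, 212L, 180L, 180L),
                        noiseSd = 2, durationRange = c(60L, 180L),
                        nSubjects = 10L, nLeftHanded = 1L, rate = 100,
                        amplitudeJitterSd = 0.12,
                        racketInformative = c("both", "body_only",
                                              "racket_only"),
                        seed = 1L) {
  racketInformative <- match.arg(racketInformative)
  stopifnot(length(counts) == 4, all(counts >= 0), noiseSd >= 0,
            durationRange[1] >= 2, durationRange[2] >= durationRange[1],
            nLeftHanded <= nSubjects)
  list(counts = as.integer(counts), noiseSd = noiseSd,
       durationRange = as.integer(durationRange), nSubjects = nSubjects,
       nLeftHanded = nLeftHanded, rate = rate,
       amplitudeJitterSd = amplitudeJitterSd,
       racketInformative = racketInformative, seed = as.integer(seed))
}

# Noise-free deterministic class template at unit amplitude: the mean
# trajectory of a right-handed trial of the given duration.
#' Deterministic class template trajectory
#'
#' The noise-free, unit-amplitude, right-handed mean trajectory of a class
#' over a fixed duration: useful for checking that the four shipped class
#' templates are pairwise distinguishable.
#'
#' @param classId class id 0..3
#' @param nFrames duration in frames
#' @return array `nFrames x 46 x 3`, mm
#' @export
strokeTemplate <- function(classId, nFrames = 100L) {
  buildStroke(classId, nFrames, jitter = 1, racketClass = classId,
              racketJitter = 1)
}

armWeights <- function(labels, dominantPrefix, otherWeight) {
  w <- rep(0, length(labels))
  chain <- c(SHO = 0.15, UPA = 0.3, ELB = 0.5, FRM = 0.7, WRA = 0.9,
             WRB = 0.9, FIN = 1.0)
  other <- if (dominantPrefix == "R") "L" else "R"
  for (part in names(chain)) {
    w[labels == paste0(dominantPrefix, part)] <- chain[[part]]
    w[labels == paste0(other, part)] <- otherWeight * chain[[part]]
  }
  w
}

# Deterministic core: body + racket coordinates for given class ids and
# amplitude multipliers; right-handed convention (dominant = right arm).
buildStroke <- function(bodyClass, nT, jitter, racketClass, racketJitter) {
  s <- seq(0, 1, length.out = nT)
  pose <- basePose()
  labels <- rownames(pose)
  disp <- jitter * handDisplacement(bodyClass, s)          # T x 3
  # two-handed backhand: the non-dominant arm follows strongly
  otherW <- if (bodyClass %in% c(1L, 3L)) 0.3 else 0.05
  w <- armWeights(labels, "R", otherW)
  body <- array(0, dim = c(nT, 39, 3))
  for (d in 1:3)
    body[, , d] <- matrix(pose[, d], nT, 39, byrow = TRUE) +
      outer(disp[, d], w)
  rkt <- racketTemplate()
  ang <- racketAngles(racketClass, s)
  rtrans <- matrix(pose["RWRA", ], nT, 3, byrow = TRUE) +
    racketJitter * handDisplacement(racketClass, s) +
    matrix(c(30, 40, -20), nT, 3, byrow = TRUE)
  racket <- array(0, dim = c(nT, 7, 3))
  for (t in seq_len(nT)) {
    R <- eulerRotation(ang[t, 1], ang[t, 2], ang[t, 3])
    racket[t, , ] <- t(R %*% t(rkt)) + matrix(rtrans[t, ], 7, 3, byrow = TRUE)
  }
  out <- array(0, dim = c(nT, 46, 3))
  out[, 1:39, ] <- body
  out[, 40:46, ] <- racket
  out
}

synthMarkerNames <- function() {
  c(markerNames(loadMarkerSet("plug_in_gait_39")),
    markerNames(loadMarkerSet("racket_7")))
}

#' Generate one synthetic stroke trial
#'
#' Draws a duration, an amplitude jitter and marker noise from the current
#' RNG stream and builds a 46-marker trial (39 body + 7 racket markers).
#' The racket is a fixed 7-point rigid template moved by a single rigid
#' transform per frame, so all 21 racket inter-marker distances are
#' constant before noise. Left-handed subjects are generated by mirroring
#' the right-handed construction.
#'
#' @param classId class id 0..3
#' @param cfg a [synthConfig()]
#' @param subjectId subject label; drawn from the pool if `NULL`
#' @param handedness `"left"`, `"right"`, or `NULL` to infer from the
#'   subject pool (the last `nLeftHanded` subjects are left-handed)
#' @return a 46-marker [Trial-class]
#' @export
generateTrial <- function(classId, cfg = synthConfig(), subjectId = NULL,
                          handedness = NULL) {
  classId <- as.integer(classId)
  if (!classId %in% 0:3) stop("invalid class id: ", classId)
  if (is.null(subjectId)) {
    sidx <- sample.int(cfg$nSubjects, 1)
    subjectId <- sprintf("S%02d", sidx)
  } else {
    sidx <- suppressWarnings(as.integer(sub("^S", "", subjectId)))
    if (is.na(sidx)) sidx <- 1L
  }
  if (is.null(handedness))
    handedness <- if (sidx > cfg$nSubjects - cfg$nLeftHanded) "left" else "right"

  nT <- if (cfg$durationRange[1] == cfg$durationRange[2]) cfg$durationRange[1]
        else sample(seq(cfg$durationRange[1], cfg$durationRange[2]), 1)
  clamp <- function(x) pmin(1.4, pmax(0.6, x))
  jitter <- clamp(rnorm(1, 1, cfg$amplitudeJitterSd))
  bodyClass <- classId
  racketClass <- classId
  racketJitter <- jitter
  if (cfg$racketInformative == "body_only") {
    racketClass <- sample(0:3, 1)
    racketJitter <- clamp(rnorm(1, 1, cfg$amplitudeJitterSd))
  } else if (cfg$racketInformative == "racket_only") {
    bodyClass <- sample(0:3, 1)
    racketJitter <- clamp(rnorm(1, 1, cfg$amplitudeJitterSd))
  }
  coords <- buildStroke(bodyClass, nT, jitter, racketClass, racketJitter)
  if (cfg$noiseSd > 0)
    coords <- coords + array(rnorm(length(coords), 0, cfg$noiseSd),
                             dim = dim(coords))
  tr <- Trial(coords, classId, synthMarkerNames(), subjectId = subjectId,
              handedness = "right", rate = cfg$rate, source = "synthetic")
  if (handedness == "left") tr <- mirrorTrial(tr)
  tr
}

#' Generate a full synthetic corpus
#'
#' Per-class counts follow the configuration (defaults mirror the real
#' corpus: backhand 212, forehand 197, both volleys 180). Fully
#' reproducible from `(cfg, cfg$seed)`; the caller's RNG state is left
#' untouched.
#'
#' @param cfg a [synthConfig()]
#' @return a 46-marker [TrialSet-class]
#' @export
generateDataset <- function(cfg = synthConfig()) {
  withSeed(cfg$seed, {
    trialList <- list()
    subj <- 0L
    for (cls in 0:3) {
      for (k in seq_len(cfg$counts[cls + 1L])) {
        subj <- subj %% cfg$nSubjects + 1L
        trialList[[length(trialList) + 1L]] <-
          generateTrial(cls, cfg, subjectId = sprintf("S%02d", subj))
      }
    }
    TrialSet(trialList, synthMarkerNames())
  })
}
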