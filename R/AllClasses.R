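#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core image containers
## ---------------------------------------------------------------------------

#' FrameImage: one decoded video frame
#'
#' Holds an 8-bit RGB frame as an integer \code{height x width x 3} array with
#' channel values in \code{[0, 255]}, together with its position in the clip.
#'
#' @slot pixels integer array \code{h x w x 3}, values in \code{[0, 255]}.
#' @slot frameIndex non-negative integer index within the clip (0-based).
#' @slot timestamp seconds from clip start.
#'
#' @exportClass FrameImage
setClass("FrameImage",
  representation(pixels = "array", frameIndex = "integer",
                 timestamp = "numeric"),
  prototype(frameIndex = 0L, timestamp = 0))

setValidity("FrameImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an h x w x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("frame must be at least 16 x 16 pixels")
  rng <- range(object@pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    return("channel values must lie in [0, 255]")
  if (object@frameIndex < 0L) return("frameIndex must be non-negative")
  if (object@timestamp < 0) return("timestamp must be non-negative")
  TRUE
})

#' FieldMask: the circular optical field of an arthroscope frame
#'
#' Boolean grid marking pixels inside the optical field (the black vignette
#' around the circular image is excluded).
#'
#' @slot inside logical \code{h x w} matrix, \code{TRUE} inside the field.
#' @slot coverage fraction of \code{TRUE} pixels.
#'
#' @exportClass FieldMask
setClass("FieldMask",
  representation(inside = "matrix", coverage = "numeric"))

setValidity("FieldMask", function(object) {
  if (!is.logical(object@inside)) return("inside must be a logical matrix")
  if (object@coverage <= 0) return("mask coverage must be positive")
  if (abs(object@coverage - mean(object@inside)) > 1e-8)
    return("coverage inconsistent with mask")
  TRUE
})

#' ClipFrames: frames of a clip grouped into whole seconds
#'
#' @slot seconds list of per-second frame groups; every group holds exactly
#'   \code{fps} \linkS4class{FrameImage} objects.
#' @slot fps frames per second.
#' @slot durationS number of complete seconds.
#'
#' @exportClass ClipFrames
setClass("ClipFrames",
  representation(seconds = "list", fps = "integer", durationS = "integer"))

setValidity("ClipFrames", function(object) {
  if (object@fps < 3L) return("fps must be at least 3")
  if (length(object@seconds) != object@durationS)
    return("durationS inconsistent with seconds")
  if (object@durationS < 1L) return("clip must contain at least one second")
  n <- vapply(object@seconds, length, integer(1))
  if (any(n != object@fps))
    return("every complete second must hold exactly fps frames")
  TRUE
})

#' ColorFeatures: per-pixel colour planes and frame-level means
#'
#' HSV and CIELAB planes of one frame plus the mean saturation and mean a*
#' over the masked (optical-field) pixels, which drive the frame-adaptive
#' threshold cut-offs.
#'
#' @slot hue degrees in \code{[0, 360)}.
#' @slot sat saturation in \code{[0, 1]}.
#' @slot val value in \code{[0, 1]}.
#' @slot lstar CIELAB L* in \code{[0, 100]}.
#' @slot astar CIELAB a* (red/green axis).
#' @slot bstar CIELAB b* (yellow/blue axis).
#' @slot meanS mean saturation over masked pixels.
#' @slot meanA mean a* over masked pixels.
#' @slot nMasked number of masked pixels.
#'
#' @exportClass ColorFeatures
setClass("ColorFeatures",
  representation(hue = "matrix", sat = "matrix", val = "matrix",
                 lstar = "matrix", astar = "matrix", bstar = "matrix",
                 meanS = "numeric", meanA = "numeric", nMasked = "integer"))

setValidity("ColorFeatures", function(object) {
  if (object@nMasked <= 0L) return("nMasked must be positive")
  if (object@meanS < 0 || object@meanS > 1) return("meanS must lie in [0, 1]")
  d <- dim(object@hue)
  for (s in c("sat", "val", "lstar", "astar", "bstar"))
    if (!identical(dim(slot(object, s)), d))
      return("all colour planes must share the frame dimensions")
  TRUE
})

## ---------------------------------------------------------------------------
## Threshold specifications
## ---------------------------------------------------------------------------

#' ThresholdSpec: the parametric blood-pixel predicate
#'
#' A masked pixel is classified as blood when all of the following hold: its
#' hue lies in the wrap-around red band (\code{hue >= hueLo} or
#' \code{hue <= hueHi} when \code{hueLo > hueHi}); its saturation is at least
#' \code{clamp(sMin + gammaS * (meanS - sRef), 0, 1)}; its value is at least
#' \code{vMin}; its a* is at least \code{aMin + gammaA * (meanA - aRef)}; and
#' its L* is at most \code{lMax}. The blood-pixel ratio is mapped linearly to
#' a score in \code{[1, 10]}, saturating at ratio \code{rMax}.
#'
#' The coupling coefficients \code{gammaS}/\code{gammaA} shift the per-pixel
#' cut-offs with the frame-level mean saturation and mean a*, so the predicate
#' adapts to how strongly the irrigation fluid as a whole is tinted.
#'
#' @slot hueLo,hueHi red hue band bounds in degrees (wrap-around).
#' @slot sMin base saturation cut in \code{[0, 1]}.
#' @slot vMin value cut in \code{[0, 1]}.
#' @slot aMin base a* cut.
#' @slot lMax L* ceiling; 100 disables the glare gate.
#' @slot gammaS,gammaA coupling of the cuts to \code{meanS}/\code{meanA}.
#' @slot sRef,aRef reference mean levels for the couplings.
#' @slot rMax blood-pixel ratio at which the score saturates at 10.
#'
#' @seealso [classifyBloodPixels()], [scoreFrame()], [fitThresholds()]
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(hueLo = "numeric", hueHi = "numeric", sMin = "numeric",
                 vMin = "numeric", aMin = "numeric", lMax = "numeric",
                 gammaS = "numeric", gammaA = "numeric", sRef = "numeric",
                 aRef = "numeric", rMax = "numeric"))

setValidity("ThresholdSpec", function(object) {
  if (object@sMin < 0 || object@sMin > 1) return("sMin must lie in [0, 1]")
  if (object@vMin < 0 || object@vMin > 1) return("vMin must lie in [0, 1]")
  if (object@rMax <= 0 || object@rMax > 1) return("rMax must lie in (0, 1]")
  if (object@hueLo < 0 || object@hueLo >= 360 ||
      object@hueHi < 0 || object@hueHi >= 360)
    return("hue bounds must lie in [0, 360)")
  if (object@hueLo == object@hueHi)
    return("hue band must be non-empty")
  TRUE
})

#' RgbBaselineSpec: RGB-only ablation predicate
#'
#' Baseline variant of the blood-pixel predicate that uses only red-channel
#' dominance: a pixel is flagged when \code{R >= rMin} and
#' \code{R - max(G, B) >= dMin} (8-bit units). Kept for ablation comparisons
#' against the full HSV + CIELAB model.
#'
#' @slot rMin minimum red channel value in \code{[0, 255]}.
#' @slot dMin minimum red dominance \code{R - max(G, B)}.
#' @slot rMax ratio at which the score saturates at 10.
#'
#' @exportClass RgbBaselineSpec
setClass("RgbBaselineSpec",
  representation(rMin = "numeric", dMin = "numeric", rMax = "numeric"))

setValidity("RgbBaselineSpec", function(object) {
  if (object@rMin < 0 || object@rMin > 255) return("rMin must lie in [0, 255]")
  if (object@rMax <= 0 || object@rMax > 1) return("rMax must lie in (0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Score containers
## ---------------------------------------------------------------------------

#' FrameScore: blood-pixel counts and score of one frame
#'
#' @slot bloodPixels number of pixels classified as blood.
#' @slot maskedPixels number of optical-field pixels.
#' @slot ratio blood / masked.
#' @slot score bleeding score in \code{[1, 10]}.
#' @slot frameIndex index of the scored frame.
#'
#' @exportClass FrameScore
setClass("FrameScore",
  representation(bloodPixels = "integer", maskedPixels = "integer",
                 ratio = "numeric", score = "numeric", frameIndex = "integer"))

setValidity("FrameScore", function(object) {
  if (object@ratio < 0 || object@ratio > 1) return("ratio must lie in [0, 1]")
  if (object@score < 1 || object@score > 10)
    return("score must lie in [1, 10]")
  TRUE
})

#' SecondScore: score of one second from three sampled frames
#'
#' @slot sampledFrames the 3 sampled frame indices (1-based within second).
#' @slot frameScores their 3 frame scores.
#' @slot meanScore their arithmetic mean.
#' @slot resampleRounds sampling rounds used by the clip that accepted it.
#'
#' @exportClass SecondScore
setClass("SecondScore",
  representation(sampledFrames = "integer", frameScores = "numeric",
                 meanScore = "numeric", resampleRounds = "integer"))

setValidity("SecondScore", function(object) {
  if (length(object@sampledFrames) != 3L)
    return("exactly 3 frames are sampled per second")
  if (length(object@frameScores) != 3L)
    return("exactly 3 frame scores per second")
  if (abs(object@meanScore - mean(object@frameScores)) > 1e-9)
    return("meanScore must equal the mean of the frame scores")
  TRUE
})

#' ClipScore: accepted score of a (canonically 3 s) clip
#'
#' @slot secondScores list of \linkS4class{SecondScore}, one per second.
#' @slot clipScore mean of the per-second scores.
#' @slot prevClipScore the score(t-1) used by the temporal jump rule.
#' @slot rounds total sampling rounds used (1 = accepted immediately).
#' @slot flagged TRUE when all resampling rounds exceeded the jump bound and
#'   the minimum-jump round was returned.
#' @slot jump absolute difference to prevClipScore for the accepted round.
#'
#' @exportClass ClipScore
setClass("ClipScore",
  representation(secondScores = "list", clipScore = "numeric",
                 prevClipScore = "numeric", rounds = "integer",
                 flagged = "logical", jump = "numeric"))

setValidity("ClipScore", function(object) {
  if (object@clipScore < 1 || object@clipScore > 10)
    return("clipScore must lie in [1, 10]")
  if (object@rounds < 1L) return("rounds must be at least 1")
  TRUE
})

#' ProcedureReport: whole-recording bleeding timeline and summary
#'
#' @slot timeline accepted per-second scores over the full recording.
#' @slot phases data.frame with columns name, start, end (half-open second
#'   ranges), meanScore, n; zero rows when no phases were supplied.
#' @slot totalBleedingScore sum of per-second scores divided by the number of
#'   scored seconds.
#' @slot clipScores list of \linkS4class{ClipScore} for the consecutive clips.
#' @slot seed RNG seed used (NA when scored under the caller's RNG state).
#' @slot temporalMode "clip" (clip vs previous clip) or "second" (each second
#'   vs the mean of the previous three accepted seconds).
#'
#' @exportClass ProcedureReport
setClass("ProcedureReport",
  representation(timeline = "numeric", phases = "data.frame",
                 totalBleedingScore = "numeric", clipScores = "list",
                 seed = "numeric", temporalMode = "character"))

setValidity("ProcedureReport", function(object) {
  if (length(object@timeline) < 1L) return("timeline must be non-empty")
  if (abs(object@totalBleedingScore - mean(object@timeline)) > 1e-9)
    return("totalBleedingScore must equal the mean per-second score")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' SyntheticSpec: parameters of the synthetic arthroscopy frame generator
#'
#' Describes one synthetic clip: a pale tissue background with low-frequency
#' multiplicative texture and radial vignetting inside a circular optical
#' field (black outside), over which blood is composited as an alpha-blended
#' translucent red overlay. Optional extras emulate confounders: a transient
#' bright clot artifact on selected frames and a pale-pink inflammation patch
#' whose saturation stays below the plausible blood range.
#'
#' @slot width,height frame size in pixels.
#' @slot baseColor pale tissue RGB in \code{[0, 255]}.
#' @slot textureAmp amplitude of the multiplicative texture field.
#' @slot vignetteStrength radial darkening toward the field edge in
#'   \code{[0, 1)}.
#' @slot fieldRadiusFrac disk radius as a fraction of the half-diagonal.
#' @slot bloodTransparency overlay transparency t in \code{[0, 1]} (0 = opaque
#'   red, 1 = invisible).
#' @slot bloodPattern "uniform", "plume" (smoothed random blobs, emulating dye
#'   dissolving into the irrigation fluid) or "none".
#' @slot bloodColor dark-red overlay RGB in \code{[0, 255]}.
#' @slot artifact empty list, or list(frames, centerFrac, radiusFrac, alpha)
#'   describing a bright clot blob on the given 0-based frame indices.
#' @slot inflammation empty list, or list(centerFrac, radiusFrac, strength)
#'   describing a pale-pink patch composited under the blood overlay.
#' @slot seed RNG seed; all generator randomness derives from it.
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(width = "integer", height = "integer", baseColor = "numeric",
                 textureAmp = "numeric", vignetteStrength = "numeric",
                 fieldRadiusFrac = "numeric", bloodTransparency = "numeric",
                 bloodPattern = "character", bloodColor = "numeric",
                 artifact = "list", inflammation = "list", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@bloodTransparency < 0 || object@bloodTransparency > 1)
    return("bloodTransparency must lie in [0, 1]")
  if (object@fieldRadiusFrac <= 0 || object@fieldRadiusFrac > 1)
    return("fieldRadiusFrac must lie in (0, 1]")
  if (!object@bloodPattern %in% c("uniform", "plume", "none"))
    return("bloodPattern must be uniform, plume or none")
  if (length(object@baseColor) != 3L || length(object@bloodColor) != 3L)
    return("baseColor and bloodColor must be RGB triplets")
  TRUE
})

#' GroundTruth: generator-declared truth for a synthetic frame or second
#'
#' @slot trueScore true bleeding score in \code{[1, 10]}.
#' @slot maskTruth the generator's exact field disk.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(trueScore = "numeric", maskTruth = "matrix"))

#' ValidationSet: a labelled collection of synthetic clips
#'
#' Generated by [generateValidationSet()]; clips are stored as generator
#' specifications and realised on demand with [realizeClip()], so arbitrarily
#' large sets stay cheap to hold.
#'
#' @slot manifest data.frame with one row per clip (clip_id, level,
#'   true_score, transparency, seed and nuisance parameters).
#' @slot specs list of \linkS4class{SyntheticSpec}, parallel to the manifest.
#' @slot fps,seconds clip geometry shared by all clips.
#'
#' @exportClass ValidationSet
setClass("ValidationSet",
  representation(manifest = "data.frame", specs = "list", fps = "integer",
                 seconds = "integer"))

setValidity("ValidationSet", function(object) {
  if (nrow(object@manifest) != length(object@specs))
    return("manifest and specs must be parallel")
  TRUE
})

## ---------------------------------------------------------------------------
## Calibration and agreement statistics
## ---------------------------------------------------------------------------

#' CalibrationResult: fitted threshold specification and its errors
#'
#' @slot spec fitted \linkS4class{ThresholdSpec} or
#'   \linkS4class{RgbBaselineSpec}.
#' @slot trainMae mean absolute error on the training clips.
#' @slot holdoutMae,holdoutMaeSd mean and SD of the absolute error on clips
#'   never seen during fitting.
#' @slot trace data.frame of evaluated parameter points with columns for each
#'   parameter plus loss and bestLoss (non-increasing).
#' @slot holdoutScores data.frame (clip, label, system) for the holdout clips.
#'
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(spec = "ANY", trainMae = "numeric", holdoutMae = "numeric",
                 holdoutMaeSd = "numeric", trace = "data.frame",
                 holdoutScores = "data.frame"))

#' RatingMatrix: complete subjects x raters score grid
#'
#' @slot scores numeric \code{n x k} matrix, no missing cells.
#' @slot subjectIds,raterIds row and column identifiers.
#'
#' @exportClass RatingMatrix
setClass("RatingMatrix",
  representation(scores = "matrix", subjectIds = "character",
                 raterIds = "character"))

setValidity("RatingMatrix", function(object) {
  if (anyNA(object@scores))
    return("rating matrix must be complete (no missing cells)")
  if (ncol(object@scores) < 2L) return("at least 2 raters required")
  if (length(object@subjectIds) != nrow(object@scores) ||
      length(object@raterIds) != ncol(object@scores))
    return("identifier lengths inconsistent with the score matrix")
  TRUE
})

#' ICCResult: an intraclass correlation estimate with confidence bounds
#'
#' @slot estimate ICC estimate (at most 1).
#' @slot ciLow,ciHigh confidence bounds at level \code{conf}.
#' @slot model "twoWayRandom" or "twoWayMixed".
#' @slot unit "single" (one rater) or "meanOfK" (the averaged panel).
#' @slot k number of raters; @slot n number of subjects.
#' @slot conf confidence level.
#' @slot msr,msc,mse the underlying ANOVA mean squares.
#'
#' @exportClass ICCResult
setClass("ICCResult",
  representation(estimate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 model = "character", unit = "character", k = "integer",
                 n = "integer", conf = "numeric", msr = "numeric",
                 msc = "numeric", mse = "numeric"))

setValidity("ICCResult", function(object) {
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@estimate + 1e-12 ||
       object@ciHigh < object@estimate - 1e-12))
    return("confidence bounds must bracket the estimate")
  TRUE
})
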