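## Internal helpers shared across modules.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Derive a bounded child seed from a user seed; kept below 2^31 - 1.
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(i)) %% 2147483587 + 1)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Accessors -----------------------------------------------------------------

#' Accessors for ArthroScore objects
#'
#' Small accessor functions for the package's S4 containers: scores, ratios,
#' sampling provenance, timelines, coverage and calibration results.
#'
#' @param x an ArthroScore S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("bleedingScore", "FrameScore", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("bleedingScore", "SecondScore", function(x) x@meanScore)
#' @rdname accessors
#' @export
setMethod("bleedingScore", "ClipScore", function(x) x@clipScore)
#' @rdname accessors
#' @export
setMethod("bleedingScore", "GroundTruth", function(x) x@trueScore)

#' @rdname accessors
#' @export
setMethod("bloodRatio", "FrameScore", function(x) x@ratio)

#' @rdname accessors
#' @export
setMethod("sampledFrames", "SecondScore", function(x) x@sampledFrames)

#' @rdname accessors
#' @export
setMethod("resampleRounds", "SecondScore", function(x) x@resampleRounds)
#' @rdname accessors
#' @export
setMethod("resampleRounds", "ClipScore", function(x) x@rounds)

#' @rdname accessors
#' @export
setMethod("isFlagged", "ClipScore", function(x) x@flagged)

#' @rdname accessors
#' @export
setMethod("secondScores", "ClipScore", function(x) x@secondScores)

#' @rdname accessors
#' @export
setMethod("scoreTimeline", "ProcedureReport", function(x) x@timeline)

#' @rdname accessors
#' @export
setMethod("totalBleedingScore", "ProcedureReport", function(x)
  x@totalBleedingScore)

#' @rdname accessors
#' @export
setMethod("phaseScores", "ProcedureReport", function(x) x@phases)

#' @rdname accessors
#' @export
setMethod("fieldCoverage", "FieldMask", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("frameCount", "ClipFrames", function(x)
  sum(vapply(x@seconds, length, integer(1))))

#' @rdname accessors
#' @export
setMethod("clipDuration", "ClipFrames", function(x) x@durationS)

#' @rdname accessors
#' @export
setMethod("iccEstimate", "ICCResult", function(x) x@estimate)

#' @rdname accessors
#' @export
setMethod("iccConfint", "ICCResult", function(x) c(x@ciLow, x@ciHigh))

#' @rdname accessors
#' @export
setMethod("fittedSpec", "CalibrationResult", function(x) x@spec)

#' @rdname accessors
#' @export
setMethod("holdoutMae", "CalibrationResult", function(x) x@holdoutMae)

#' @rdname accessors
#' @export
setMethod("searchTrace", "CalibrationResult", function(x) x@trace)

## show methods --------------------------------------------------------------

setMethod("show", "FrameImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FrameImage %d x %d, index %d, t = %.3f s\n",
              d[1], d[2], object@frameIndex, object@timestamp))
})

setMethod("show", "FieldMask", function(object) {
  cat(sprintf("FieldMask %d x %d, coverage %.3f\n",
              nrow(object@inside), ncol(object@inside), object@coverage))
})

setMethod("show", "ClipFrames", function(object) {
  cat(sprintf("ClipFrames: %d s at %d fps (%d frames)\n",
              object@durationS, object@fps, frameCount(object)))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat("ThresholdSpec (HSV + CIELAB blood-pixel predicate)\n")
  cat(sprintf("  hue band: [%.1f, %.1f] deg (wrap-around)\n",
              object@hueLo, object@hueHi))
  cat(sprintf("  sMin %.3f  vMin %.3f  aMin %.2f  lMax %.1f\n",
              object@sMin, object@vMin, object@aMin, object@lMax))
  cat(sprintf("  gammaS %.3f (sRef %.3f)  gammaA %.3f (aRef %.2f)\n",
              object@gammaS, object@sRef, object@gammaA, object@aRef))
  cat(sprintf("  rMax %.3f (ratio at score 10)\n", object@rMax))
})

setMethod("show", "RgbBaselineSpec", function(object) {
  cat(sprintf("RgbBaselineSpec: R >= %.1f, R - max(G,B) >= %.1f, rMax %.3f\n",
              object@rMin, object@dMin, object@rMax))
})

setMethod("show", "FrameScore", function(object) {
  cat(sprintf("FrameScore: %d / %d blood pixels (ratio %.4f), score %.2f\n",
              object@bloodPixels, object@maskedPixels, object@ratio,
              object@score))
})

setMethod("show", "SecondScore", function(object) {
  cat(sprintf("SecondScore %.2f from frames [%s] (scores %s)\n",
              object@meanScore,
              paste(object@sampledFrames, collapse = ", "),
              paste(sprintf("%.2f", object@frameScores), collapse = ", ")))
})

setMethod("show", "ClipScore", function(object) {
  cat(sprintf(
    "ClipScore %.2f over %d s (prev %.2f, rounds %d%s)\n",
    object@clipScore, length(object@secondScores), object@prevClipScore,
    object@rounds, if (object@flagged) ", FLAGGED" else ""))
})

setMethod("show", "ProcedureReport", function(object) {
  cat(sprintf("ProcedureReport: %d s, total bleeding score %.2f\n",
              length(object@timeline), object@totalBleedingScore))
  if (nrow(object@phases))
    for (i in seq_len(nrow(object@phases)))
      cat(sprintf("  phase %-24s [%d, %d): %.2f\n",
                  object@phases$name[i], object@phases$start[i],
                  object@phases$end[i], object@phases$meanScore[i]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec %dx%d, t = %.2f (%s), field %.2f, seed %d\n",
    object@width, object@height, object@bloodTransparency,
    object@bloodPattern, object@fieldRadiusFrac, object@seed))
})

setMethod("show", "ValidationSet", function(object) {
  cat(sprintf("ValidationSet: %d clips (%d s at %d fps), levels %s\n",
              nrow(object@manifest), object@seconds, object@fps,
              paste(sort(unique(object@manifest$level)), collapse = ",")))
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult\n")
  show(object@spec)
  cat(sprintf("  train MAE %.3f, holdout MAE %.3f +/- %.3f (n = %d)\n",
              object@trainMae, object@holdoutMae, object@holdoutMaeSd,
              nrow(object@holdoutScores)))
})

setMethod("show", "RatingMatrix", function(object) {
  cat(sprintf("RatingMatrix: %d subjects x %d raters\n",
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(%s, %s): %.4f [%0.4f, %0.4f] (%d subjects, k = %d)\n",
              if (object@model == "twoWayRandom") "A" else "A*",
              if (object@unit == "single") "1" else "k",
              object@estimate, object@ciLow, object@ciHigh, object@n,
              object@k))
})
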