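#' Score a single frame
#'
#' Classifies blood pixels inside the optical field with the supplied
#' specification and maps the blood-pixel ratio to a bleeding score in
#' \code{[1, 10]} via \code{1 + 9 * min(ratio / rMax, 1)}. Dispatches on the
#' specification: a \linkS4class{ThresholdSpec} applies the full HSV + CIELAB
#' predicate, an \linkS4class{RgbBaselineSpec} the red-dominance ablation
#' baseline.
#'
#' @param frame a \linkS4class{FrameImage}.
#' @param mask a \linkS4class{FieldMask} for the same frame.
#' @param spec a \linkS4class{ThresholdSpec} or \linkS4class{RgbBaselineSpec}.
#' @return a \linkS4class{FrameScore}.
#' @examples
#' fr <- generateFrame(syntheticSpec(bloodTransparency = 0.3))
#' m <- detectFieldMask(fr$frame)
#' scoreFrame(fr$frame, m, defaultThresholdSpec())
#' @export
setGeneric("scoreFrame", function(frame, mask, spec)
  standardGeneric("scoreFrame"))

#' @rdname accessors
#' @export
setGeneric("bleedingScore", function(x) standardGeneric("bleedingScore"))

#' @rdname accessors
#' @export
setGeneric("bloodRatio", function(x) standardGeneric("bloodRatio"))

#' @rdname accessors
#' @export
setGeneric("sampledFrames", function(x) standardGeneric("sampledFrames"))

#' @rdname accessors
#' @export
setGeneric("resampleRounds", function(x) standardGeneric("resampleRounds"))

#' @rdname accessors
#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))

#' @rdname accessors
#' @export
setGeneric("secondScores", function(x) standardGeneric("secondScores"))

#' @rdname accessors
#' @export
setGeneric("scoreTimeline", function(x) standardGeneric("scoreTimeline"))

#' @rdname accessors
#' @export
setGeneric("totalBleedingScore", function(x) standardGeneric("totalBleedingScore"))

#' @rdname accessors
#' @export
setGeneric("phaseScores", function(x) standardGeneric("phaseScores"))

#' @rdname accessors
#' @export
setGeneric("fieldCoverage", function(x) standardGeneric("fieldCoverage"))

#' @rdname accessors
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' @rdname accessors
#' @export
setGeneric("clipDuration", function(x) standardGeneric("clipDuration"))

#' @rdname accessors
#' @export
setGeneric("iccEstimate", function(x) standardGeneric("iccEstimate"))

#' @rdname accessors
#' @export
setGeneric("iccConfint", function(x) standardGeneric("iccConfint"))

#' @rdname accessors
#' @export
setGeneric("fittedSpec", function(x) standardGeneric("fittedSpec"))

#' @rdname accessors
#' @export
setGeneric("holdoutMae", function(x) standardGeneric("holdoutMae"))

#' @rdname accessors
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))
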