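## Core scoring pipeline: blood-pixel classification, ratio -> [1, 10]
## mapping, three-random-frames-per-second aggregation, the abrupt-jump
## resampling rule, and clip / procedure summaries.

#' Classify blood pixels of a frame
#'
#' Applies the parametric multi-space predicate of a
#' \linkS4class{ThresholdSpec}: hue inside the wrap-around red band,
#' saturation above the frame-adaptive cut
#' \code{clamp(sMin + gammaS * (meanS - sRef), 0, 1)}, value above
#' \code{vMin}, a* above \code{aMin + gammaA * (meanA - aRef)}, and L* at
#' most \code{lMax}. Pixels outside the optical-field mask are never flagged.
#'
#' @param features a \linkS4class{ColorFeatures}.
#' @param mask the \linkS4class{FieldMask} the features were computed with.
#' @param spec a \linkS4class{ThresholdSpec}.
#' @return list with \code{blood} (logical matrix), \code{bloodPixels} and
#'   \code{maskedPixels} counts.
#' @export
classifyBloodPixels <- function(features, mask, spec) {
  if (features@nMasked != sum(mask@inside))
    .stopf("features and mask are inconsistent")
  sCut <- .clamp(spec@sMin + spec@gammaS * (features@meanS - spec@sRef), 0, 1)
  aCut <- spec@aMin + spec@gammaA * (features@meanA - spec@aRef)
  hueIn <- if (spec@hueLo <= spec@hueHi)
    features@hue >= spec@hueLo & features@hue <= spec@hueHi
  else
    features@hue >= spec@hueLo | features@hue <= spec@hueHi
  blood <- mask@inside & hueIn &
    features@sat >= sCut & features@val >= spec@vMin &
    features@astar >= aCut & features@lstar <= spec@lMax
  list(blood = blood, bloodPixels = sum(blood),
       maskedPixels = as.integer(features@nMasked))
}

#' Map a blood-pixel ratio to the 1-10 bleeding score
#'
#' Linear with a saturation ceiling: \code{1 + 9 * min(ratio / rMax, 1)}, so
#' a frame with no blood pixels scores 1 and a ratio of \code{rMax} or more
#' scores 10.
#'
#' @param ratio blood-pixel ratio(s) in \code{[0, 1]}.
#' @param rMax saturation ratio in \code{(0, 1]}.
#' @return score(s) in \code{[1, 10]}.
#' @export
ratioToScore <- function(ratio, rMax) {
  stopifnot(all(ratio >= 0 & ratio <= 1), rMax > 0, rMax <= 1)
  1 + 9 * pmin(ratio / rMax, 1)
}

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", signature(spec = "ThresholdSpec"),
  function(frame, mask, spec) {
    feat <- extractFeatures(frame, mask)
    cls <- classifyBloodPixels(feat, mask, spec)
    ratio <- cls$bloodPixels / cls$maskedPixels
    new("FrameScore", bloodPixels = as.integer(cls$bloodPixels),
        maskedPixels = cls$maskedPixels, ratio = ratio,
        score = ratioToScore(ratio, spec@rMax),
        frameIndex = frame@frameIndex)
  })

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", signature(spec = "RgbBaselineSpec"),
  function(frame, mask, spec) {
    px <- frame@pixels
    if (!identical(dim(px)[1:2], dim(mask@inside)))
      .stopf("frame and mask dimensions differ")
    n <- sum(mask@inside)
    if (n == 0L) .stopf("empty field mask")
    red <- px[, , 1]
    dom <- red - pmax(px[, , 2], px[, , 3])
    blood <- mask@inside & red >= spec@rMin & dom >= spec@dMin
    ratio <- sum(blood) / n
    new("FrameScore", bloodPixels = as.integer(sum(blood)),
        maskedPixels = as.integer(n), ratio = ratio,
        score = ratioToScore(ratio, spec@rMax),
        frameIndex = frame@frameIndex)
  })

#' RGB-only baseline frame scoring
#'
#' Convenience wrapper running the identical pipeline with the red-dominance
#' ablation predicate (see \linkS4class{RgbBaselineSpec}).
#'
#' @param frame a \linkS4class{FrameImage}.
#' @param mask a \linkS4class{FieldMask}.
#' @param redSpec an \linkS4class{RgbBaselineSpec}.
#' @return a \linkS4class{FrameScore}.
#' @export
scoreFrameRgbBaseline <- function(frame, mask, redSpec = rgbBaselineSpec()) {
  scoreFrame(frame, mask, redSpec)
}

#' Score one second from three random frames
#'
#' Samples 3 distinct frames uniformly without replacement (using the current
#' RNG state) and returns the mean of their frame scores; the sampled indices
#' are recorded for provenance. Averaging three random frames bounds the
#' influence of a single contaminated frame (e.g. a floating clot fragment)
#' on the second score to (10 - 1) / 3 = 3 score points.
#'
#' @param frames list of \linkS4class{FrameImage} (the frames of one second).
#' @param mask a \linkS4class{FieldMask}.
#' @param spec a \linkS4class{ThresholdSpec} or \linkS4class{RgbBaselineSpec}.
#' @return a \linkS4class{SecondScore}.
#' @export
scoreSecond <- function(frames, mask, spec) {
  if (length(frames) < 3L)
    .stopf("insufficient frames: a second needs at least 3 (got %d)",
           length(frames))
  idx <- sort(sample.int(length(frames), 3L))
  fs <- vapply(idx, function(i) {
    m <- if (is.null(mask)) detectFieldMask(frames[[i]]) else mask
    scoreFrame(frames[[i]], m, spec)@score
  }, numeric(1))
  new("SecondScore", sampledFrames = as.integer(idx), frameScores = fs,
      meanScore = mean(fs), resampleRounds = 1L)
}

## One full sampling round over every second of a clip.
.scoreRound <- function(secs, mask, spec) {
  ss <- lapply(secs, scoreSecond, mask = mask, spec = spec)
  list(seconds = ss,
       clipScore = mean(vapply(ss, function(x) x@meanScore, numeric(1))))
}

#' Score a clip with the temporal jump rule
#'
#' Scores every second of the clip from three random frames and applies the
#' abrupt-jump rule: when the clip score differs from the previous clip's
#' score by more than \code{jumpLimit} (strictly), a fresh set of three
#' frames is drawn for every second, up to \code{maxRetries} additional
#' rounds. If all rounds exceed the bound the minimum-jump round is returned
#' and flagged. When \code{prevScore} is absent the clip is virtually
#' duplicated: a first pass provides score(t-1) and the clip is then scored
#' again as score(t), emulating a 6 s recording made of two identical 3 s
#' segments.
#'
#' @param clip a \linkS4class{ClipFrames}.
#' @param spec a \linkS4class{ThresholdSpec} or \linkS4class{RgbBaselineSpec}.
#' @param prevScore score of the previous clip, or NULL for virtual
#'   duplication.
#' @param mask optional \linkS4class{FieldMask}; by default the mask is
#'   computed on the first frame and reused when the border is static (it is
#'   recomputed per frame when coverage drifts by more than 5%).
#' @param seed optional integer; when given, scoring runs under
#'   \code{withr::with_seed(seed)} and is bit-reproducible.
#' @param maxRetries maximum number of resampling rounds after the first.
#' @param jumpLimit jump bound (a difference of exactly \code{jumpLimit} is
#'   accepted).
#' @return a \linkS4class{ClipScore}.
#' @examples
#' g <- generateClip(syntheticSpec(bloodTransparency = 0.4), seconds = 1,
#'                   fps = 6)
#' scoreClip(g$clip, defaultThresholdSpec(), seed = 1)
#' @export
scoreClip <- function(clip, spec, prevScore = NULL, mask = NULL, seed = NULL,
                      maxRetries = 5L, jumpLimit = 3) {
  if (!is.null(seed))
    return(withr::with_seed(seed,
      scoreClip(clip, spec, prevScore = prevScore, mask = mask, seed = NULL,
                maxRetries = maxRetries, jumpLimit = jumpLimit)))
  if (clip@durationS < 1L) .stopf("empty clip")
  if (is.null(mask)) {
    cm <- .clipMask(clip)
    mask <- cm$mask  # NULL => per-frame masks in scoreSecond
  }
  secs <- clip@seconds
  first <- .scoreRound(secs, mask, spec)
  if (is.null(prevScore)) {
    prevScore <- first$clipScore
    current <- .scoreRound(secs, mask, spec)
  } else current <- first
  rounds <- 1L
  best <- current
  bestJump <- abs(current$clipScore - prevScore)
  while (abs(current$clipScore - prevScore) > jumpLimit &&
         rounds <= maxRetries) {
    current <- .scoreRound(secs, mask, spec)
    rounds <- rounds + 1L
    j <- abs(current$clipScore - prevScore)
    if (j < bestJump) { best <- current; bestJump <- j }
  }
  flagged <- bestJump > jumpLimit
  accepted <- if (abs(current$clipScore - prevScore) <= jumpLimit)
    current else best
  ss <- lapply(accepted$seconds, function(s) {
    s@resampleRounds <- rounds
    s
  })
  new("ClipScore", secondScores = ss, clipScore = accepted$clipScore,
      prevClipScore = prevScore, rounds = rounds, flagged = flagged,
      jump = abs(accepted$clipScore - prevScore))
}

.validatePhases <- function(phases, nSeconds) {
  if (is.null(phases)) {
    return(data.frame(name = character(), start = integer(),
                      end = integer(), meanScore = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("name", "start", "end") %in% names(phases)))
  ph <- phases[order(phases$start), , drop = FALSE]
  if (any(ph$start < 0) || any(ph$end > nSeconds) ||
      any(ph$end <= ph$start))
    .stopf("phase ranges must be non-empty half-open [start, end) within [0, %d)",
           nSeconds)
  if (nrow(ph) > 1L && any(ph$end[-nrow(ph)] > ph$start[-1L]))
    .stopf("phase ranges must not overlap")
  ph
}

#' Score a whole recording
#'
#' Processes the recording as consecutive clips of \code{clipLen} seconds
#' (the canonical 3 s unit); each clip's previous score is the preceding
#' clip's accepted score and the first clip uses virtual duplication. The
#' per-second accepted scores form the timeline; the total bleeding score is
#' their sum divided by the number of scored seconds, a length-independent
#' whole-procedure summary. Optional named phases (half-open second ranges)
#' get their own mean scores.
#'
#' With \code{temporalMode = "second"} the jump rule instead compares each
#' second to the mean of the up-to-three previously accepted seconds,
#' resampling only that second.
#'
#' @param frames a \linkS4class{ClipFrames} covering the recording.
#' @param spec a \linkS4class{ThresholdSpec} or \linkS4class{RgbBaselineSpec}.
#' @param phases optional data.frame with columns name, start, end.
#' @param seed optional integer seed; per-clip seeds are derived from it so
#'   reruns are bit-identical.
#' @param clipSeeds optional integer vector overriding the derived per-clip
#'   seeds (one per clip).
#' @param clipLen seconds per clip.
#' @param maxRetries,jumpLimit passed to [scoreClip()].
#' @param temporalMode "clip" (default, clip vs previous clip) or "second".
#' @return a \linkS4class{ProcedureReport}.
#' @export
scoreProcedure <- function(frames, spec, phases = NULL, seed = NULL,
                           clipSeeds = NULL, clipLen = 3L, maxRetries = 5L,
                           jumpLimit = 3, temporalMode = c("clip", "second")) {
  temporalMode <- match.arg(temporalMode)
  nSec <- frames@durationS
  ph <- .validatePhases(phases, nSec)
  cm <- .clipMask(frames)
  mask <- cm$mask
  if (temporalMode == "second") {
    timeline <- .scoreProcedureBySecond(frames, spec, mask, seed, maxRetries,
                                        jumpLimit)
    clipScores <- list()
  } else {
    starts <- seq(1L, nSec, by = clipLen)
    nClips <- length(starts)
    if (is.null(clipSeeds) && !is.null(seed))
      clipSeeds <- vapply(seq_len(nClips), function(i) .childSeed(seed, i),
                          integer(1))
    clipScores <- vector("list", nClips)
    prev <- NULL
    for (ci in seq_len(nClips)) {
      secIdx <- starts[ci]:min(starts[ci] + clipLen - 1L, nSec)
      sub <- new("ClipFrames", seconds = frames@seconds[secIdx],
                 fps = frames@fps, durationS = length(secIdx))
      cs <- scoreClip(sub, spec, prevScore = prev, mask = mask,
                      seed = if (is.null(clipSeeds)) NULL else clipSeeds[ci],
                      maxRetries = maxRetries, jumpLimit = jumpLimit)
      clipScores[[ci]] <- cs
      prev <- cs@clipScore
    }
    timeline <- unlist(lapply(clipScores, function(cs)
      vapply(cs@secondScores, function(s) s@meanScore, numeric(1))))
  }
  if (nrow(ph)) {
    ph$meanScore <- vapply(seq_len(nrow(ph)), function(i)
      mean(timeline[(ph$start[i] + 1L):ph$end[i]]), numeric(1))
    ph$n <- as.integer(ph$end - ph$start)
  }
  new("ProcedureReport", timeline = timeline, phases = ph,
      totalBleedingScore = mean(timeline), clipScores = clipScores,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      temporalMode = temporalMode)
}

## Optional per-second temporal mode: each second is compared to the mean of
## the previous (up to) three accepted seconds.
.scoreProcedureBySecond <- function(frames, spec, mask, seed, maxRetries,
                                    jumpLimit) {
  run <- function() {
    accepted <- numeric(0)
    for (si in seq_len(frames@durationS)) {
      sec <- frames@seconds[[si]]
      s <- scoreSecond(sec, mask, spec)@meanScore
      ref <- if (length(accepted)) mean(utils::tail(accepted, 3L)) else {
        ## virtual duplication analogue: a fresh draw provides the reference
        scoreSecond(sec, mask, spec)@meanScore
      }
      tries <- 0L
      bestS <- s
      bestJ <- abs(s - ref)
      while (abs(s - ref) > jumpLimit && tries < maxRetries) {
        s <- scoreSecond(sec, mask, spec)@meanScore
        tries <- tries + 1L
        if (abs(s - ref) < bestJ) { bestS <- s; bestJ <- abs(s - ref) }
      }
      accepted <- c(accepted, if (abs(s - ref) <= jumpLimit) s else bestS)
    }
    accepted
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
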