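## Synthetic arthroscopy frame generator: pale textured tissue background,
## circular optical field with a black surround and radial vignetting, blood
## composited as an alpha-blended translucent red overlay, plus optional
## clot-artifact and inflammation confounders -- all with declared ground
## truth so every scoring component is testable without clinical footage.

#' Construct a SyntheticSpec
#'
#' Defaults describe a realistic quiet arthroscopic scene: a beige-gray
#' tissue background (pale white/beige/grayish tones dominate the joint
#' space), 12% low-frequency multiplicative texture, moderate radial
#' vignetting, and an optical field disk of 0.65 of the half-diagonal. Blood
#' is a dark red; its transparency t maps to the true score as
#' \code{10 - 10 t} (clamped to \code{[1, 10]}).
#'
#' @param width,height frame size in pixels.
#' @param baseColor pale tissue RGB.
#' @param textureAmp multiplicative texture amplitude.
#' @param vignetteStrength radial darkening at the field edge.
#' @param fieldRadiusFrac disk radius as a fraction of the half-diagonal.
#' @param bloodTransparency overlay transparency t in \code{[0, 1]}.
#' @param bloodPattern "uniform", "plume" or "none".
#' @param bloodColor overlay RGB.
#' @param artifact empty list or list(frames, centerFrac, radiusFrac, alpha).
#' @param inflammation empty list or list(centerFrac, radiusFrac, strength).
#' @param seed RNG seed for all generator randomness.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(width = 128L, height = 128L,
                          baseColor = c(210, 196, 182), textureAmp = 0.12,
                          vignetteStrength = 0.3, fieldRadiusFrac = 0.65,
                          bloodTransparency = 0.5, bloodPattern = "uniform",
                          bloodColor = c(150, 25, 35), artifact = list(),
                          inflammation = list(), seed = 1L) {
  new("SyntheticSpec", width = as.integer(width), height = as.integer(height),
      baseColor = as.numeric(baseColor), textureAmp = textureAmp,
      vignetteStrength = vignetteStrength, fieldRadiusFrac = fieldRadiusFrac,
      bloodTransparency = bloodTransparency, bloodPattern = bloodPattern,
      bloodColor = as.numeric(bloodColor), artifact = artifact,
      inflammation = inflammation, seed = as.integer(seed))
}

#' Map overlay transparency to the true bleeding score
#'
#' Linear calibration of the red-overlay protocol: score
#' \code{= 10 - 10 t}, clamped to \code{[1, 10]}, so 90% transparency
#' corresponds to score 1 and 10% transparency to score 9.
#'
#' @param t transparency value(s) in \code{[0, 1]}.
#' @return true score(s) in \code{[1, 10]}.
#' @examples
#' transparencyToScore(c(0.9, 0.5, 0.1))
#' @export
transparencyToScore <- function(t) {
  if (any(t < 0 | t > 1)) .stopf("transparency must lie in [0, 1]")
  .clamp(10 - 10 * t, 1, 10)
}

## Bilinear upsampling of a coarse matrix to h x w.
.bilinearUp <- function(coarse, h, w) {
  gh <- nrow(coarse); gw <- ncol(coarse)
  u <- if (h == 1L) rep(1, h) else (seq_len(h) - 1) / (h - 1) * (gh - 1) + 1
  v <- if (w == 1L) rep(1, w) else (seq_len(w) - 1) / (w - 1) * (gw - 1) + 1
  i0 <- pmin(floor(u), gh - 1L); fi <- u - i0
  j0 <- pmin(floor(v), gw - 1L); fj <- v - j0
  rows <- coarse[i0, , drop = FALSE] * (1 - fi) +
    coarse[i0 + 1L, , drop = FALSE] * fi
  rows[, j0, drop = FALSE] * rep(1 - fj, each = h) +
    rows[, j0 + 1L, drop = FALSE] * rep(fj, each = h)
}

.gaussBlob <- function(h, w, centerFrac, radiusFrac, R) {
  cy <- centerFrac[1] * h; cx <- centerFrac[2] * w
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  sigma <- radiusFrac * R
  exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
}

## Render the clip-static scene: continuous [0, 1] background (texture,
## vignette, optional inflammation patch), field disk, plume field.
## All randomness is drawn in a fixed order under the spec seed.
.renderBase <- function(spec) {
  h <- spec@height; w <- spec@width
  withr::with_seed(spec@seed, {
    gh <- max(4L, h %/% 16L); gw <- max(4L, w %/% 16L)
    shared <- .bilinearUp(matrix(stats::rnorm(gh * gw), gh, gw), h, w)
    chan <- lapply(1:3, function(i)
      .bilinearUp(matrix(stats::rnorm(gh * gw), gh, gw), h, w))
    plume <- if (spec@bloodPattern == "plume") {
      f <- .bilinearUp(matrix(stats::rnorm(25), 5, 5), h, w)
      f <- pmax(f, 0)
      if (max(f) > 0) f / max(f) else f
    } else NULL
  })
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  halfDiag <- sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  R <- spec@fieldRadiusFrac * halfDiag
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  inside <- dist <= R
  vignette <- 1 - spec@vignetteStrength * pmin(dist / R, 1)^2
  bg <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    tex <- .clamp(1 + spec@textureAmp *
                    (0.85 * shared + 0.55 * chan[[ch]]), 0.3, 1.7)
    bg[, , ch] <- spec@baseColor[ch] / 255 * tex * vignette
  }
  if (length(spec@inflammation)) {
    inf <- spec@inflammation
    blob <- .gaussBlob(h, w, inf$centerFrac, inf$radiusFrac, R) * inf$strength
    pink <- c(205, 155, 160) / 255  # pale pink, saturation below blood range
    for (ch in 1:3)
      bg[, , ch] <- (1 - blob) * bg[, , ch] + blob * pink[ch]
  }
  bg <- .clamp(bg, 0, 1)
  list(bg = bg, inside = inside, plume = plume, R = R)
}

## Composite blood at transparency t over a rendered base and quantise.
.compositeFrame <- function(base, spec, t) {
  h <- spec@height; w <- spec@width
  alphaMap <- if (spec@bloodPattern == "none") {
    matrix(0, h, w)
  } else {
    a <- 1 - t
    if (spec@bloodPattern == "plume") a * base$plume else matrix(a, h, w)
  }
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alphaMap) * base$bg[, , ch] +
      alphaMap * spec@bloodColor[ch] / 255
  for (ch in 1:3) out[, , ch][!base$inside] <- 0
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(round(out[, , ch] * 255))
  px
}

.applyArtifact <- function(px, base, spec) {
  art <- spec@artifact
  blob <- .gaussBlob(nrow(px), ncol(px), art$centerFrac, art$radiusFrac,
                     base$R)
  blob <- (blob > 0.35) * (if (is.null(art$alpha)) 0.95 else art$alpha)
  clot <- c(190, 25, 30)  # bright clot red
  for (ch in 1:3) {
    plane <- px[, , ch] / 255
    plane <- (1 - blob) * plane + blob * clot[ch] / 255
    plane[!base$inside] <- 0
    px[, , ch] <- as.integer(round(plane * 255))
  }
  px
}

#' Generate one synthetic frame with ground truth
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param frameIndex 0-based index recorded in the frame (an artifact listed
#'   in the spec is applied when it names this index).
#' @return list with \code{frame} (\linkS4class{FrameImage}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' fr <- generateFrame(syntheticSpec(bloodTransparency = 0.2, seed = 7))
#' bleedingScore(fr$truth)
#' @export
generateFrame <- function(spec, frameIndex = 0L) {
  base <- .renderBase(spec)
  px <- .compositeFrame(base, spec, spec@bloodTransparency)
  if (length(spec@artifact) && frameIndex %in% spec@artifact$frames)
    px <- .applyArtifact(px, base, spec)
  truth <- new("GroundTruth",
               trueScore = if (spec@bloodPattern == "none") 1
                 else transparencyToScore(spec@bloodTransparency),
               maskTruth = base$inside)
  list(frame = frameImage(px, frameIndex = frameIndex), truth = truth)
}

#' Generate a synthetic clip with per-second ground truth
#'
#' All frames share one field disk and background; the per-second overlay
#' transparency is either constant (visual homogeneity, the validation-study
#' condition) or follows \code{schedule}. Frames within a second are
#' identical except where a clot artifact is injected; artifacts do not
#' change the ground truth, since a transiently visualised clot is not
#' bleeding.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seconds clip duration in whole seconds.
#' @param fps frames per second (>= 3).
#' @param schedule optional per-second transparency vector of length
#'   \code{seconds}.
#' @return list with \code{clip} (\linkS4class{ClipFrames}), \code{truth}
#'   (data.frame second/transparency/trueScore) and \code{mask} (the exact
#'   field disk).
#' @export
generateClip <- function(spec, seconds = 3L, fps = 24L, schedule = NULL) {
  stopifnot(seconds >= 1L, fps >= 3L)
  tSched <- if (is.null(schedule)) rep(spec@bloodTransparency, seconds)
            else schedule
  if (length(tSched) != seconds)
    .stopf("schedule length must equal seconds")
  base <- .renderBase(spec)
  secs <- vector("list", seconds)
  idx <- 0L
  for (s in seq_len(seconds)) {
    px <- .compositeFrame(base, spec, tSched[s])
    grp <- vector("list", fps)
    for (j in seq_len(fps)) {
      fpx <- if (length(spec@artifact) && idx %in% spec@artifact$frames)
        .applyArtifact(px, base, spec) else px
      grp[[j]] <- frameImage(fpx, frameIndex = idx, timestamp = idx / fps)
      idx <- idx + 1L
    }
    secs[[s]] <- grp
  }
  truth <- data.frame(second = seq_len(seconds) - 1L,
                      transparency = tSched,
                      trueScore = if (spec@bloodPattern == "none")
                        rep(1, seconds) else transparencyToScore(tSched))
  list(clip = new("ClipFrames", seconds = secs, fps = as.integer(fps),
                  durationS = as.integer(seconds)),
       truth = truth,
       mask = new("FieldMask", inside = base$inside,
                  coverage = mean(base$inside)))
}

#' Generate the labelled synthetic validation set
#'
#' Emulates the validation design at desk scale: \code{nPerLevel}
#' homogeneous clips per true-score level with randomised nuisance
#' parameters (tissue tint, texture amplitude, vignetting, field radius,
#' blood shade drawn from a narrow dark-red family) and, in a fraction of
#' clips, a pale-pink inflammation confounder. Per-level transparency is
#' \code{(10 - level) / 10} so the true score equals the level.
#'
#' @param nPerLevel clips per score level.
#' @param levels integer score levels (1-10).
#' @param seed RNG seed; two runs with the same seed give identical sets.
#' @param width,height frame size.
#' @param fps,seconds clip geometry.
#' @param inflammationProb probability that a clip carries an inflammation
#'   patch.
#' @param dir optional directory; when given, every clip is written as a PNG
#'   sequence under \code{clip_###/} together with \code{manifest.csv}.
#' @return a \linkS4class{ValidationSet}.
#' @examples
#' vs <- generateValidationSet(1, levels = c(1, 5, 9), seed = 3,
#'                             width = 64, height = 64, fps = 3)
#' vs@manifest$true_score
#' @export
generateValidationSet <- function(nPerLevel = 20L, levels = 1:10, seed = 1L,
                                  width = 128L, height = 128L, fps = 24L,
                                  seconds = 3L, inflammationProb = 0.35,
                                  dir = NULL) {
  stopifnot(nPerLevel >= 1L, all(levels >= 1 & levels <= 10))
  rows <- list(); specs <- list()
  withr::with_seed(seed, {
    id <- 0L
    for (lev in levels) for (r in seq_len(nPerLevel)) {
      id <- id + 1L
      tint <- stats::runif(3, -12, 12)
      baseColor <- .clamp(c(210, 196, 182) + tint, 150, 245)
      bloodColor <- c(stats::runif(1, 130, 170), stats::runif(1, 15, 40),
                      stats::runif(1, 25, 50))
      inf <- if (stats::runif(1) < inflammationProb)
        list(centerFrac = stats::runif(2, 0.3, 0.7),
             radiusFrac = stats::runif(1, 0.15, 0.30),
             strength = stats::runif(1, 0.4, 0.7))
      else list()
      sp <- syntheticSpec(
        width = width, height = height, baseColor = baseColor,
        textureAmp = stats::runif(1, 0.08, 0.18),
        vignetteStrength = stats::runif(1, 0.20, 0.45),
        fieldRadiusFrac = stats::runif(1, 0.58, 0.70),
        bloodTransparency = (10 - lev) / 10,
        bloodPattern = "uniform", bloodColor = bloodColor,
        inflammation = inf,
        seed = sample.int(2^30, 1))
      specs[[id]] <- sp
      rows[[id]] <- data.frame(
        clip_id = sprintf("clip_%03d", id), level = lev,
        true_score = transparencyToScore((10 - lev) / 10),
        transparency = (10 - lev) / 10, seed = sp@seed,
        base_r = baseColor[1], base_g = baseColor[2], base_b = baseColor[3],
        blood_r = bloodColor[1], blood_g = bloodColor[2],
        blood_b = bloodColor[3],
        texture_amp = sp@textureAmp, vignette = sp@vignetteStrength,
        field_radius_frac = sp@fieldRadiusFrac,
        inflammation = length(inf) > 0, stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  vs <- new("ValidationSet", manifest = manifest, specs = specs,
            fps = as.integer(fps), seconds = as.integer(seconds))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest)))
      writeClipPng(realizeClip(vs, i)$clip,
                   file.path(dir, manifest$clip_id[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  vs
}

#' Realise one clip of a validation set
#'
#' @param vs a \linkS4class{ValidationSet}.
#' @param i clip index (row of the manifest).
#' @return as [generateClip()].
#' @export
realizeClip <- function(vs, i) {
  generateClip(vs@specs[[i]], seconds = vs@seconds, fps = vs@fps)
}
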