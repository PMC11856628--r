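## Frame input: image sequences (and, when an ffmpeg binary is available,
## video containers), per-second grouping, and optical-field mask detection.

#' Construct a FrameImage
#'
#' @param pixels numeric or integer \code{h x w x 3} array with values in
#'   \code{[0, 255]}.
#' @param frameIndex 0-based index within the clip.
#' @param timestamp seconds from clip start.
#' @return a \linkS4class{FrameImage}.
#' @export
frameImage <- function(pixels, frameIndex = 0L, timestamp = 0) {
  storage.mode(pixels) <- "integer"
  new("FrameImage", pixels = pixels, frameIndex = as.integer(frameIndex),
      timestamp = as.numeric(timestamp))
}

## Read one image file into an integer h x w x 3 array in [0, 255].
## EBImage stores images as width x height in [0, 1]; transpose to rows =
## image rows and rescale at this boundary.
.readFrameArray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  out <- array(0L, c(dim(a)[2], dim(a)[1], 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(round(t(a[, , ch]) * 255))
  out
}

.writeFrameArray <- function(pixels, path) {
  a <- array(0, c(dim(pixels)[2], dim(pixels)[1], 3L))
  for (ch in 1:3) a[, , ch] <- t(pixels[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path, bits = 8L)
  invisible(path)
}

#' Read a clip as per-second frame groups
#'
#' Reads a directory of lexicographically ordered image files (PNG/TIFF) or,
#' when an \command{ffmpeg} binary is on the PATH, a video container, and
#' groups the decoded frames into whole seconds. A trailing partial second
#' with fewer than \code{fps} frames is dropped with a warning; the canonical
#' scoring unit is the whole second.
#'
#' @param path directory of image files or a video file.
#' @param fpsOverride frames per second; defaults to 24 for image sequences
#'   (the native frame rate of the targeted arthroscopy recorders) and to the
#'   container's rate for videos.
#' @return a \linkS4class{ClipFrames}.
#' @examples
#' d <- file.path(tempdir(), "clipdemo")
#' writeClipPng(generateClip(syntheticSpec(), seconds = 1, fps = 4)$clip, d)
#' readClip(d, fpsOverride = 4)
#' @export
readClip <- function(path, fpsOverride = NULL) {
  if (!file.exists(path)) .stopf("input path does not exist: %s", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) .stopf("no PNG/TIFF frames found in %s", path)
    fps <- if (is.null(fpsOverride)) 24L else as.integer(fpsOverride)
  } else {
    extracted <- .extractVideoFrames(path, fpsOverride)
    files <- extracted$files
    fps <- extracted$fps
  }
  if (fps < 3L) .stopf("fps must be at least 3 (got %d)", fps)
  nComplete <- length(files) %/% fps
  if (nComplete == 0L)
    .stopf("empty clip: %d frames decode to zero complete seconds at %d fps",
           length(files), fps)
  dropped <- length(files) - nComplete * fps
  if (dropped > 0L)
    warning(sprintf("dropping trailing partial second (%d frames)", dropped))
  secs <- vector("list", nComplete)
  idx <- 0L
  for (s in seq_len(nComplete)) {
    grp <- vector("list", fps)
    for (j in seq_len(fps)) {
      grp[[j]] <- frameImage(.readFrameArray(files[idx + 1L]),
                             frameIndex = idx, timestamp = idx / fps)
      idx <- idx + 1L
    }
    secs[[s]] <- grp
  }
  new("ClipFrames", seconds = secs, fps = fps, durationS = nComplete)
}

## Decode a video container by shelling out to ffmpeg when present.
.extractVideoFrames <- function(path, fpsOverride) {
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg))
    .stopf(paste("video container input requires an ffmpeg binary on the",
                 "PATH; none found. Decode %s to a PNG sequence and pass the",
                 "directory instead."), path)
  fps <- if (is.null(fpsOverride)) 24L else as.integer(fpsOverride)
  out <- file.path(tempfile("frames"), "f")
  dir.create(dirname(out), recursive = TRUE)
  status <- system2(ffmpeg, c("-v", "error", "-i", shQuote(path),
                              "-vf", sprintf("fps=%d", fps),
                              shQuote(paste0(out, "%06d.png"))))
  if (status != 0L) .stopf("ffmpeg failed to decode %s", path)
  files <- sort(list.files(dirname(out), pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) .stopf("ffmpeg produced no frames for %s", path)
  list(files = files, fps = fps)
}

#' Write a clip as a PNG sequence
#'
#' Frames are written as \code{frame_000000.png, ...} in decode order; the
#' sequence round-trips losslessly through [readClip()].
#'
#' @param clip a \linkS4class{ClipFrames}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeClipPng <- function(clip, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  i <- 0L
  for (sec in clip@seconds) for (fr in sec) {
    .writeFrameArray(fr@pixels, file.path(dir, sprintf("frame_%06d.png", i)))
    i <- i + 1L
  }
  invisible(dir)
}

#' Detect the circular optical field of a frame
#'
#' Arthroscope frames carry a near-black vignette around a circular optical
#' field. Pixels with HSV value below \code{vBlack} are marked as border
#' candidates; the mask is the largest connected bright component after
#' morphological closing with a disc brush.
#'
#' @param frame a \linkS4class{FrameImage}.
#' @param vBlack value threshold in \code{[0, 1]} below which a pixel is
#'   considered part of the black border.
#' @param brushSize diameter in pixels of the closing brush.
#' @return a \linkS4class{FieldMask}.
#' @examples
#' fr <- generateFrame(syntheticSpec())
#' detectFieldMask(fr$frame)
#' @export
detectFieldMask <- function(frame, vBlack = 0.08, brushSize = 5L) {
  px <- frame@pixels
  v <- pmax(px[, , 1], px[, , 2], px[, , 3]) / 255
  bright <- v >= vBlack
  if (!any(bright)) .stopf("empty field: frame is entirely black")
  ## EBImage works width x height; transpose at the boundary.
  closed <- EBImage::closing(t(bright) * 1,
                             EBImage::makeBrush(as.integer(brushSize), "disc"))
  labels <- EBImage::bwlabel(closed)
  tab <- tabulate(as.integer(labels[labels > 0]))
  if (!length(tab)) .stopf("empty field: no bright component found")
  inside <- t(labels == which.max(tab))
  cov <- mean(inside)
  if (cov == 0) .stopf("empty field: mask coverage is zero")
  new("FieldMask", inside = inside, coverage = cov)
}

## Static-mask caching for a clip: compute the mask on the first frame, spot
## check coverage on the last frame, and fall back to per-frame masks when the
## border is not static (coverage differs by more than 5%).
.clipMask <- function(clip, vBlack = 0.08) {
  frames <- unlist(clip@seconds, recursive = FALSE)
  m1 <- detectFieldMask(frames[[1L]], vBlack)
  if (length(frames) > 1L) {
    m2 <- detectFieldMask(frames[[length(frames)]], vBlack)
    if (abs(m2@coverage - m1@coverage) / m1@coverage > 0.05)
      return(list(mask = NULL, static = FALSE, vBlack = vBlack))
  }
  list(mask = m1, static = TRUE, vBlack = vBlack)
}
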