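## Colour-space conversions: 8-bit sRGB -> HSV and CIELAB (D65, 2 degrees).
##
## CIELAB uses the standard sRGB companding and the tabulated sRGB -> XYZ
## matrix for D65; grDevices::convertColor re-derives the primaries and
## deviates from the tabulated standard by up to ~0.26 in a*/b*, so the
## transform is computed here explicitly.

.srgbToXyzMatrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.d65White <- c(0.95047, 1.00000, 1.08883)

#' Convert a frame to HSV planes
#'
#' Standard hexcone HSV on channels normalised to \code{[0, 1]}. Hue is
#' returned in degrees \code{[0, 360)}; achromatic pixels get hue 0.
#'
#' @param frame a \linkS4class{FrameImage}.
#' @return list with matrices \code{hue}, \code{sat}, \code{val}.
#' @examples
#' fr <- generateFrame(syntheticSpec())
#' h <- rgbToHsv(fr$frame)
#' range(h$hue)
#' @export
rgbToHsv <- function(frame) {
  px <- frame@pixels
  hsv <- grDevices::rgb2hsv(r = as.vector(px[, , 1]),
                            g = as.vector(px[, , 2]),
                            b = as.vector(px[, , 3]),
                            maxColorValue = 255)
  d <- dim(px)[1:2]
  hue <- matrix(hsv[1L, ] * 360, d[1], d[2])
  hue[hue >= 360] <- 0
  list(hue = hue,
       sat = matrix(hsv[2L, ], d[1], d[2]),
       val = matrix(hsv[3L, ], d[1], d[2]))
}

## Vectorised sRGB (0..1) -> Lab on an n x 3 matrix.
.srgbMatrixToLab <- function(rgb01) {
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92,
                ((rgb01 + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgbToXyzMatrix)
  xr <- sweep(xyz, 2, .d65White, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xr > eps, xr^(1 / 3), xr / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Convert a frame to CIELAB planes
#'
#' Interprets the 8-bit input as sRGB: sRGB companding to linear RGB, the
#' tabulated sRGB -> XYZ matrix, D65 white point, 2-degree observer.
#'
#' @param frame a \linkS4class{FrameImage}.
#' @return list with matrices \code{lstar}, \code{astar}, \code{bstar}.
#' @examples
#' fr <- generateFrame(syntheticSpec())
#' lab <- rgbToLab(fr$frame)
#' range(lab$lstar)
#' @export
rgbToLab <- function(frame) {
  px <- frame@pixels
  lab <- .srgbMatrixToLab(cbind(as.vector(px[, , 1]),
                                as.vector(px[, , 2]),
                                as.vector(px[, , 3])) / 255)
  d <- dim(px)[1:2]
  list(lstar = matrix(lab[, 1], d[1], d[2]),
       astar = matrix(lab[, 2], d[1], d[2]),
       bstar = matrix(lab[, 3], d[1], d[2]))
}

#' Extract colour features of a frame over its optical field
#'
#' Computes all six HSV/CIELAB planes plus the frame-level mean saturation and
#' mean a* over the masked pixels, which drive the adaptive threshold cut-offs
#' of the blood-pixel predicate.
#'
#' @param frame a \linkS4class{FrameImage}.
#' @param mask a \linkS4class{FieldMask} of the same dimensions.
#' @return a \linkS4class{ColorFeatures} object.
#' @examples
#' fr <- generateFrame(syntheticSpec())
#' feat <- extractFeatures(fr$frame, detectFieldMask(fr$frame))
#' feat@meanS
#' @export
extractFeatures <- function(frame, mask) {
  if (!identical(dim(frame@pixels)[1:2], dim(mask@inside)))
    .stopf("frame and mask dimensions differ")
  n <- sum(mask@inside)
  if (n == 0L) .stopf("empty field mask: no pixels inside the optical field")
  hsv <- rgbToHsv(frame)
  lab <- rgbToLab(frame)
  new("ColorFeatures",
      hue = hsv$hue, sat = hsv$sat, val = hsv$val,
      lstar = lab$lstar, astar = lab$astar, bstar = lab$bstar,
      meanS = mean(hsv$sat[mask@inside]),
      meanA = mean(lab$astar[mask@inside]),
      nMasked = as.integer(n))
}
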