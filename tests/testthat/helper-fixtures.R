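## Shared fixtures: tiny frames, reference conversions and a frozen
## plausible threshold specification used as the "known truth" in
## self-consistency tests.

## A calibrated-range specification frozen as a literal so tests are stable.
knownSpec <- function() {
  thresholdSpec(hueLo = 343, hueHi = 20.5, sMin = 0.25, vMin = 0.10,
                aMin = 5.812, lMax = 100, gammaS = 0.547, gammaA = 0.970,
                sRef = 0.15, aRef = 5, rMax = 0.863)
}

## Strict spec that flags saturated reds only; clean pale tissue scores 1.
strictRedSpec <- function(rMax = 0.8) {
  thresholdSpec(hueLo = 330, hueHi = 25, sMin = 0.45, vMin = 0.15,
                aMin = 30, lMax = 100, gammaS = 0, gammaA = 0,
                sRef = 0.15, aRef = 5, rMax = rMax)
}

## Uniform-colour frame.
uniformFrame <- function(rgb, h = 24L, w = 24L) {
  frameImage(array(rep(as.integer(rgb), each = h * w), c(h, w, 3L)))
}

fullMask <- function(h = 24L, w = 24L) {
  new("FieldMask", inside = matrix(TRUE, h, w), coverage = 1)
}

## Frame with the first k pixels (column order) pure red on mid-gray; with
## an all-true mask and the red-dominance baseline it scores 1 + 9 k / (h w).
stairFrame <- function(k, h = 30L, w = 30L) {
  px <- array(rep(c(120L, 120L, 120L), each = h * w), c(h, w, 3L))
  if (k > 0) {
    r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
    r[seq_len(k)] <- 255L; g[seq_len(k)] <- 0L; b[seq_len(k)] <- 0L
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  }
  frameImage(px)
}

## ClipFrames made of identical copies of given frames (one list per second).
clipOfSeconds <- function(frameList, fps = 6L) {
  secs <- lapply(frameList, function(fr) rep(list(fr), fps))
  new("ClipFrames", seconds = secs, fps = as.integer(fps),
      durationS = length(secs))
}

## Per-pixel scalar reference for the blood predicate (independent loop).
loopClassify <- function(features, mask, spec) {
  d <- dim(features@hue)
  out <- matrix(FALSE, d[1], d[2])
  sCut <- min(max(spec@sMin + spec@gammaS * (features@meanS - spec@sRef), 0), 1)
  aCut <- spec@aMin + spec@gammaA * (features@meanA - spec@aRef)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!mask@inside[i, j]) next
    hue <- features@hue[i, j]
    hueIn <- if (spec@hueLo <= spec@hueHi)
      hue >= spec@hueLo && hue <= spec@hueHi
    else hue >= spec@hueLo || hue <= spec@hueHi
    out[i, j] <- hueIn &&
      features@sat[i, j] >= sCut &&
      features@val[i, j] >= spec@vMin &&
      features@astar[i, j] >= aCut &&
      features@lstar[i, j] <= spec@lMax
  }
  out
}

## From-scratch two-way ANOVA mean squares via stats::aov (independent of
## the package's direct-sums implementation), plus the absolute-agreement
## estimators written out again.
oracleIccA <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(score = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(score ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  list(
    a1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    ak = (msr - mse) / (msr + (msc - mse) / n))
}

## Fixed 6 x 3 rating matrix with externally verified ICC values.
fixedRatings <- function() {
  matrix(c(7, 9, 8,
           1, 2, 2.5,
           5, 6, 5.5,
           3, 2, 4,
           9, 8.5, 9.5,
           4, 5, 4.5), nrow = 6, byrow = TRUE)
}
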