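## Small, fast calibration checks; the full validation-design fit lives in
## the acceptance suite.

makeLabelledClips <- function(n = 10, size = 48L, seedBase = 300L) {
  ts <- seq(0.1, 0.9, length.out = n)
  clips <- lapply(seq_len(n), function(i)
    generateClip(syntheticSpec(width = size, height = size,
                               bloodTransparency = ts[i],
                               seed = seedBase + i), seconds = 2, fps = 3))
  labels <- vapply(clips, function(g)
    scoreClip(g$clip, knownSpec(), seed = 1)@clipScore, numeric(1))
  list(clips = clips, labels = labels)
}

test_that("zero refinement returns the best evaluated coarse point", {
  x <- makeLabelledClips(8)
  fit <- fitThresholds(x$clips, labels = x$labels, seed = 4, sweeps = 0,
                       maxPixels = 800)
  tr <- searchTrace(fit)
  best <- tr[which.min(tr$loss), ]
  expect_equal(fit@trainMae, min(tr$loss))
  for (nm in c("hueLo", "hueHi", "sMin", "vMin", "aMin", "gammaA", "rMax"))
    expect_equal(slot(fittedSpec(fit), nm), best[[nm]])
})

test_that("the running best loss never increases along the search", {
  x <- makeLabelledClips(8)
  fit <- fitThresholds(x$clips, labels = x$labels, seed = 4, sweeps = 1,
                       maxPixels = 800)
  expect_true(all(diff(searchTrace(fit)$bestLoss) <= 0))
  expect_true(validObject(fittedSpec(fit)))
  expect_equal(fit@trainMae, min(searchTrace(fit)$loss))
})

test_that("refitting with the same seed and data is bit-identical", {
  x <- makeLabelledClips(8)
  f1 <- fitThresholds(x$clips, labels = x$labels, seed = 9, sweeps = 1,
                      coarse = FALSE, maxPixels = 800)
  f2 <- fitThresholds(x$clips, labels = x$labels, seed = 9, sweeps = 1,
                      coarse = FALSE, maxPixels = 800)
  for (nm in slotNames("ThresholdSpec"))
    expect_identical(slot(fittedSpec(f1), nm), slot(fittedSpec(f2), nm))
  expect_identical(holdoutMae(f1), holdoutMae(f2))
})

test_that("degenerate inputs are rejected", {
  x <- makeLabelledClips(6)
  expect_error(fitThresholds(x$clips, labels = rep(5, 6)), "distinct label")
  expect_error(fitThresholds(x$clips, labels = x$labels[-1]), "one label")
  expect_error(fitThresholds(x$clips, labels = x$labels, holdoutFrac = 0),
               "holdoutFrac")
  expect_error(fitThresholds(x$clips), "labels")
})

test_that("the RGB baseline fits through the same machinery", {
  x <- makeLabelledClips(8)
  fit <- fitThresholds(x$clips, labels = x$labels, mode = "rgb", seed = 4,
                       sweeps = 1, maxPixels = 800)
  expect_s4_class(fittedSpec(fit), "RgbBaselineSpec")
  expect_true(all(diff(searchTrace(fit)$bestLoss) <= 0))
})
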