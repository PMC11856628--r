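test_that("ratio maps linearly to [1, 10] with a saturation ceiling", {
  expect_identical(ratioToScore(0, 0.6), 1)
  expect_identical(ratioToScore(0.6, 0.6), 10)
  expect_identical(ratioToScore(0.9, 0.6), 10)
  expect_identical(ratioToScore(0.3, 0.6), 5.5)
  expect_error(ratioToScore(1.2, 0.6))
})

test_that("the blood predicate flags saturated reds and spares gray", {
  red <- uniformFrame(c(170, 30, 40))
  m <- fullMask()
  feat <- extractFeatures(red, m)
  cls <- classifyBloodPixels(feat, m, strictRedSpec())
  expect_equal(cls$bloodPixels, cls$maskedPixels)

  gray <- uniformFrame(c(150, 150, 150))
  cls2 <- classifyBloodPixels(extractFeatures(gray, m), m, strictRedSpec())
  expect_equal(cls2$bloodPixels, 0L)  # fails every saturation gate

  ## pixels outside the mask are never flagged
  half <- new("FieldMask",
              inside = rbind(matrix(TRUE, 12, 24), matrix(FALSE, 12, 24)),
              coverage = 0.5)
  cls3 <- classifyBloodPixels(extractFeatures(red, half), half,
                              strictRedSpec())
  expect_equal(cls3$bloodPixels, sum(half@inside))
  expect_false(any(cls3$blood[!half@inside]))
})

test_that("vectorised classification equals the per-pixel loop", {
  set.seed(33)
  for (i in 1:5) {
    px <- array(sample.int(256, 20 * 20 * 3, TRUE) - 1L, c(20L, 20L, 3L))
    f <- frameImage(px)
    inside <- matrix(runif(400) > 0.3, 20, 20)
    m <- new("FieldMask", inside = inside, coverage = mean(inside))
    sp <- thresholdSpec(hueLo = runif(1, 300, 359), hueHi = runif(1, 5, 60),
                        sMin = runif(1, 0, 0.6), vMin = runif(1, 0, 0.4),
                        aMin = runif(1, -5, 30), lMax = runif(1, 60, 100),
                        gammaS = runif(1, 0, 1.2), gammaA = runif(1, 0, 1.2),
                        rMax = runif(1, 0.2, 1))
    feat <- extractFeatures(f, m)
    expect_identical(classifyBloodPixels(feat, m, sp)$blood,
                     loopClassify(feat, m, sp))
  }
})

test_that("a second is scored from three distinct sampled frames", {
  fr <- uniformFrame(c(170, 30, 40))
  frames <- rep(list(fr), 8)
  m <- fullMask()
  set.seed(1)
  ss <- scoreSecond(frames, m, strictRedSpec())
  expect_length(sampledFrames(ss), 3L)
  expect_false(anyDuplicated(sampledFrames(ss)) > 0)
  expect_equal(bleedingScore(ss), 10)  # identical frames: mean = any frame

  set.seed(42); a <- scoreSecond(frames, m, strictRedSpec())
  set.seed(42); b <- scoreSecond(frames, m, strictRedSpec())
  expect_identical(sampledFrames(a), sampledFrames(b))
  expect_identical(bleedingScore(a), bleedingScore(b))

  expect_error(scoreSecond(frames[1:2], m, strictRedSpec()), "insufficient")
})

test_that("sampled-frame averages estimate the all-frame mean", {
  ## 6 frames with known scores via the staircase construction: sampling
  ## theory says the mean of repeated 3-frame means approaches the mean of
  ## all frame scores
  ks <- c(0, 100, 200, 300, 500, 700)
  frames <- lapply(ks, stairFrame)
  m <- fullMask(30L, 30L)
  sp <- rgbBaselineSpec(rMin = 200, dMin = 50, rMax = 1)
  frameScores <- 1 + 9 * ks / 900
  means <- vapply(1:400, function(s) {
    set.seed(s)
    bleedingScore(scoreSecond(frames, m, sp))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mean(frameScores)), 3 * se)
})

test_that("the RGB baseline scores red dominance only", {
  m <- fullMask()
  red <- scoreFrameRgbBaseline(uniformFrame(c(255, 0, 0)), m,
                               rgbBaselineSpec(rMin = 120, dMin = 40,
                                               rMax = 0.6))
  expect_equal(bloodRatio(red), 1)
  expect_equal(bleedingScore(red), 10)

  gray <- scoreFrameRgbBaseline(uniformFrame(c(128, 128, 128)), m)
  expect_equal(bloodRatio(gray), 0)
  expect_equal(bleedingScore(gray), 1)
})

test_that("the jump rule resamples and flags abrupt clips", {
  fr <- uniformFrame(c(170, 30, 40))   # scores 10 under strictRedSpec
  clip <- clipOfSeconds(rep(list(fr), 3), fps = 6)
  m <- fullMask()

  ## prev within the bound: accepted in round 1
  ok <- scoreClip(clip, strictRedSpec(), prevScore = 7, mask = m, seed = 1)
  expect_equal(resampleRounds(ok), 1L)
  expect_false(isFlagged(ok))
  expect_equal(ok@jump, 3)  # difference of exactly 3 is accepted

  ## every round scores 10 vs prev 2: exactly maxRetries resampling rounds,
  ## then the minimum-jump round is returned flagged
  bad <- scoreClip(clip, strictRedSpec(), prevScore = 2, mask = m, seed = 1,
                   maxRetries = 5)
  expect_equal(resampleRounds(bad), 6L)  # 1 initial + 5 resampling rounds
  expect_true(isFlagged(bad))
  expect_equal(bleedingScore(bad), 10)

  ## virtual duplication: identical frames give identical halves, round 1
  vd <- scoreClip(clip, strictRedSpec(), seed = 3)
  expect_equal(vd@prevClipScore, bleedingScore(vd))
  expect_equal(resampleRounds(vd), 1L)
})

test_that("clip scoring is bit-reproducible under a seed", {
  g <- generateClip(syntheticSpec(width = 32L, height = 32L,
                                  bloodTransparency = 0.45, seed = 21),
                    seconds = 2, fps = 6)
  a <- scoreClip(g$clip, knownSpec(), seed = 99)
  b <- scoreClip(g$clip, knownSpec(), seed = 99)
  expect_identical(bleedingScore(a), bleedingScore(b))
  expect_identical(lapply(secondScores(a), sampledFrames),
                   lapply(secondScores(b), sampledFrames))
})

test_that("scores stay in [1, 10] and ignore pixels outside the mask", {
  set.seed(8)
  m <- fullMask(20L, 20L)
  for (i in 1:5) {
    px <- array(sample.int(256, 20 * 20 * 3, TRUE) - 1L, c(20L, 20L, 3L))
    sp <- thresholdSpec(sMin = runif(1, 0, 0.5), aMin = runif(1, -5, 25),
                        rMax = runif(1, 0.1, 1))
    s <- scoreFrame(frameImage(px), m, sp)
    expect_gte(bleedingScore(s), 1); expect_lte(bleedingScore(s), 10)
  }

  fr <- generateFrame(syntheticSpec(width = 48L, height = 48L,
                                    bloodTransparency = 0.3, seed = 14))
  mask <- detectFieldMask(fr$frame)
  s1 <- scoreFrame(fr$frame, mask, knownSpec())
  px <- fr$frame@pixels
  for (ch in 1:3) {  # paint the border bright red
    plane <- px[, , ch]
    plane[!mask@inside] <- c(255L, 0L, 0L)[ch]
    px[, , ch] <- plane
  }
  s2 <- scoreFrame(frameImage(px), mask, knownSpec())
  expect_identical(bleedingScore(s1), bleedingScore(s2))
})

test_that("procedures chain clips, honour phases and summarise totals", {
  ## staircase frames with exact scores 1..6 under the red-dominance
  ## baseline on a borderless 30x30 frame (900 field pixels)
  ks <- (0:5) * 100
  frames <- lapply(ks, stairFrame)
  proc <- clipOfSeconds(frames, fps = 6)
  sp <- rgbBaselineSpec(rMin = 200, dMin = 50, rMax = 1)
  phases <- data.frame(name = c("A", "B"), start = c(0, 3), end = c(3, 6))
  rep <- scoreProcedure(proc, sp, phases = phases, seed = 2)
  expect_equal(scoreTimeline(rep), 1 + 9 * ks / 900)
  expect_equal(totalBleedingScore(rep), 3.5)
  expect_equal(phaseScores(rep)$meanScore, c(2, 5))

  ## constant timeline
  const <- scoreProcedure(clipOfSeconds(rep(list(stairFrame(100)), 4),
                                        fps = 6), sp, seed = 1)
  expect_equal(totalBleedingScore(const), 2)

  expect_error(scoreProcedure(proc, sp, seed = 1,
                              phases = data.frame(name = "X", start = 0,
                                                  end = 9)),
               "phase")
  expect_error(scoreProcedure(proc, sp, seed = 1,
                              phases = data.frame(name = c("X", "Y"),
                                                  start = c(0, 2),
                                                  end = c(3, 5))),
               "overlap")
})

test_that("concatenating one clip reproduces its score", {
  g <- generateClip(syntheticSpec(width = 32L, height = 32L,
                                  bloodTransparency = 0.5, seed = 17),
                    seconds = 3, fps = 6)
  k <- 4L
  secs <- rep(g$clip@seconds, k)
  proc <- new("ClipFrames", seconds = secs, fps = 6L, durationS = 3L * k)
  single <- scoreClip(g$clip, knownSpec(), seed = 11)
  rep <- scoreProcedure(proc, knownSpec(), clipSeeds = rep(11L, k))
  expect_equal(totalBleedingScore(rep), bleedingScore(single),
               tolerance = 1e-12)
})

test_that("the per-second temporal mode produces a bounded timeline", {
  g <- generateClip(syntheticSpec(width = 32L, height = 32L,
                                  bloodTransparency = 0.4, seed = 23),
                    seconds = 4, fps = 6)
  rep <- scoreProcedure(g$clip, knownSpec(), seed = 5,
                        temporalMode = "second")
  expect_length(scoreTimeline(rep), 4L)
  expect_true(all(scoreTimeline(rep) >= 1 & scoreTimeline(rep) <= 10))
})
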