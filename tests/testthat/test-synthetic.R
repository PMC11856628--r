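test_that("transparency maps linearly to the true score", {
  expect_identical(transparencyToScore(0.9), 1)
  expect_identical(transparencyToScore(0.1), 9)
  expect_identical(transparencyToScore(0.5), 5)
  expect_identical(transparencyToScore(1), 1)   # clamped floor
  expect_identical(transparencyToScore(0), 10)
  expect_error(transparencyToScore(1.2), "transparency")
})

test_that("compositing follows the closed-form alpha blend exactly", {
  sp <- syntheticSpec(width = 32L, height = 32L, bloodTransparency = 0.37,
                      seed = 8)
  fr <- generateFrame(sp)
  base <- ArthroScore:::.renderBase(sp)
  a <- 1 - 0.37
  for (ch in 1:3) {
    expected <- (1 - a) * base$bg[, , ch] + a * sp@bloodColor[ch] / 255
    expected[!base$inside] <- 0
    expect_identical(fr$frame@pixels[, , ch],
                     matrix(as.integer(round(expected * 255)), 32L, 32L))
  }

  ## invisible overlay equals the clean background; opaque overlay equals
  ## the overlay colour inside the field
  f1 <- generateFrame(syntheticSpec(width = 32L, height = 32L,
                                    bloodTransparency = 1, seed = 8))
  f0 <- generateFrame(syntheticSpec(width = 32L, height = 32L,
                                    bloodPattern = "none", seed = 8))
  expect_identical(f1$frame@pixels, f0$frame@pixels)

  fo <- generateFrame(syntheticSpec(width = 32L, height = 32L,
                                    bloodTransparency = 0, seed = 8))
  inside <- fo$truth@maskTruth
  for (ch in 1:3)
    expect_true(all(fo$frame@pixels[, , ch][inside] ==
                    as.integer(round(syntheticSpec()@bloodColor[ch]))))
})

test_that("generation is deterministic in the seed", {
  a <- generateFrame(syntheticSpec(width = 32L, height = 32L, seed = 77))
  b <- generateFrame(syntheticSpec(width = 32L, height = 32L, seed = 77))
  expect_identical(a$frame@pixels, b$frame@pixels)
})

test_that("clips carry the declared geometry and per-second truth", {
  g <- generateClip(syntheticSpec(width = 32L, height = 32L,
                                  bloodTransparency = 0.4, seed = 2),
                    seconds = 3, fps = 24)
  expect_equal(frameCount(g$clip), 72L)
  expect_equal(nrow(g$truth), 3L)
  expect_true(all(g$truth$trueScore == 6))

  ## schedule drives per-second truth
  g2 <- generateClip(syntheticSpec(width = 32L, height = 32L, seed = 2),
                     seconds = 3, fps = 3, schedule = c(0.9, 0.5, 0.1))
  expect_equal(g2$truth$trueScore, c(1, 5, 9))

  ## an artifact frame leaves the ground truth untouched
  art <- syntheticSpec(width = 32L, height = 32L, bloodTransparency = 0.8,
                       seed = 2,
                       artifact = list(frames = 4L, centerFrac = c(0.5, 0.5),
                                       radiusFrac = 0.2, alpha = 0.95))
  g3 <- generateClip(art, seconds = 3, fps = 3)
  expect_equal(g3$truth$trueScore, rep(2, 3))
  expect_false(identical(g3$clip@seconds[[2]][[2]]@pixels,
                         g3$clip@seconds[[2]][[1]]@pixels))

  ## generator mask is exactly its declared disk
  expect_identical(g$mask@inside, generateFrame(
    syntheticSpec(width = 32L, height = 32L, seed = 2))$truth@maskTruth)
})

test_that("ground truth is monotone in opacity", {
  t <- seq(0, 1, by = 0.05)
  s <- transparencyToScore(t)
  expect_true(all(diff(s) <= 0))  # more transparency, never more bleeding
})

test_that("validation sets are labelled, complete and reproducible", {
  vs <- generateValidationSet(2, levels = 1:10, seed = 31, width = 32L,
                              height = 32L, fps = 3)
  expect_equal(nrow(vs@manifest), 20L)
  expect_equal(as.vector(table(vs@manifest$level)), rep(2L, 10))
  expect_equal(vs@manifest$true_score,
               transparencyToScore(vs@manifest$transparency))

  vs2 <- generateValidationSet(2, levels = 1:10, seed = 31, width = 32L,
                               height = 32L, fps = 3)
  expect_identical(vs@manifest, vs2@manifest)

  one <- generateValidationSet(1, levels = 1, seed = 5, width = 32L,
                               height = 32L, fps = 3)
  expect_equal(nrow(one@manifest), 1L)
  expect_equal(one@manifest$true_score, 1)

  ## written sets round-trip through the reader
  d <- file.path(tempdir(), "synth-vs")
  unlink(d, recursive = TRUE)
  generateValidationSet(1, levels = c(2, 8), seed = 6, width = 32L,
                        height = 32L, fps = 3, dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  clip <- readClip(file.path(d, "clip_001"), fpsOverride = 3)
  expect_equal(clipDuration(clip), 3L)
})
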