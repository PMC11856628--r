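test_that("HSV conversion matches the hexcone definition on key colours", {
  f <- uniformFrame(c(255, 0, 0))
  h <- rgbToHsv(f)
  expect_equal(h$hue[1, 1], 0)
  expect_equal(h$sat[1, 1], 1)
  expect_equal(h$val[1, 1], 1)

  g <- rgbToHsv(uniformFrame(c(128, 128, 128)))
  expect_equal(g$sat[1, 1], 0)
  expect_equal(g$val[1, 1], 128 / 255)
  expect_equal(g$hue[1, 1], 0)  # achromatic convention

  ## independent closed form for (200, 30, 60): R max, delta = 170
  x <- rgbToHsv(uniformFrame(c(200, 30, 60)))
  expect_equal(x$hue[1, 1], (60 * (30 - 60) / 170 + 360), tolerance = 1e-6)
  expect_equal(x$sat[1, 1], 170 / 200, tolerance = 1e-6)
  expect_equal(x$val[1, 1], 200 / 255, tolerance = 1e-6)
})

test_that("CIELAB conversion reproduces reference values (sRGB, D65)", {
  w <- rgbToLab(uniformFrame(c(255, 255, 255)))
  expect_equal(w$lstar[1, 1], 100, tolerance = 1e-4)
  expect_lt(abs(w$astar[1, 1]), 0.01)
  expect_lt(abs(w$bstar[1, 1]), 0.01)

  k <- rgbToLab(uniformFrame(c(0, 0, 0)))
  expect_equal(k$lstar[1, 1], 0)

  ## frozen independent reference conversions (scikit-image rgb2lab)
  r <- rgbToLab(uniformFrame(c(255, 0, 0)))
  expect_equal(r$lstar[1, 1], 53.240588, tolerance = 0.01)
  expect_equal(r$astar[1, 1], 80.092308, tolerance = 0.01)
  expect_equal(r$bstar[1, 1], 67.202751, tolerance = 0.01)

  x <- rgbToLab(uniformFrame(c(200, 30, 60)))
  expect_equal(x$lstar[1, 1], 43.563032, tolerance = 0.01)
  expect_equal(x$astar[1, 1], 64.057043, tolerance = 0.01)
  expect_equal(x$bstar[1, 1], 28.472346, tolerance = 0.01)
})

test_that("HSV round-trips to RGB within one quantisation step", {
  set.seed(11)
  px <- array(sample.int(256, 20 * 20 * 3, replace = TRUE) - 1L,
              c(20L, 20L, 3L))
  f <- frameImage(px)
  h <- rgbToHsv(f)
  ## analytic HSV -> RGB inversion
  hh <- h$hue / 60
  c <- h$val * h$sat
  xx <- c * (1 - abs(hh %% 2 - 1))
  m <- h$val - c
  idx <- floor(hh) %% 6
  r1 <- ifelse(idx == 0 | idx == 5, c, ifelse(idx == 1 | idx == 4, xx, 0))
  g1 <- ifelse(idx == 1 | idx == 2, c, ifelse(idx == 0 | idx == 3, xx, 0))
  b1 <- ifelse(idx == 3 | idx == 4, c, ifelse(idx == 2 | idx == 5, xx, 0))
  back <- round(255 * (array(c(r1, g1, b1), dim(px)) + rep(m, 3)))
  expect_lte(max(abs(back - px)), 1)
})

test_that("channel ranges are respected on random frames", {
  set.seed(4)
  for (i in 1:5) {
    f <- frameImage(array(sample.int(256, 18 * 18 * 3, TRUE) - 1L,
                          c(18L, 18L, 3L)))
    h <- rgbToHsv(f); lab <- rgbToLab(f)
    expect_true(all(h$hue >= 0 & h$hue < 360))
    expect_true(all(h$sat >= 0 & h$sat <= 1))
    expect_true(all(h$val >= 0 & h$val <= 1))
    expect_true(all(lab$lstar >= 0 & lab$lstar <= 100 + 1e-9))
  }
})

test_that("masked means match a per-pixel loop and ignore outside pixels", {
  set.seed(21)
  px <- array(sample.int(256, 24 * 24 * 3, TRUE) - 1L, c(24L, 24L, 3L))
  f <- frameImage(px)
  inside <- matrix(runif(24 * 24) > 0.4, 24, 24)
  mask <- new("FieldMask", inside = inside, coverage = mean(inside))
  feat <- extractFeatures(f, mask)

  ## brute-force loop average
  h <- rgbToHsv(f); lab <- rgbToLab(f)
  accS <- 0; accA <- 0; n <- 0
  for (i in 1:24) for (j in 1:24) if (inside[i, j]) {
    accS <- accS + h$sat[i, j]; accA <- accA + lab$astar[i, j]; n <- n + 1
  }
  expect_equal(feat@meanS, accS / n, tolerance = 1e-9)
  expect_equal(feat@meanA, accA / n, tolerance = 1e-9)

  ## scrambling pixels outside the mask must not change the means
  px2 <- px
  for (ch in 1:3) {
    plane <- px2[, , ch]
    plane[!inside] <- 255L - plane[!inside]
    px2[, , ch] <- plane
  }
  feat2 <- extractFeatures(frameImage(px2), mask)
  expect_identical(feat@meanS, feat2@meanS)
  expect_identical(feat@meanA, feat2@meanA)
})

test_that("uniform and two-value frames give exact feature means", {
  f <- uniformFrame(c(200, 30, 60))
  feat <- extractFeatures(f, fullMask())
  expect_equal(feat@meanS, 170 / 200, tolerance = 1e-9)

  ## half red / half gray: mean a* is the average of the two pixel values
  h <- 24L; w <- 24L
  px <- array(0L, c(h, w, 3L))
  px[, 1:12, ] <- rep(c(255L, 0L, 0L), each = h * 12)
  px[, 13:24, ] <- rep(c(128L, 128L, 128L), each = h * 12)
  feat2 <- extractFeatures(frameImage(px), fullMask(h, w))
  aRed <- rgbToLab(uniformFrame(c(255, 0, 0)))$astar[1, 1]
  aGray <- rgbToLab(uniformFrame(c(128, 128, 128)))$astar[1, 1]
  expect_equal(feat2@meanA, (aRed + aGray) / 2, tolerance = 1e-9)
})
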