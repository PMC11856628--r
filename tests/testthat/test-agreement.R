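test_that("MAE matches hand arithmetic and a loop oracle", {
  expect_equal(maeScore(c(1, 5, 8), c(1, 5, 8)), c(mean = 0, sd = 0))
  expect_equal(maeScore(c(1, 2), c(2, 4))[["mean"]], 1.5)
  expect_error(maeScore(1:3, 1:4), "length")

  set.seed(2)
  a <- runif(1000, 1, 10); b <- runif(1000, 1, 10)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(maeScore(a, b)[["mean"]], acc / 1000, tolerance = 1e-12)
  expect_identical(maeScore(a, b), maeScore(b, a))
})

test_that("the Shapiro-Wilk gate rejects uniform scores and keeps its level", {
  set.seed(7)
  u <- runif(500, 1, 10)
  gate <- shapiroWilkGate(u)
  expect_false(gate$normal)  # SW has essentially full power vs uniform here

  ## type-I calibration: rejection rate of true normals stays near alpha
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    !shapiroWilkGate(rnorm(500))$normal
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)

  expect_error(shapiroWilkGate(c(1, 2)), "between 3 and 5000")
  expect_error(shapiroWilkGate(rep(4, 10)), "constant")
})

test_that("ICC estimators agree with an independent ANOVA oracle", {
  m <- fixedRatings()
  o <- oracleIccA(m)
  a1 <- iccAgreement(m, unit = "single")
  ak <- iccAgreement(m, unit = "meanOfK")
  expect_equal(iccEstimate(a1), o$a1, tolerance = 1e-9)
  expect_equal(iccEstimate(ak), o$ak, tolerance = 1e-9)

  ## externally verified values for the same matrix (pingouin 0.6.1)
  expect_equal(iccEstimate(a1), 0.932249322493, tolerance = 1e-9)
  expect_equal(iccEstimate(ak), 0.976348155156, tolerance = 1e-9)

  ## confidence bounds bracket the estimate at the requested level
  ci <- iccConfint(a1)
  expect_lt(ci[1], iccEstimate(a1)); expect_gt(ci[2], iccEstimate(a1))

  ## the mixed model records metadata, same agreement arithmetic
  mx <- iccAgreement(m, model = "twoWayMixed", unit = "single")
  expect_equal(iccEstimate(mx), iccEstimate(a1))
  expect_equal(mx@model, "twoWayMixed")
})

test_that("ICC hits the degenerate and invariance cases", {
  ## raters identical to each other: perfect agreement
  m <- cbind(c(2, 5, 7, 3, 9, 4), c(2, 5, 7, 3, 9, 4), c(2, 5, 7, 3, 9, 4))
  expect_equal(iccEstimate(iccAgreement(m, unit = "single")), 1)
  expect_equal(iccEstimate(iccAgreement(m, unit = "meanOfK")), 1)

  set.seed(12)
  base <- matrix(runif(30, 1, 10), 10, 3)
  ## mean-of-k at least single when agreement is positive (Spearman-Brown)
  a1 <- iccEstimate(iccAgreement(base, unit = "single"))
  ak <- iccEstimate(iccAgreement(base, unit = "meanOfK"))
  if (a1 > 0) expect_gte(ak, a1)
  ## location invariance
  expect_equal(iccEstimate(iccAgreement(base + 2.5, unit = "single")), a1,
               tolerance = 1e-12)
  expect_equal(iccEstimate(iccAgreement(base + 2.5, unit = "meanOfK")), ak,
               tolerance = 1e-12)

  expect_error(iccAgreement(rbind(c(1, NA), c(2, 3))), "complete|missing")
})

test_that("subgroup analysis partitions subjects and recomposes the MAE", {
  set.seed(9)
  rater <- runif(60, 1, 10)
  system <- pmin(pmax(rater + rnorm(60, 0, 0.7), 1), 10)
  tab <- subgroupAnalysis(rater, system)
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$n), 60L)

  ## bin-weighted MAEs recompose the global MAE
  keep <- tab$n > 0
  expect_equal(sum(tab$mae[keep] * tab$n[keep]) / 60,
               maeScore(rater, system)[["mean"]], tolerance = 1e-12)

  ## a single all-covering interval reproduces the global MAE
  one <- subgroupAnalysis(rater, system, breaks = c(-Inf, Inf))
  expect_equal(one$mae[1], maeScore(rater, system)[["mean"]],
               tolerance = 1e-12)
  expect_equal(one$n[1], 60L)

  expect_error(subgroupAnalysis(numeric(0), numeric(0)), "empty")
})

test_that("long-format ratings CSVs load as complete matrices by session", {
  d <- expand.grid(subject_id = sprintf("v%02d", 1:6), rater_id = c("r1", "r2"),
                   session = 1:2)
  set.seed(3)
  d$score <- round(runif(nrow(d), 1, 10), 1)
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  sessions <- readRatingsCsv(f)
  expect_length(sessions, 2L)
  expect_equal(dim(sessions[[1]]@scores), c(6L, 2L))
  expect_equal(sessions[[1]]@scores["v03", "r2"],
               d$score[d$subject_id == "v03" & d$rater_id == "r2" &
                       d$session == 1])
})
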