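## Validation statistics: MAE +/- SD, Shapiro-Wilk normality gate,
## ANOVA-based intraclass correlation (absolute agreement, single and
## mean-of-k units) and the score-subgroup table.

#' Mean absolute error between two score vectors
#'
#' @param a,b equal-length numeric vectors.
#' @return named numeric \code{c(mean, sd)} of the elementwise absolute
#'   differences (sample SD; 0 for length 1).
#' @examples
#' maeScore(c(1, 2), c(2, 4))
#' @export
maeScore <- function(a, b) {
  if (length(a) != length(b)) .stopf("score vectors differ in length")
  if (!length(a)) .stopf("empty score vectors")
  d <- abs(a - b)
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test (AS R94, via \code{stats::shapiro.test}) and
#' returns the decision that drives the choice of agreement method; scores
#' that fail the gate are analysed with ICC, the distribution-free route.
#'
#' @param x numeric vector, \code{3 <= length(x) <= 5000}.
#' @param alpha test level.
#' @return list with \code{statistic} (W), \code{p} and \code{normal}
#'   (\code{TRUE} when normality is not rejected at \code{alpha}).
#' @export
shapiroWilkGate <- function(x, alpha = 0.05) {
  if (length(x) < 3L || length(x) > 5000L)
    .stopf("Shapiro-Wilk needs between 3 and 5000 observations")
  if (stats::sd(x) == 0) .stopf("degenerate input: constant score vector")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha)
}

#' Construct a RatingMatrix
#'
#' @param scores numeric \code{n x k} matrix (subjects by raters), complete.
#' @param subjectIds,raterIds optional identifiers.
#' @return a \linkS4class{RatingMatrix}.
#' @export
ratingMatrix <- function(scores, subjectIds = NULL, raterIds = NULL) {
  scores <- as.matrix(scores)
  if (is.null(subjectIds))
    subjectIds <- rownames(scores) %||% sprintf("s%03d", seq_len(nrow(scores)))
  if (is.null(raterIds))
    raterIds <- colnames(scores) %||% sprintf("r%d", seq_len(ncol(scores)))
  new("RatingMatrix", scores = scores, subjectIds = as.character(subjectIds),
      raterIds = as.character(raterIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Two-way (subjects x raters) ANOVA mean squares.
.anovaMS <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation with absolute agreement
#'
#' ANOVA-based ICC estimators in the McGraw-Wong absolute-agreement form:
#' single-rater \code{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' (k/n)(MSC - MSE))} and mean-of-k \code{ICC(A,k) = (MSR - MSE) /
#' (MSR + (MSC - MSE)/n)}, with F-based confidence intervals. The two-way
#' mixed model uses the same arithmetic; the model choice records whether
#' raters are regarded as a random sample or as the fixed panel of interest.
#'
#' @param x a \linkS4class{RatingMatrix} or a complete numeric matrix
#'   (subjects in rows, raters in columns).
#' @param model "twoWayRandom" or "twoWayMixed".
#' @param unit "single" or "meanOfK".
#' @param conf confidence level for the interval.
#' @return an \linkS4class{ICCResult}.
#' @examples
#' m <- cbind(a = c(7, 1, 5, 3, 9, 4), b = c(9, 2, 6, 2, 8.5, 5))
#' iccAgreement(m, unit = "meanOfK")
#' @export
iccAgreement <- function(x, model = c("twoWayRandom", "twoWayMixed"),
                         unit = c("single", "meanOfK"), conf = 0.95) {
  model <- match.arg(model); unit <- match.arg(unit)
  m <- if (is(x, "RatingMatrix")) x@scores else as.matrix(x)
  if (anyNA(m)) .stopf("missing cells: the design must be complete")
  if (nrow(m) < 2L || ncol(m) < 2L)
    .stopf("ICC needs at least 2 subjects and 2 raters")
  if (nrow(m) < 5L)
    warning("fewer than 5 subjects: confidence bounds are unreliable")
  ms <- .anovaMS(m)
  n <- ms$n; k <- ms$k
  den1 <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  denK <- ms$msr + (ms$msc - ms$mse) / n
  est1 <- if (den1 == 0) NA_real_ else (ms$msr - ms$mse) / den1
  estK <- if (denK == 0) NA_real_ else (ms$msr - ms$mse) / denK
  est <- if (unit == "single") est1 else estK

  alpha <- 1 - conf
  ci <- c(NA_real_, NA_real_)
  if (!is.na(est1) && ms$mse > 0) {
    ## McGraw-Wong F-based interval for ICC(A,1); Satterthwaite df.
    r <- est1
    Fj <- ms$msc / ms$mse
    vn <- (k - 1) * (n - 1) *
      (k * r * Fj + n * (1 + (k - 1) * r) - k * r)^2
    vd <- (n - 1) * k^2 * r^2 * Fj^2 +
      (n * (1 + (k - 1) * r) - k * r)^2
    v <- vn / vd
    fU <- stats::qf(1 - alpha / 2, n - 1, v)
    fL <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (ms$msr - fU * ms$mse) /
      (fU * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    u1 <- n * (fL * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fL * ms$msr)
    ci <- if (unit == "single") c(l1, u1)
      else c(l1 * k / (1 + (k - 1) * l1), u1 * k / (1 + (k - 1) * u1))
  } else if (!is.na(est) && ms$mse == 0) {
    ci <- c(est, est)  # perfect agreement: degenerate interval
  }
  new("ICCResult", estimate = est, ciLow = min(ci, est, na.rm = FALSE),
      ciHigh = ci[2], model = model, unit = unit, k = as.integer(k),
      n = as.integer(n), conf = conf, msr = ms$msr, msc = ms$msc,
      mse = ms$mse)
}

.subgroupBreaks <- c(-Inf, seq(1.5, 9.5, by = 1), Inf)

.subgroupLabels <- function(breaks) {
  nb <- length(breaks)
  if (nb == 2L) return("all")
  c(sprintf("s < %.1f", breaks[2]),
    if (nb > 3) sprintf("%.1f <= s < %.1f", breaks[2:(nb - 2)],
                        breaks[3:(nb - 1)]),
    sprintf("%.1f <= s", breaks[nb - 1]))
}

#' Score-subgroup error and agreement table
#'
#' Bins subjects by the rater-average score into the standard ten intervals
#' (\code{s < 1.5}, \code{1.5 <= s < 2.5}, ..., \code{9.5 <= s}) and reports
#' per-bin system mean +/- SD, absolute error mean +/- SD and the mean-of-2
#' absolute-agreement ICC between rater average and system. Bins with fewer
#' than 3 subjects are flagged unstable; sparse subgroups produce erratic
#' ICCs.
#'
#' @param raterAvg rater-average score per subject.
#' @param system system score per subject.
#' @param breaks bin edges partitioning the score range.
#' @return data.frame with one row per bin: interval, n, rater_mean,
#'   system_mean, system_sd, mae, mae_sd, icc, unstable.
#' @export
subgroupAnalysis <- function(raterAvg, system, breaks = .subgroupBreaks) {
  if (length(raterAvg) != length(system)) .stopf("length mismatch")
  if (!length(raterAvg)) .stopf("empty input")
  bins <- cut(raterAvg, breaks = breaks, right = FALSE,
              labels = .subgroupLabels(breaks))
  out <- lapply(levels(bins), function(lv) {
    sel <- bins == lv
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(interval = lv, n = 0L, rater_mean = NA_real_,
                        system_mean = NA_real_, system_sd = NA_real_,
                        mae = NA_real_, mae_sd = NA_real_, icc = NA_real_,
                        unstable = TRUE, stringsAsFactors = FALSE))
    m <- maeScore(raterAvg[sel], system[sel])
    icc <- if (n >= 2L) {
      est <- suppressWarnings(
        tryCatch(iccAgreement(cbind(raterAvg[sel], system[sel]),
                              unit = "meanOfK")@estimate,
                 error = function(e) NA_real_))
      est
    } else NA_real_
    data.frame(interval = lv, n = n, rater_mean = mean(raterAvg[sel]),
               system_mean = mean(system[sel]),
               system_sd = if (n > 1L) stats::sd(system[sel]) else 0,
               mae = m[["mean"]], mae_sd = m[["sd"]], icc = icc,
               unstable = n < 3L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a long-format ratings CSV into rating matrices
#'
#' Expects columns \code{subject_id}, \code{rater_id}, \code{score} and
#' optionally \code{session}; returns one \linkS4class{RatingMatrix} per
#' session (a single unnamed session when the column is absent).
#'
#' @param path CSV file.
#' @return named list of \linkS4class{RatingMatrix}.
#' @export
readRatingsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "rater_id", "score")
  if (!all(need %in% names(d)))
    .stopf("ratings CSV needs columns subject_id, rater_id, score")
  if (!"session" %in% names(d)) d$session <- 1L
  lapply(split(d, d$session), function(ds) {
    m <- stats::xtabs(score ~ subject_id + rater_id, data = ds)
    cnt <- stats::xtabs(~ subject_id + rater_id, data = ds)
    if (any(cnt != 1L)) .stopf("ratings must form a complete design")
    ratingMatrix(matrix(as.numeric(m), nrow(m), ncol(m),
                        dimnames = dimnames(m)),
                 subjectIds = rownames(m), raterIds = colnames(m))
  })
}
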