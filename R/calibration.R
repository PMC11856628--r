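## Threshold calibration: the published scoring constants are not public, so
## usable ThresholdSpec values are re-derived by explicit optimisation --
## coarse grid search followed by coordinate descent minimising the mean
## absolute error against labelled clips.

## ---------------------------------------------------------------------------
## Feature cache
##
## Calibration evaluates hundreds of candidate parameter points; colour
## features are therefore extracted once per second (the first frame stands
## for its second -- exact for the homogeneous synthetic clips the objective
## is defined on) on a fixed random subsample of masked pixels, and every
## candidate is scored as pure vector arithmetic on the cache.
## ---------------------------------------------------------------------------

.buildCache <- function(realize, nClips, secondsPerClip, maxPixels, seed) {
  cols <- nClips * secondsPerClip
  H <- S <- V <- A <- L <- R <- D <- matrix(0, maxPixels, cols)
  meanS <- meanA <- numeric(cols)
  nReal <- integer(cols)
  secClip <- integer(cols)
  col <- 0L
  for (i in seq_len(nClips)) {
    g <- realize(i)
    ## same mask path as the scoring pipeline (static first-frame mask), so
    ## calibration optimises exactly what scoreClip() will compute
    inside <- detectFieldMask(g$clip@seconds[[1L]][[1L]])@inside
    pool <- which(inside)
    ## Whole field when it fits the budget (the objective is then exact);
    ## otherwise a fixed random subsample.
    idx <- if (length(pool) <= maxPixels) pool
      else withr::with_seed(.childSeed(seed, i), sample(pool, maxPixels))
    n <- length(idx)
    pad <- maxPixels - n
    for (s in seq_len(secondsPerClip)) {
      col <- col + 1L
      px <- g$clip@seconds[[s]][[1L]]@pixels
      r <- px[, , 1][idx]; gg <- px[, , 2][idx]; b <- px[, , 3][idx]
      hsv <- grDevices::rgb2hsv(r = r, g = gg, b = b, maxColorValue = 255)
      lab <- .srgbMatrixToLab(cbind(r, gg, b) / 255)
      hh <- hsv[1L, ] * 360; hh[hh >= 360] <- 0
      ## sentinel padding can never satisfy any predicate; denominators use
      ## the real pixel count, so short columns stay exact
      H[, col] <- c(hh, rep(180, pad))
      S[, col] <- c(hsv[2L, ], rep(-1, pad))
      V[, col] <- c(hsv[3L, ], rep(-1, pad))
      A[, col] <- c(lab[, 2], rep(-1e6, pad))
      L[, col] <- c(lab[, 1], rep(1e6, pad))
      R[, col] <- c(r, rep(-1, pad))
      D[, col] <- c(r - pmax(gg, b), rep(-1e6, pad))
      meanS[col] <- mean(hsv[2L, ]); meanA[col] <- mean(lab[, 2])
      nReal[col] <- n
      secClip[col] <- i
    }
  }
  list(H = H, S = S, V = V, A = A, L = L, R = R, D = D,
       meanS = meanS, meanA = meanA, nReal = nReal, secClip = secClip,
       secondsPerClip = secondsPerClip, nPix = maxPixels)
}

## Predicted clip scores for a candidate spec on (a subset of clips in) the
## cache; mirrors classifyBloodPixels()/ratioToScore() exactly.
.cacheClipScores <- function(cache, spec, clipIdx) {
  keep <- cache$secClip %in% clipIdx
  nPix <- cache$nPix
  if (is(spec, "ThresholdSpec")) {
    H <- cache$H[, keep, drop = FALSE]
    sCut <- .clamp(spec@sMin + spec@gammaS * (cache$meanS[keep] - spec@sRef),
                   0, 1)
    aCut <- spec@aMin + spec@gammaA * (cache$meanA[keep] - spec@aRef)
    hueIn <- if (spec@hueLo <= spec@hueHi)
      H >= spec@hueLo & H <= spec@hueHi
    else H >= spec@hueLo | H <= spec@hueHi
    flags <- hueIn &
      cache$S[, keep, drop = FALSE] >=
        matrix(sCut, nPix, sum(keep), byrow = TRUE) &
      cache$V[, keep, drop = FALSE] >= spec@vMin &
      cache$A[, keep, drop = FALSE] >=
        matrix(aCut, nPix, sum(keep), byrow = TRUE) &
      cache$L[, keep, drop = FALSE] <= spec@lMax
  } else {
    flags <- cache$R[, keep, drop = FALSE] >= spec@rMin &
      cache$D[, keep, drop = FALSE] >= spec@dMin
  }
  secScore <- ratioToScore(colSums(flags) / cache$nReal[keep], spec@rMax)
  grp <- cache$secClip[keep]
  as.vector(rowsum(secScore, grp)) / cache$secondsPerClip
}

.specWith <- function(spec, name, value) {
  slot(spec, name) <- value
  spec
}

.paramTable <- function(mode) {
  if (mode == "hsvlab")
    data.frame(
      name  = c("rMax", "hueLo", "hueHi", "sMin", "vMin", "aMin",
                "gammaS", "gammaA"),
      lo    = c(0.02, 290,   5,    0,    0,    -5,   0,    0),
      hi    = c(1.00, 359.9, 80,   1,    0.6,  40,   2,    2),
      step  = c(0.10, 8,     8,    0.05, 0.05, 3,    0.15, 0.15),
      stringsAsFactors = FALSE)
  else
    data.frame(
      name = c("rMax", "rMin", "dMin"),
      lo   = c(0.02, 60, 0), hi = c(1.00, 230, 100),
      step = c(0.10, 12, 8), stringsAsFactors = FALSE)
}

.coarseGrid <- function(mode, start) {
  if (mode == "hsvlab") {
    g <- expand.grid(rMax = c(0.15, 0.3, 0.5, 0.75, 1.0),
                     aMin = c(0, 6, 12, 20),
                     gammaA = c(0, 0.5, 0.8, 0.92, 0.97),
                     gammaS = c(0, 0.5),
                     sMin = c(0.1, 0.25, 0.4),
                     hueHi = c(15, 30, 45))
  } else {
    g <- expand.grid(rMax = c(0.15, 0.3, 0.5, 0.75, 1.0),
                     rMin = c(90, 120, 150, 180),
                     dMin = c(5, 20, 40, 65))
  }
  lapply(seq_len(nrow(g)), function(i) {
    sp <- start
    for (nm in names(g)) sp <- .specWith(sp, nm, g[i, nm])
    sp
  })
}

#' Fit threshold constants to labelled clips
#'
#' Minimises the mean absolute error between predicted clip scores and labels
#' over the parameters of the blood-pixel predicate: a coarse grid over the
#' dominant parameters (score ceiling \code{rMax}, base a* cut and mean
#' couplings for the full model; red-dominance cuts for the RGB baseline)
#' followed by cyclic coordinate descent with shrinking steps. The search is
#' deterministic given \code{seed}; every evaluated point is recorded in the
#' trace and the running best loss never increases.
#'
#' A random \code{holdoutFrac} of the clips is excluded from fitting; the
#' fitted specification is then evaluated on them with the full scoring
#' pipeline ([scoreClip()] with virtual duplication), giving an honest
#' held-out MAE.
#'
#' @param x a \linkS4class{ValidationSet}, or a list of clip bundles as
#'   returned by [generateClip()] (then \code{labels} is required).
#' @param labels true scores, one per clip; defaults to the validation-set
#'   manifest labels.
#' @param mode "hsvlab" (full model) or "rgb" (ablation baseline).
#' @param holdoutFrac fraction of clips held out, in \code{(0, 0.5]}.
#' @param seed seed for the holdout split, pixel subsampling and holdout
#'   scoring.
#' @param start starting specification; defaults to [thresholdSpec()] /
#'   [rgbBaselineSpec()].
#' @param coarse run the coarse grid stage before descent.
#' @param sweeps coordinate-descent sweeps (0 returns the best coarse point).
#' @param maxPixels masked pixels subsampled per frame for the objective.
#' @return a \linkS4class{CalibrationResult}.
#' @examples
#' \donttest{
#' vs <- generateValidationSet(2, levels = c(1, 4, 7, 10), seed = 11,
#'                             width = 64, height = 64, fps = 3)
#' fit <- fitThresholds(vs, sweeps = 2, maxPixels = 500)
#' holdoutMae(fit)
#' }
#' @export
fitThresholds <- function(x, labels = NULL, mode = c("hsvlab", "rgb"),
                          holdoutFrac = 0.3, seed = 1L, start = NULL,
                          coarse = TRUE, sweeps = 6L, maxPixels = 2500L) {
  mode <- match.arg(mode)
  if (is(x, "ValidationSet")) {
    nClips <- nrow(x@manifest)
    if (is.null(labels)) labels <- x@manifest$true_score
    secondsPerClip <- x@seconds
    realize <- function(i) realizeClip(x, i)
  } else {
    nClips <- length(x)
    if (is.null(labels)) .stopf("labels are required for a plain clip list")
    secondsPerClip <- x[[1L]]$clip@durationS
    realize <- function(i) x[[i]]
  }
  if (length(labels) != nClips) .stopf("one label per clip required")
  if (length(unique(labels)) < 2L)
    .stopf("calibration needs at least 2 distinct label levels")
  if (holdoutFrac <= 0 || holdoutFrac > 0.5)
    .stopf("holdoutFrac must lie in (0, 0.5]")
  if (is.null(start))
    start <- if (mode == "hsvlab") thresholdSpec() else rgbBaselineSpec()

  cache <- .buildCache(realize, nClips, secondsPerClip, maxPixels, seed)
  holdout <- withr::with_seed(.childSeed(seed, 777),
                              sort(sample.int(nClips,
                                              max(1L, round(holdoutFrac *
                                                            nClips)))))
  train <- setdiff(seq_len(nClips), holdout)
  if (length(unique(labels[train])) < 2L)
    .stopf("training split is label-degenerate; change seed or holdoutFrac")

  params <- .paramTable(mode)
  traceRows <- list()
  bestLoss <- Inf
  lossOf <- function(sp) {
    pred <- .cacheClipScores(cache, sp, train)
    loss <- mean(abs(pred - labels[train]))
    bestLoss <<- min(bestLoss, loss)
    row <- as.data.frame(.specFields(sp))
    row$loss <- loss
    row$bestLoss <- bestLoss
    traceRows[[length(traceRows) + 1L]] <<- row
    loss
  }

  ## Mean coupling levels on the training frames; used for conditioned moves
  ## (a step in gammaA/gammaS alone shifts every frame's cut, so the paired
  ## move compensates the base cut to keep the cut at an average frame fixed,
  ## letting descent track the diagonal valley those two parameters form).
  trainCols <- cache$secClip %in% train
  mbarA <- mean(cache$meanA[trainCols])
  mbarS <- mean(cache$meanS[trainCols])

  candidateSpecs <- function(sp, nm, step) {
    cur <- slot(sp, nm)
    lo <- params$lo[params$name == nm]; hi <- params$hi[params$name == nm]
    ## short steps plus longer jumps, so descent can cross flat shelves of
    ## the piecewise-linear MAE surface
    vals <- setdiff(unique(.clamp(cur + c(-3, -1, 1, 3) * step, lo, hi)),
                    cur)
    out <- lapply(vals, function(v) .specWith(sp, nm, v))
    if (nm == "gammaA") {
      out <- c(out, lapply(vals, function(v) {
        sp2 <- .specWith(sp, nm, v)
        .specWith(sp2, "aMin",
                  .clamp(sp@aMin - (v - cur) * (mbarA - sp@aRef),
                         params$lo[params$name == "aMin"],
                         params$hi[params$name == "aMin"]))
      }))
    } else if (nm == "gammaS") {
      out <- c(out, lapply(vals, function(v) {
        sp2 <- .specWith(sp, nm, v)
        .specWith(sp2, "sMin",
                  .clamp(sp@sMin - (v - cur) * (mbarS - sp@sRef), 0, 1))
      }))
    }
    out
  }

  descend <- function(sp0, v0) {
    best <- sp0; bestVal <- v0
    steps <- params$step
    for (sw in seq_len(sweeps)) {
      ## cycle through the parameters until a full cycle yields no move
      for (cycle in 1:6) {
        cycleImproved <- FALSE
        anchor <- best
        for (pi in seq_len(nrow(params))) {
          nm <- params$name[pi]
          for (move in 1:12) {
            improved <- FALSE
            for (sp in candidateSpecs(best, nm, steps[pi])) {
              if (validObject(sp, test = TRUE) != TRUE) next
              v <- lossOf(sp)
              if (v < bestVal - 1e-12) {
                best <- sp; bestVal <- v
                improved <- TRUE; cycleImproved <- TRUE
              }
            }
            if (!improved) break
          }
        }
        ## pattern (Hooke-Jeeves) extrapolation: repeat the combined move of
        ## the whole cycle, which tracks diagonal valleys that per-coordinate
        ## steps zigzag along
        if (cycleImproved) {
          for (rep in 1:6) {
            sp <- best
            for (pi in seq_len(nrow(params))) {
              nm <- params$name[pi]
              delta <- slot(best, nm) - slot(anchor, nm)
              sp <- .specWith(sp, nm, .clamp(slot(best, nm) + delta,
                                             params$lo[pi], params$hi[pi]))
            }
            if (validObject(sp, test = TRUE) != TRUE) break
            v <- lossOf(sp)
            if (v < bestVal - 1e-12) {
              anchor <- best; best <- sp; bestVal <- v
            } else break
          }
        }
        if (!cycleImproved) break
      }
      steps <- steps * 0.5
    }
    list(spec = best, val = bestVal)
  }

  startVal <- lossOf(start)
  pool <- list(list(spec = start, val = startVal))
  if (coarse) {
    gridSpecs <- .coarseGrid(mode, start)
    gridVals <- vapply(gridSpecs, lossOf, numeric(1))
    ## greedy-diverse selection: walk the grid by ascending loss and keep
    ## points that are well separated in (range-normalised) parameter space,
    ## so the multi-start pool covers distinct gate-binding regimes rather
    ## than one basin's neighbours
    normPar <- function(sp) vapply(seq_len(nrow(params)), function(j)
      (slot(sp, params$name[j]) - params$lo[j]) /
        (params$hi[j] - params$lo[j]), numeric(1))
    chosen <- integer(0)
    for (i in order(gridVals)) {
      if (length(chosen) >= 3L) break
      p <- normPar(gridSpecs[[i]])
      if (!length(chosen) ||
          all(vapply(chosen, function(j)
            sqrt(sum((p - normPar(gridSpecs[[j]]))^2)) >= 0.35,
            logical(1))))
        chosen <- c(chosen, i)
    }
    pool <- c(pool, lapply(chosen, function(i)
      list(spec = gridSpecs[[i]], val = gridVals[i])))
    pool <- pool[order(vapply(pool, `[[`, numeric(1), "val"))]
    if (sweeps == 0L) pool <- pool[1L]  # best evaluated point wins outright
  }
  ## derivative-free simplex polish around an incumbent; the MAE surface
  ## near its optimum is a shallow curved valley that per-coordinate steps
  ## zigzag along, while a simplex tracks it
  polish <- function(sp0, v0) {
    par0 <- vapply(params$name, function(nm) slot(sp0, nm), numeric(1))
    fn <- function(par) {
      if (any(par < params$lo) || any(par > params$hi)) return(v0 + 10)
      sp <- sp0
      for (j in seq_along(par)) sp <- .specWith(sp, params$name[j], par[j])
      if (validObject(sp, test = TRUE) != TRUE) return(v0 + 10)
      lossOf(sp)
    }
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10,
                                       parscale = params$step))
    if (opt$value < v0 - 1e-12) {
      sp <- sp0
      for (j in seq_along(opt$par))
        sp <- .specWith(sp, params$name[j],
                        .clamp(opt$par[j], params$lo[j], params$hi[j]))
      list(spec = sp, val = opt$value)
    } else list(spec = sp0, val = v0)
  }

  best <- pool[[1L]]$spec; bestVal <- pool[[1L]]$val
  if (sweeps > 0L) {
    ## multi-start: descend from the best starting points, keep the best end;
    ## each start is annealed -- descent is restarted with full step sizes
    ## until a whole restart yields no further improvement
    for (p in pool[seq_len(min(3L, length(pool)))]) {
      res <- p
      for (restart in 1:2) {
        nxt <- descend(res$spec, res$val)
        if (nxt$val >= res$val - 1e-9) { res <- nxt; break }
        res <- nxt
      }
      if (res$val < bestVal) { best <- res$spec; bestVal <- res$val }
    }
    res <- polish(best, bestVal)
    best <- res$spec; bestVal <- res$val
  }

  ## Held-out evaluation with the full scoring pipeline.
  sys <- vapply(holdout, function(i) {
    g <- realize(i)
    scoreClip(g$clip, best, seed = .childSeed(seed, 10000 + i))@clipScore
  }, numeric(1))
  err <- abs(sys - labels[holdout])
  hs <- data.frame(clip = holdout, label = labels[holdout], system = sys)
  new("CalibrationResult", spec = best, trainMae = bestVal,
      holdoutMae = mean(err),
      holdoutMaeSd = if (length(err) > 1L) stats::sd(err) else 0,
      trace = do.call(rbind, traceRows), holdoutScores = hs)
}
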