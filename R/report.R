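## Procedure report serialisation: timeline CSV, report JSON with full
## provenance, and an optional timeline plot.

.provenance <- function(seed = NA, specMd5 = NA_character_,
                        inputMd5 = NA_character_) {
  list(package = "ArthroScore",
       version = as.character(utils::packageVersion("ArthroScore")),
       seed = seed, spec_checksum = specMd5, input_checksum = inputMd5)
}

## MD5 over the sorted file listing (name, size, per-file md5) of an input.
.inputChecksum <- function(path) {
  files <- if (dir.exists(path))
    sort(list.files(path, full.names = TRUE, recursive = TRUE)) else path
  md5 <- tools::md5sum(files)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(basename(files), md5, sep = "  "), f)
  unname(tools::md5sum(f))
}

#' Write the per-second timeline of a procedure as CSV
#'
#' Columns: second_index (0-based), sampled_frames (semicolon-joined 1-based
#' indices within the second), frame_scores, mean_score, resample_rounds,
#' flagged.
#'
#' @param report a \linkS4class{ProcedureReport}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeTimelineCsv <- function(report, path) {
  rows <- list()
  sec <- 0L
  if (length(report@clipScores)) {
    for (cs in report@clipScores) for (ss in cs@secondScores) {
      rows[[length(rows) + 1L]] <- data.frame(
        second_index = sec,
        sampled_frames = paste(ss@sampledFrames, collapse = ";"),
        frame_scores = paste(sprintf("%.6f", ss@frameScores), collapse = ";"),
        mean_score = ss@meanScore,
        resample_rounds = ss@resampleRounds,
        flagged = cs@flagged, stringsAsFactors = FALSE)
      sec <- sec + 1L
    }
    d <- do.call(rbind, rows)
  } else {
    d <- data.frame(second_index = seq_along(report@timeline) - 1L,
                    sampled_frames = NA, frame_scores = NA,
                    mean_score = report@timeline, resample_rounds = NA,
                    flagged = NA)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a procedure report as JSON
#'
#' Embeds the timeline, phase means, total bleeding score, every resampling
#' event (second range, rejected-round count, jump magnitude) and full
#' provenance (package version, spec checksum, seed, input checksum).
#'
#' @param report a \linkS4class{ProcedureReport}.
#' @param path output JSON file.
#' @param spec the specification used (for its checksum).
#' @param inputPath optional scored input (for its checksum).
#' @return \code{path}, invisibly.
#' @export
writeProcedureReport <- function(report, path, spec = NULL,
                                 inputPath = NULL) {
  resampling <- if (length(report@clipScores)) {
    evs <- Filter(function(cs) cs@rounds > 1L, report@clipScores)
    lapply(evs, function(cs) list(rounds = cs@rounds, jump = cs@jump,
                                  flagged = cs@flagged,
                                  clip_score = cs@clipScore,
                                  prev_score = cs@prevClipScore))
  } else list()
  obj <- list(
    provenance = .provenance(
      seed = report@seed,
      specMd5 = if (is.null(spec)) NA_character_ else specChecksum(spec),
      inputMd5 = if (is.null(inputPath)) NA_character_
                 else .inputChecksum(inputPath)),
    temporal_mode = report@temporalMode,
    total_bleeding_score = report@totalBleedingScore,
    n_seconds = length(report@timeline),
    timeline = report@timeline,
    phases = if (nrow(report@phases)) report@phases else list(),
    resampling_events = resampling)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Plot the bleeding-score timeline
#'
#' Base-graphics timeline of per-second scores with shaded phase ranges and
#' the total bleeding score in the title.
#'
#' @param report a \linkS4class{ProcedureReport}.
#' @return invisibly, the report.
#' @export
plotTimeline <- function(report) {
  t <- seq_along(report@timeline) - 1L
  graphics::plot(t, report@timeline, type = "l", ylim = c(1, 10),
                 xlab = "time (s)", ylab = "bleeding score",
                 main = sprintf("Total bleeding score %.2f",
                                report@totalBleedingScore))
  if (nrow(report@phases)) {
    for (i in seq_len(nrow(report@phases))) {
      graphics::rect(report@phases$start[i], 1, report@phases$end[i], 10,
                     col = grDevices::adjustcolor(i + 1, alpha.f = 0.08),
                     border = NA)
      graphics::text((report@phases$start[i] + report@phases$end[i]) / 2,
                     9.5, report@phases$name[i], cex = 0.8)
    }
  }
  invisible(report)
}

#' Agreement report between system scores and rater scores
#'
#' Computes the validation-statistics bundle on a scored clip collection:
#' the Shapiro-Wilk gate on the rater scores, interobserver ICC(A,k)
#' (two-way random), optional intraobserver ICC across two rating sessions
#' (two-way mixed, per rater), system-vs-rater-average MAE +/- SD and
#' mean-of-2 ICC(A,k), and the score-subgroup table.
#'
#' @param ratings a \linkS4class{RatingMatrix} or list of them (one per
#'   session, as from [readRatingsCsv()]).
#' @param system numeric system score per subject (same order as the rating
#'   matrix rows).
#' @param conf confidence level for ICC intervals.
#' @return list with elements \code{normality}, \code{interobserver},
#'   \code{intraobserver}, \code{mae}, \code{system_icc}, \code{subgroups}.
#' @export
agreementReport <- function(ratings, system, conf = 0.95) {
  sessions <- if (is(ratings, "RatingMatrix")) list(ratings) else ratings
  m1 <- sessions[[1L]]@scores
  if (nrow(m1) != length(system))
    .stopf("system scores must match the number of rated subjects")
  gate <- shapiroWilkGate(as.vector(m1))
  inter <- iccAgreement(m1, model = "twoWayRandom", unit = "meanOfK",
                        conf = conf)
  intra <- NULL
  if (length(sessions) >= 2L) {
    m2 <- sessions[[2L]]@scores
    perRater <- vapply(seq_len(ncol(m1)), function(j)
      iccAgreement(cbind(m1[, j], m2[, j]), model = "twoWayMixed",
                   unit = "single", conf = conf)@estimate, numeric(1))
    intra <- list(perRater = perRater, mean = mean(perRater))
  }
  raterAvg <- rowMeans(m1)
  mae <- maeScore(raterAvg, system)
  sysIcc <- iccAgreement(cbind(raterAvg, system), model = "twoWayRandom",
                         unit = "meanOfK", conf = conf)
  list(normality = gate, interobserver = inter, intraobserver = intra,
       mae = mae, system_icc = sysIcc,
       subgroups = subgroupAnalysis(raterAvg, system))
}

#' Write an agreement report as JSON plus a readable subgroup table
#'
#' @param rep list from [agreementReport()].
#' @param path output JSON file; a sibling \code{.txt} with the subgroup
#'   table is written alongside.
#' @return \code{path}, invisibly.
#' @export
writeAgreementReport <- function(rep, path) {
  iccAsList <- function(x) list(estimate = x@estimate, ci_low = x@ciLow,
                                ci_high = x@ciHigh, model = x@model,
                                unit = x@unit, k = x@k, n = x@n)
  obj <- list(
    provenance = .provenance(),
    normality = rep$normality,
    interobserver_icc = iccAsList(rep$interobserver),
    intraobserver = rep$intraobserver,
    mae = as.list(rep$mae),
    system_icc = iccAsList(rep$system_icc),
    subgroups = rep$subgroups)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(sprintf("%-16s %8s %14s %14s %8s", "Rater avg bin", "n",
                     "System score", "Abs error", "ICC"), con)
  sg <- rep$subgroups
  for (i in seq_len(nrow(sg)))
    writeLines(sprintf("%-16s %8d %7.2f +/- %.2f %7.2f +/- %.2f %8.2f",
                       sg$interval[i], sg$n[i], sg$system_mean[i],
                       sg$system_sd[i], sg$mae[i], sg$mae_sd[i],
                       sg$icc[i]), con)
  invisible(path)
}
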