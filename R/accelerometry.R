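#' Summarise minute-level accelerometer counts into activity outcomes
#'
#' Applies wear-time validity and intensity cut-points to a minute-level
#' count trace: a day is valid iff it holds at least
#' \code{60 * min_wear_hours} wear minutes, and an individual's summary is
#' valid iff at least \code{min_valid_days} days are valid. Over valid days
#' only, three outcomes are computed: total activity (mean counts/minute
#' over the whole valid recording), moderate-to-vigorous activity (mean
#' minutes/day with counts strictly above \code{mvpa_cut}) and sedentary
#' time (mean minutes/day with counts strictly below \code{sedentary_cut}).
#' Boundary counts (exactly 3,600 or exactly 199) fall in the unlabelled
#' middle band. Invalid summaries are flagged, not errors.
#'
#' @param trace data.frame with columns \code{id}, \code{day},
#'   \code{counts} (and optionally \code{minute}); wear minutes are the
#'   minutes present per day (no non-wear detection is applied).
#' @param min_wear_hours minimum wear hours per valid day (default 10).
#' @param min_valid_days minimum valid days for a valid summary (default 3).
#' @param mvpa_cut counts/min; minutes strictly above count as
#'   moderate-to-vigorous (default 3,600).
#' @param sedentary_cut counts/min; minutes strictly below count as
#'   sedentary (default 199).
#'
#' @return data.frame with one row per individual: id, total_pa, mvpa,
#'   sedentary, n_valid_days, valid. Outcome columns are NA when invalid.
#' @examples
#' tr <- simulateMinuteCounts(600, 0.05, 0.6, 3, 600, seed = 1)
#' summarizeActigraphy(tr)
#' @export
summarizeActigraphy <- function(trace, min_wear_hours = 10,
                                min_valid_days = 3,
                                mvpa_cut = 3600, sedentary_cut = 199) {
  if (nrow(trace) == 0L)
    return(data.frame(id = character(), total_pa = numeric(),
                      mvpa = numeric(), sedentary = numeric(),
                      n_valid_days = integer(), valid = logical(),
                      stringsAsFactors = FALSE))
  stopifnot(all(c("id", "day", "counts") %in% names(trace)))
  if (any(trace$counts < 0, na.rm = TRUE)) stop("negative counts")
  min_minutes <- 60 * min_wear_hours
  out <- lapply(split(trace, trace$id), function(tr) {
    per_day <- lapply(split(tr$counts, tr$day), function(cts) {
      c(wear = length(cts), total = sum(cts),
        mvpa = sum(cts > mvpa_cut), sed = sum(cts < sedentary_cut))
    })
    per_day <- do.call(rbind, per_day)
    ok <- per_day[, "wear"] >= min_minutes & per_day[, "wear"] > 0
    nv <- sum(ok)
    valid <- nv >= min_valid_days
    if (nv > 0) {
      v <- per_day[ok, , drop = FALSE]
      total_pa <- sum(v[, "total"]) / sum(v[, "wear"])
      mvpa <- mean(v[, "mvpa"])
      sed <- mean(v[, "sed"])
    } else total_pa <- mvpa <- sed <- NA_real_
    data.frame(id = tr$id[1L],
               total_pa = if (valid) total_pa else NA_real_,
               mvpa = if (valid) mvpa else NA_real_,
               sedentary = if (valid) sed else NA_real_,
               n_valid_days = as.integer(nv), valid = valid,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a long-format minute-level trace CSV
#'
#' Expected columns: id, day, minute, counts.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readMinuteTrace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "day", "counts") %in% names(d)))
  d
}

#' Write per-individual activity summaries as TSV
#'
#' @param summary output of \code{\link{summarizeActigraphy}}.
#' @param path file path.
#' @export
writeActivitySummary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
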