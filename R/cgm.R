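#' Glycemic band definitions
#'
#' Consensus CGM bands in mmol/l: time in range (TIR) 3.9-10, time in tight
#' range (TITR) 3.9-7.8, time above range (TAR) > 10, time below range
#' (TBR) < 3.9.  TIR/TITR are closed intervals; TAR/TBR are strict, so
#' TBR + TIR + TAR partitions every reading exactly.
#'
#' @return A list with elements `tir`, `titr` (each `c(lo, hi)`) and the
#'   physiologic sensor range `sensor`.
#' @export
glycemic_bands <- function() {
  list(tir = c(3.9, 10), titr = c(3.9, 7.8), sensor = c(0.5, 45))
}

#' Construct and validate a CGM trace
#'
#' Canonicalizes raw readings for one participant: sorts by timestamp,
#' drops duplicate timestamps (first occurrence wins; daylight-saving
#' duplicates resolve the same way because timestamps are treated as
#' timezone-naive clock times stored in UTC), and drops values outside the
#' physiologic sensor range 0.5-45 mmol/l with a message.
#'
#' @param participant_id Identifier.
#' @param time `POSIXct` timestamps (minute resolution).
#' @param glucose Glucose readings in mmol/l.
#' @param nominal_interval Nominal sampling interval in minutes.
#' @param quiet Suppress messages about dropped readings.
#' @return An object of class `cgm_trace`: a list with `participant_id`,
#'   `time`, `glucose`, `nominal_interval`.
#' @export
cgm_trace <- function(participant_id, time, glucose, nominal_interval = 5,
                      quiet = FALSE) {
  if (length(time) != length(glucose)) {
    stop("time and glucose must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty CGM trace", call. = FALSE)
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct", call. = FALSE)
  attr(time, "tzone") <- "UTC"  # timezone-naive clock times, stored as UTC
  ord <- order(time)
  time <- time[ord]; glucose <- glucose[ord]
  dup <- duplicated(time)
  if (any(dup)) {
    if (!quiet) message(sum(dup), " duplicate timestamp(s) dropped (first occurrence kept)")
    time <- time[!dup]; glucose <- glucose[!dup]
  }
  rng <- glycemic_bands()$sensor
  bad <- !is.finite(glucose) | glucose < rng[1] | glucose > rng[2]
  if (any(bad)) {
    if (!quiet) message(sum(bad), " out-of-range reading(s) dropped")
    time <- time[!bad]; glucose <- glucose[!bad]
  }
  if (length(glucose) < 2L) {
    stop("fewer than 2 valid readings survive validation", call. = FALSE)
  }
  structure(list(participant_id = participant_id, time = time,
                 glucose = glucose, nominal_interval = nominal_interval),
            class = "cgm_trace")
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat("<cgm_trace> participant", x$participant_id, "-", length(x$glucose),
      "readings,", format(min(x$time)), "to", format(max(x$time)), "\n")
  invisible(x)
}

new_trace_like <- function(trace, keep) {
  structure(list(participant_id = trace$participant_id,
                 time = trace$time[keep], glucose = trace$glucose[keep],
                 nominal_interval = trace$nominal_interval),
            class = "cgm_trace")
}

#' Restrict a trace to the window before an anchor date
#'
#' Keeps readings in the half-open interval
#' `[anchor - days, anchor)`, where `anchor` is taken at 00:00 of the
#' anchor date.  A reading stamped exactly at the anchor's midnight is
#' excluded.  An empty window is a legal result.
#'
#' @param trace A [cgm_trace()].
#' @param anchor A `Date` (or anything coercible) marking the window end.
#' @param days Window length in days (default 90).
#' @return A `cgm_trace` with the retained readings (possibly zero).
#' @export
window_trace <- function(trace, anchor, days = 90) {
  stopifnot(inherits(trace, "cgm_trace"), days > 0)
  end <- as.POSIXct(as.Date(anchor), tz = "UTC")
  start <- end - days * 86400
  new_trace_like(trace, trace$time >= start & trace$time < end)
}

trace_values <- function(x) if (inherits(x, "cgm_trace")) x$glucose else x

#' Mean sensor glucose (AG)
#'
#' @param x A [cgm_trace()] or numeric vector of readings in mmol/l.
#' @return Mean glucose, mmol/l.
#' @export
mean_glucose <- function(x) {
  v <- trace_values(x)
  if (length(v) < 1L) stop("at least one reading required", call. = FALSE)
  mean(v)
}

#' Glucose dispersion: SD and CV
#'
#' Sample standard deviation (n-1 denominator) and coefficient of
#' variation `100 * SD / AG`.
#'
#' @param x A [cgm_trace()] or numeric vector (at least two readings).
#' @return A list with `sd` (mmol/l) and `cv` (%).
#' @export
glucose_dispersion <- function(x) {
  v <- trace_values(x)
  if (length(v) < 2L) stop("at least two readings required for dispersion", call. = FALSE)
  s <- stats::sd(v)
  list(sd = s, cv = 100 * s / mean(v))
}

#' Percentage of readings within a closed glucose band
#'
#' Reading-count based (not duration-weighted): the fraction of readings
#' with `lo <= value <= hi`, as a percentage.  Time above range uses the
#' strict complement `> hi` and time below range `< lo`, so the three
#' bands partition the readings exactly.
#'
#' @param x A [cgm_trace()] or numeric vector.
#' @param lo,hi Band limits in mmol/l, `lo < hi`.
#' @return Percentage in `[0, 100]`.
#' @export
time_in_band <- function(x, lo, hi) {
  stopifnot(lo < hi)
  v <- trace_values(x)
  if (length(v) < 1L) stop("at least one reading required", call. = FALSE)
  100 * sum(v >= lo & v <= hi) / length(v)
}

#' @rdname time_in_band
#' @export
time_above <- function(x, hi) {
  v <- trace_values(x)
  if (length(v) < 1L) stop("at least one reading required", call. = FALSE)
  100 * sum(v > hi) / length(v)
}

#' @rdname time_in_band
#' @export
time_below <- function(x, lo) {
  v <- trace_values(x)
  if (length(v) < 1L) stop("at least one reading required", call. = FALSE)
  100 * sum(v < lo) / length(v)
}

#' Summarize a CGM trace into the consensus metric suite
#'
#' Computes AG, SD, CV, TIR, TITR, TAR, TBR, the uGMI of AG (IFCC), the
#' linear comparator GMI (% NGSP), the reading count, and the wear
#' percentage.  Wear is the reading count relative to the expected count
#' at the nominal interval: over `window_days` when supplied, otherwise
#' over the observed span of the trace.
#'
#' @param trace A [cgm_trace()].
#' @param window_days Window length the trace is meant to cover, for the
#'   wear denominator; `NULL` uses the observed span.
#' @param formula,cc Passed to [ugmi()] / [gmi_comparator()].
#' @return An object of class `glycemic_summary` (a named list).
#' @export
summarize_trace <- function(trace, window_days = NULL,
                            formula = ugmi_formula(), cc = conversion_constants()) {
  stopifnot(inherits(trace, "cgm_trace"))
  v <- trace$glucose
  if (length(v) < 2L) stop("at least two readings required to summarize", call. = FALSE)
  bands <- glycemic_bands()
  ag <- mean(v)
  disp <- glucose_dispersion(v)
  n <- length(v)
  span_min <- if (is.null(window_days)) {
    as.numeric(difftime(max(trace$time), min(trace$time), units = "mins")) +
      trace$nominal_interval
  } else {
    window_days * 1440
  }
  expected <- span_min / trace$nominal_interval
  structure(list(
    ag = ag, sd = disp$sd, cv = disp$cv,
    tir = time_in_band(v, bands$tir[1], bands$tir[2]),
    titr = time_in_band(v, bands$titr[1], bands$titr[2]),
    tar = time_above(v, bands$tir[2]),
    tbr = time_below(v, bands$tir[1]),
    ugmi_ifcc = ugmi(ag, "ifcc", formula, cc),
    gmi_ngsp = gmi_comparator(ag, cc = cc),
    n_readings = n,
    wear_pct = 100 * n / expected
  ), class = "glycemic_summary")
}

#' @export
print.glycemic_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<glycemic_summary> AG %.2f mmol/l, SD %.2f, CV %.1f%%\n",
    "  TIR %.1f%%  TITR %.1f%%  TAR %.1f%%  TBR %.1f%%\n",
    "  uGMI %.1f mmol/mol (%.1f%% NGSP)  GMI %.1f%%  n=%d  wear %.1f%%\n"),
    x$ag, x$sd, x$cv, x$tir, x$titr, x$tar, x$tbr,
    x$ugmi_ifcc, ifcc_to_ngsp(x$ugmi_ifcc), x$gmi_ngsp,
    x$n_readings, x$wear_pct))
  invisible(x)
}

#' Screen a trace for CGM completeness
#'
#' Deterministic pass/fail with a machine-readable reason, mirroring the
#' exclusion of participants with incomplete CGM data.  A trace passes if
#' it spans at least `min_days` days and its wear percentage is at least
#' `min_wear_pct`.
#'
#' @param trace A [cgm_trace()] (possibly empty, which fails).
#' @param min_wear_pct Minimum wear percentage (default 70, the consensus
#'   CGM-sufficiency recommendation).
#' @param min_days Minimum span in days (default 14).
#' @param window_days Wear denominator window, as in [summarize_trace()].
#' @return A list with `pass` (logical) and `reason` (`"ok"`, `"empty"`,
#'   `"min_days"`, or `"min_wear"`).
#' @export
sufficiency_filter <- function(trace, min_wear_pct = 70, min_days = 14,
                               window_days = NULL) {
  n <- length(trace$glucose)
  if (n < 2L) return(list(pass = FALSE, reason = "empty"))
  span_days <- as.numeric(difftime(max(trace$time), min(trace$time), units = "days"))
  if (span_days < min_days) return(list(pass = FALSE, reason = "min_days"))
  span_min <- if (is.null(window_days)) {
    span_days * 1440 + trace$nominal_interval
  } else {
    window_days * 1440
  }
  wear <- 100 * n / (span_min / trace$nominal_interval)
  if (wear < min_wear_pct) return(list(pass = FALSE, reason = "min_wear"))
  list(pass = TRUE, reason = "ok")
}

#' Construct a participant record
#'
#' @param id Identifier.
#' @param group `"case"` or `"control"`.
#' @param visits A data.frame with columns `date` (`Date`) and `hba1c`
#'   (IFCC mmol/mol); sorted by date on construction.
#' @param trace A [cgm_trace()] holding all of the participant's readings.
#' @param diagnosis_date `Date` of incident diagnosis (cases only; `NA`
#'   for controls).
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(id, group = c("control", "case"), visits, trace,
                               diagnosis_date = as.Date(NA)) {
  group <- match.arg(group)
  stopifnot(is.data.frame(visits), all(c("date", "hba1c") %in% names(visits)),
            inherits(trace, "cgm_trace"))
  if (group == "case" && is.na(diagnosis_date)) {
    stop("cases must have a diagnosis date", call. = FALSE)
  }
  check_hba1c(visits$hba1c, "ifcc")
  visits <- visits[order(visits$date), , drop = FALSE]
  structure(list(id = id, group = group, visits = visits, trace = trace,
                 diagnosis_date = as.Date(diagnosis_date)),
            class = "participant_record")
}

#' Sentinel marking a participant excluded from aggregation
#'
#' @param id Participant identifier.
#' @param reason Machine-readable exclusion reason.
#' @return An object of class `excluded_participant`.
#' @export
excluded_participant <- function(id, reason) {
  structure(list(participant_id = id, reason = reason),
            class = "excluded_participant")
}

#' @rdname excluded_participant
#' @param x Object to test.
#' @export
is_excluded <- function(x) inherits(x, "excluded_participant")

#' Aggregate one participant into a feature row
#'
#' Implements the pre-diagnosis censoring and pooling rule: for cases,
#' visits dated on or after the diagnosis date are discarded (half-open
#' convention, as in [window_trace()]); the HbA1c feature is the mean of
#' the remaining visits' laboratory HbA1c; CGM features are computed on
#' the pooled readings of the remaining visits' windows (each window
#' screened by [sufficiency_filter()]; overlapping windows are de-duplicated
#' by timestamp) with a final guard dropping any reading on or after the
#' diagnosis date.  The uGMI feature is the uGMI of the pooled AG.
#'
#' @param record A [participant_record()].
#' @param window_days CGM window length per visit (default 90).
#' @param min_wear_pct,min_days Passed to [sufficiency_filter()].
#' @param mode `"pooled"` (one summary over the concatenated readings,
#'   the default) or `"per_visit"` (unweighted mean of per-window
#'   summaries).
#' @param formula,cc Passed to [ugmi()].
#' @return A one-row data.frame with columns `participant_id`, `outcome`,
#'   `ugmi`, `ag`, `hba1c`, `titr`, `tir`, `tbr`, `tar`, `sd`, `cv`,
#'   `n_visits`, `n_readings`; or an [excluded_participant()] sentinel
#'   carrying the reason if no usable pre-diagnosis data survive.
#' @export
participant_aggregate <- function(record, window_days = 90, min_wear_pct = 70,
                                  min_days = 14, mode = c("pooled", "per_visit"),
                                  formula = ugmi_formula(),
                                  cc = conversion_constants()) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "participant_record"))
  visits <- record$visits
  if (record$group == "case") {
    visits <- visits[visits$date < record$diagnosis_date, , drop = FALSE]
  }
  if (nrow(visits) == 0L) {
    return(excluded_participant(record$id, "no pre-diagnosis visits"))
  }
  windows <- lapply(visits$date, function(d) window_trace(record$trace, d, window_days))
  ok <- vapply(windows, function(w) {
    sufficiency_filter(w, min_wear_pct, min_days, window_days)$pass
  }, logical(1))
  windows <- windows[ok]
  if (length(windows) == 0L) {
    return(excluded_participant(record$id, "no sufficient CGM windows"))
  }
  time <- do.call(c, lapply(windows, `[[`, "time"))
  attr(time, "tzone") <- "UTC"
  glucose <- unlist(lapply(windows, `[[`, "glucose"))
  ord <- order(time)
  time <- time[ord]; glucose <- glucose[ord]
  dup <- duplicated(time)
  time <- time[!dup]; glucose <- glucose[!dup]
  if (record$group == "case") {
    keep <- time < as.POSIXct(record$diagnosis_date, tz = "UTC")
    time <- time[keep]; glucose <- glucose[keep]
  }
  if (length(glucose) < 2L) {
    return(excluded_participant(record$id, "no pre-diagnosis readings"))
  }
  pooled <- cgm_trace(record$id, time, glucose, record$trace$nominal_interval,
                      quiet = TRUE)
  if (mode == "pooled") {
    s <- summarize_trace(pooled, window_days = NULL, formula = formula, cc = cc)
  } else {
    per <- lapply(windows, summarize_trace, window_days = window_days,
                  formula = formula, cc = cc)
    s <- lapply(setNames(nm = c("ag", "sd", "cv", "tir", "titr", "tar", "tbr")),
                function(f) mean(vapply(per, `[[`, numeric(1), f)))
    s$ugmi_ifcc <- ugmi(s$ag, "ifcc", formula, cc)
    s$n_readings <- sum(vapply(per, `[[`, numeric(1), "n_readings"))
  }
  data.frame(participant_id = record$id,
             outcome = as.integer(record$group == "case"),
             ugmi = s$ugmi_ifcc, ag = s$ag, hba1c = mean(visits$hba1c),
             titr = s$titr, tir = s$tir, tbr = s$tbr, tar = s$tar,
             sd = s$sd, cv = s$cv,
             n_visits = nrow(visits), n_readings = s$n_readings,
             stringsAsFactors = FALSE)
}

#' Build the nine-feature table for a set of participants
#'
#' Applies [participant_aggregate()] to each record; participants with no
#' usable pre-diagnosis data are excluded and listed (with reasons) in the
#' `"excluded"` attribute of the result.
#'
#' @param records A list of [participant_record()] objects.
#' @param ... Passed to [participant_aggregate()].
#' @return A data.frame (one row per retained participant) with attribute
#'   `"excluded"`: a data.frame of `participant_id`, `reason`.
#' @export
build_feature_table <- function(records, ...) {
  rows <- lapply(records, participant_aggregate, ...)
  excluded <- data.frame(participant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- !vapply(rows, is_excluded, logical(1))
  if (any(!keep)) {
    excluded <- data.frame(
      participant_id = vapply(rows[!keep], `[[`, character(1), "participant_id"),
      reason = vapply(rows[!keep], `[[`, character(1), "reason"),
      stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, rows[keep])
  rownames(ft) <- NULL
  structure(ft, excluded = excluded)
}

#' Names of the nine candidate features
#'
#' @return Character vector in the canonical column order.
#' @export
feature_names <- function() {
  c("ugmi", "ag", "hba1c", "titr", "tir", "tbr", "tar", "sd", "cv")
}
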