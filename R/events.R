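#' Is a day a relapse-indicating ("bad") day?
#'
#' A day counts against sobriety when alcohol was detected or when every
#' scheduled breathalyzer test was omitted — omission is treated as a
#' compliance failure that frequently masks drinking. Days with `NA` status
#' (no scheduled test) return `NA`.
#'
#' @param status Character vector with values in
#'   `c("no_alcohol", "alcohol_detected", "all_omitted")`.
#' @return Logical vector.
#' @export
daily_bad_day <- function(status) {
  known <- status %in% sobriety_statuses | is.na(status)
  if (!all(known)) {
    stop("unknown sobriety status '", status[which(!known)[1]], "'",
         call. = FALSE)
  }
  ifelse(is.na(status), NA, status %in% c("alcohol_detected", "all_omitted"))
}

#' Detect exacerbation events in a daily status series
#'
#' An exacerbation event (EE) — a rapid worsening of the disease state — is
#' a maximal run of at least `min_len` consecutive bad days (see
#' [daily_bad_day()]; the predicate is pluggable via `bad_day`). Days with
#' no status are treated as not-bad for run-finding.
#'
#' @param status_series Character vector of daily statuses (gapless grid).
#' @param min_len Minimum run length to count as an EE (default 2).
#' @param bad_day Predicate mapping the status vector to logical.
#' @return An `event_calendar`: list with `events` (data.frame `start`,
#'   `end`, 0-based inclusive day indices), `in_ee` (logical per day),
#'   `n_days`.
#' @export
detect_exacerbation_events <- function(status_series, min_len = 2L,
                                       bad_day = daily_bad_day) {
  bad <- bad_day(status_series)
  bad[is.na(bad)] <- FALSE
  n <- length(bad)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  events <- data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
  in_ee <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    in_ee[(events$start[i]:events$end[i]) + 1L] <- TRUE
  }
  structure(list(events = events, in_ee = in_ee, n_days = n),
            class = "event_calendar")
}

#' @export
print.event_calendar <- function(x, ...) {
  cat("<event_calendar> ", x$n_days, " days, ", nrow(x$events),
      " exacerbation event(s), ", sum(x$in_ee), " in-event days\n", sep = "")
  invisible(x)
}

#' Approximate sobriety index from daily breathalyzer status
#'
#' Applies the same construction as the questionnaire biomarkers to sobriety
#' data: code `no_alcohol` = 100, `alcohol_detected` = 0, `all_omitted` =
#' missing, then gap-decay imputation and exponential smoothing. This is an
#' explicit *approximation* of the Addiction Monitoring Index (AMI), whose
#' exact published construction is external; when the source system supplies
#' an `ami` column, prefer that (see [eligibility_mask()]).
#'
#' @param status_series Character vector of daily statuses; `NA` treated as
#'   missing (no test scheduled).
#' @param params [smoothing_params()]; 0.21 is the factor historically used
#'   for breathalyzer-based indices.
#' @return Numeric vector in \[0, 100\], `NA` before the first performed
#'   test.
#' @export
sobriety_index <- function(status_series, params = smoothing_params(0.21)) {
  raw <- rep(NA_real_, length(status_series))
  raw[!is.na(status_series) & status_series == "no_alcohol"] <- 100
  raw[!is.na(status_series) & status_series == "alcohol_detected"] <- 0
  n <- length(raw)
  out <- rep(NA_real_, n)
  first_obs <- which(!is.na(raw))[1]
  if (!is.na(first_obs)) {
    imp <- impute_raw_series(raw[first_obs:n])
    out[first_obs:n] <- exponential_smooth(imp$value, params)
  }
  out
}

#' Forecasting labels from an event calendar
#'
#' Day `t` is labeled positive when some exacerbation event *starts* on a
#' day in `[t + lo, t + hi]` (in-progress events do not re-trigger labels).
#' Labels are `NA` where the look-ahead window does not fit inside the
#' panel, so right-edge days are excluded from training/evaluation rather
#' than silently labeled negative.
#'
#' @param calendar An [detect_exacerbation_events()] calendar.
#' @param look_ahead Integer pair `(lo, hi)`; the study design uses
#'   `c(1, 3)` or `c(5, 7)`. Other windows require `allow_custom = TRUE`.
#' @param allow_custom Permit non-standard look-ahead windows.
#' @return A `label_set`: list with `label` (integer 0/1/NA per day),
#'   `look_ahead`.
#' @export
make_labels <- function(calendar, look_ahead = c(1L, 3L),
                        allow_custom = FALSE) {
  look_ahead <- as.integer(look_ahead)
  if (length(look_ahead) != 2L || look_ahead[1] > look_ahead[2]) {
    stop("look_ahead must be an increasing pair (lo, hi)", call. = FALSE)
  }
  standard <- identical(look_ahead, c(1L, 3L)) ||
    identical(look_ahead, c(5L, 7L))
  if (!standard && !allow_custom) {
    stop("look_ahead must be c(1, 3) or c(5, 7); ",
         "set allow_custom = TRUE to override", call. = FALSE)
  }
  n <- calendar$n_days
  lo <- look_ahead[1]
  hi <- look_ahead[2]
  is_start <- rep(FALSE, n)
  if (nrow(calendar$events)) {
    is_start[calendar$events$start + 1L] <- TRUE
  }
  label <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    a <- t + lo
    b <- t + hi
    if (b > n) next  # window does not fit
    label[t] <- as.integer(any(is_start[a:b]))
  }
  structure(list(label = label, look_ahead = look_ahead),
            class = "label_set")
}

#' Per-day eligibility for issuing a forecast
#'
#' A prediction is issued only for days on which it is clinically meaningful:
#' at least `startup_days` into the treatment period (the start-up period is
#' excluded), not already inside an exacerbation event, and with a sobriety
#' index (AMI) of at least `ami_min` — patients already relapsing or at
#' rock-bottom compliance need no forecast. Days with missing AMI are
#' ineligible.
#'
#' @param calendar An `event_calendar`.
#' @param ami_series Numeric AMI per day (recorded AMI where available,
#'   otherwise [sobriety_index()]).
#' @param ami_min Inclusive AMI threshold (default 40).
#' @param startup_days Number of leading treatment days excluded (default 7:
#'   0-based days 0..6 are ineligible).
#' @return Logical vector, one flag per day.
#' @export
eligibility_mask <- function(calendar, ami_series, ami_min = 40,
                             startup_days = 7L) {
  n <- calendar$n_days
  if (length(ami_series) != n) {
    stop("ami_series length (", length(ami_series),
         ") does not match calendar days (", n, ")", call. = FALSE)
  }
  day <- seq_len(n) - 1L
  eligible <- day >= startup_days &
    !calendar$in_ee &
    !is.na(ami_series) &
    ami_series >= ami_min
  eligible
}

#' Write detected events and labels to CSV
#'
#' @param calendar An `event_calendar`.
#' @param dates Date vector aligned to the calendar days.
#' @param patient_id Patient identifier for the output rows.
#' @param path Output CSV path.
#' @export
write_events <- function(calendar, dates, patient_id, path) {
  ev <- calendar$events
  out <- data.frame(patient_id = rep(patient_id, nrow(ev)),
                    start_date = dates[ev$start + 1L],
                    end_date = dates[ev$end + 1L])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
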