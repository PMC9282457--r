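#' Exponential smoothing parameters
#'
#' The single tunable of the biomarker construction: the smoothing factor
#' alpha in (0, 1), the weight of the current day's raw value in the
#' recursion `S_t = alpha * x_t + (1 - alpha) * S_{t-1}`. The default 0.32
#' makes questionnaire biomarkers track the Addiction Monitoring Index
#' closely; 0.21 is the historical alternative used for breathalyzer-based
#' indices (it under-reacts to answer variation and mainly dips on missing
#' data).
#'
#' @param alpha Smoothing factor, strictly between 0 and 1.
#' @return A `smoothing_params` object.
#' @export
smoothing_params <- function(alpha = 0.32) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in the open interval (0, 1)",
         call. = FALSE)
  }
  structure(list(alpha = alpha), class = "smoothing_params")
}

#' Raw daily value: average of the day's available answers
#'
#' For one day, the mean of the coded answers to the questions contributing
#' to a biomarker; `NA` when none of them was answered (that day is later
#' imputed).
#'
#' @param day_answers Named numeric vector (or 1-row slice of a panel) of
#'   coded values, `NA` for unanswered questions.
#' @param question_subset Character vector of contributing question ids.
#' @return The mean of available subset answers, or `NA_real_`.
#' @export
raw_daily_value <- function(day_answers, question_subset) {
  if (!length(question_subset)) {
    stop("question_subset must be non-empty", call. = FALSE)
  }
  vals <- unlist(day_answers[question_subset], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

raw_daily_series <- function(panel, question_subset) {
  sub <- as.matrix(panel[, question_subset, drop = FALSE])
  ans <- rowSums(!is.na(sub))
  out <- rowMeans(sub, na.rm = TRUE)
  out[ans == 0] <- NA_real_
  out
}

#' Impute unanswered days of a raw daily series
#'
#' The missing-not-at-random imputation: an unanswered day is assumed to
#' reflect a worsening state, so its raw value decays with the length of the
#' silence. With `k` the number of days since the last answered day:
#' `k = 1` gives 2/3 of that day's raw value, `k = 2` gives 1/3 of it, and
#' `k >= 3` gives 0. Observed days pass through unchanged.
#'
#' @param raw_series Numeric vector with `NA` for unanswered days; the first
#'   element must be observed.
#' @return List with components `value` (filled numeric vector) and
#'   `provenance` (character: `"observed"`, `"imputed_decay"`,
#'   `"imputed_zero"`).
#' @examples
#' impute_raw_series(c(90, NA, NA, NA))$value  # 90 60 30 0
#' @export
impute_raw_series <- function(raw_series) {
  x <- as.numeric(raw_series)
  n <- length(x)
  if (!n || all(is.na(x))) {
    stop("raw series contains no observed value", call. = FALSE)
  }
  if (is.na(x[1])) {
    stop("raw series must begin with an observed value ",
         "(trim to the first answered day first)", call. = FALSE)
  }
  prov <- rep("observed", n)
  last_obs <- x[1]
  gap <- 0L
  for (t in seq_len(n)) {
    if (!is.na(x[t])) {
      last_obs <- x[t]
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap == 1L) {
        x[t] <- 2 / 3 * last_obs
        prov[t] <- "imputed_decay"
      } else if (gap == 2L) {
        x[t] <- 1 / 3 * last_obs
        prov[t] <- "imputed_decay"
      } else {
        x[t] <- 0
        prov[t] <- "imputed_zero"
      }
    }
  }
  list(value = x, provenance = prov)
}

#' Exponentially smooth a filled raw daily series
#'
#' `S_0 = x_0`; `S_t = alpha * x_t + (1 - alpha) * S_{t-1}` for `t > 0`.
#'
#' @param filled_series Numeric vector without missing values.
#' @param params A [smoothing_params()] object (or bare alpha).
#' @return Numeric vector of the same length.
#' @export
exponential_smooth <- function(filled_series, params = smoothing_params()) {
  if (is.numeric(params)) {
    params <- smoothing_params(params)
  }
  x <- as.numeric(filled_series)
  if (anyNA(x)) {
    stop("filled series must not contain missing values", call. = FALSE)
  }
  if (!length(x)) {
    return(numeric(0))
  }
  alpha <- params$alpha
  # recursive filter with S_{-1} = x_0 makes S_0 = alpha x_0 + (1-alpha) x_0 = x_0
  s <- stats::filter(alpha * x, 1 - alpha, method = "recursive", init = x[1])
  as.numeric(s)
}

#' Build a digital biomarker series for one patient
#'
#' Composition of the full construction: per-day averaging over the
#' contributing questions, gap-decay imputation of unanswered days, and
#' exponential smoothing. The series starts at the patient's first day with
#' an observed raw value for the subset (before that day, "days since the
#' last answered day" is undefined); earlier panel days carry `NA` with
#' provenance `"undefined"`.
#'
#' @param panel A [build_day_grid()] panel.
#' @param question_subset Contributing question ids, e.g. [webe_questions].
#' @param params [smoothing_params()].
#' @param name Biomarker name used in outputs.
#' @return A `biomarker_series`: data.frame with `day`, `date`, `raw`
#'   (filled raw daily value), `value` (smoothed index in \[0, 100\]) and
#'   `provenance`; attributes `patient_id`, `name`, `alpha`,
#'   `question_subset`.
#' @export
build_biomarker <- function(panel, question_subset,
                            params = smoothing_params(),
                            name = "biomarker") {
  if (!nrow(panel)) {
    stop("panel is empty", call. = FALSE)
  }
  raw <- raw_daily_series(panel, question_subset)
  n <- length(raw)
  value <- rep(NA_real_, n)
  filled <- rep(NA_real_, n)
  prov <- rep("undefined", n)
  first_obs <- which(!is.na(raw))[1]
  if (!is.na(first_obs)) {
    imp <- impute_raw_series(raw[first_obs:n])
    sm <- exponential_smooth(imp$value, params)
    idx <- first_obs:n
    filled[idx] <- imp$value
    value[idx] <- sm
    prov[idx] <- imp$provenance
  }
  structure(
    data.frame(day = panel$day, date = panel$date,
               raw = filled, value = value, provenance = prov),
    patient_id = attr(panel, "patient_id"),
    name = name,
    alpha = params$alpha,
    question_subset = question_subset,
    class = c("biomarker_series", "data.frame")
  )
}

#' @export
print.biomarker_series <- function(x, ...) {
  def <- sum(!is.na(x$value))
  cat("<biomarker_series> ", attr(x, "name"),
      " (alpha = ", attr(x, "alpha"), "), patient ", attr(x, "patient_id"),
      ": ", def, "/", nrow(x), " days with a value\n", sep = "")
  if (def) {
    cat("  observed ", sum(x$provenance == "observed"),
        ", imputed_decay ", sum(x$provenance == "imputed_decay"),
        ", imputed_zero ", sum(x$provenance == "imputed_zero"), "\n", sep = "")
  }
  invisible(x)
}

#' Write biomarker series to tidy CSV
#'
#' One row per patient-day: `patient_id,date,biomarker,value,provenance`.
#'
#' @param series_list List of `biomarker_series` objects.
#' @param path Output CSV path.
#' @export
write_biomarkers <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(patient_id = attr(s, "patient_id"), date = s$date,
               biomarker = attr(s, "name"), value = s$value,
               provenance = s$provenance)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$value), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
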