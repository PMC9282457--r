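#' Construct and validate a questionnaire table
#'
#' Long-format table of coded daily answers: one row per
#' (patient, date, question). Values must lie in the question's coded set and
#' duplicates are rejected.
#'
#' @param df Data frame with columns `patient_id`, `date` (Date or ISO-8601
#'   string), `question`, `value` (coded 0--100).
#' @param coding An [answer_coding()] object used for value validation.
#' @return A `questionnaire_table` (a validated data.frame).
#' @export
questionnaire_table <- function(df, coding = answer_coding()) {
  need <- c("patient_id", "date", "question", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("questionnaire table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$patient_id <- as.character(df$patient_id)
  df$date <- parse_iso_date(df$date, "questionnaire")
  df$question <- as.character(df$question)
  df$value <- as.numeric(df$value)

  bad_q <- which(!df$question %in% names(coding))
  if (length(bad_q)) {
    stop("row ", bad_q[1], ": unknown question '", df$question[bad_q[1]], "'",
         call. = FALSE)
  }
  for (q in unique(df$question)) {
    idx <- which(df$question == q)
    ok <- df$value[idx] %in% coded_set(q, coding)
    if (!all(ok)) {
      row <- idx[which(!ok)[1]]
      stop("row ", row, ": value ", df$value[row],
           " is not in the coded set of question '", q, "'", call. = FALSE)
    }
  }
  key <- paste(df$patient_id, df$date, df$question, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("row ", dup[1], ": duplicate record for (",
         df$patient_id[dup[1]], ", ", df$date[dup[1]], ", ",
         df$question[dup[1]], ")", call. = FALSE)
  }
  class(df) <- c("questionnaire_table", "data.frame")
  df
}

#' Read a questionnaire CSV
#'
#' Expects comma-separated UTF-8 text with header columns
#' `patient_id,date,question` and either `answer` (labels, coded via
#' `coding`) or `value` (pre-coded numbers). If both are present, `value`
#' wins.
#'
#' @param path Path to the CSV file.
#' @inheritParams questionnaire_table
#' @return A `questionnaire_table`.
#' @export
read_questionnaire <- function(path, coding = answer_coding()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!"value" %in% names(df)) {
    if (!"answer" %in% names(df)) {
      stop("questionnaire file needs an 'answer' or 'value' column",
           call. = FALSE)
    }
    df$value <- code_answer(df$question, df$answer, coding)
  }
  questionnaire_table(df, coding)
}

sobriety_statuses <- c("no_alcohol", "alcohol_detected", "all_omitted")

#' Construct and validate a sobriety table
#'
#' Daily breathalyzer outcome per patient: `no_alcohol` (all scheduled tests
#' passed), `alcohol_detected` (at least one positive test) or `all_omitted`
#' (every scheduled test skipped). Several same-day rows collapse to one with
#' precedence `alcohol_detected > no_alcohol > all_omitted`, i.e. a single
#' positive test marks the day and a single performed test beats omission.
#' An optional `ami` column carries the Addiction Monitoring Index (0--100)
#' when the source system provides it.
#'
#' @param df Data frame with columns `patient_id`, `date`, `status` and
#'   optionally `ami`.
#' @return A `sobriety_table` data.frame with one row per (patient, date).
#' @export
sobriety_table <- function(df) {
  need <- c("patient_id", "date", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sobriety table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_ami <- "ami" %in% names(df)
  df <- as.data.frame(df)[c(need, if (has_ami) "ami")]
  df$patient_id <- as.character(df$patient_id)
  df$date <- parse_iso_date(df$date, "sobriety")
  df$status <- as.character(df$status)
  bad <- which(!df$status %in% sobriety_statuses)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown sobriety status '", df$status[bad[1]], "'",
         call. = FALSE)
  }
  if (has_ami) {
    df$ami <- as.numeric(df$ami)
    out_of_range <- which(!is.na(df$ami) & (df$ami < 0 | df$ami > 100))
    if (length(out_of_range)) {
      stop("row ", out_of_range[1], ": ami ", df$ami[out_of_range[1]],
           " outside [0, 100]", call. = FALSE)
    }
  }
  # collapse multiple same-day records by severity precedence
  sev <- c(alcohol_detected = 3, no_alcohol = 2, all_omitted = 1)
  ord <- order(df$patient_id, df$date, -sev[df$status])
  df <- df[ord, , drop = FALSE]
  key <- paste(df$patient_id, df$date, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sobriety_table", "data.frame")
  df
}

#' Read a sobriety CSV
#'
#' Columns `patient_id,date,status[,ami]`; see [sobriety_table()] for the
#' status vocabulary and same-day collapsing rule.
#'
#' @param path Path to the CSV file.
#' @return A `sobriety_table`.
#' @export
read_sobriety <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sobriety_table(df)
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) {
    return(x)
  }
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad)) {
    stop("row ", bad[1], ": malformed ", what, " date '", x[bad[1]],
         "' (expected ISO-8601 YYYY-MM-DD)", call. = FALSE)
  }
  d
}

#' Lay out a patient's records on a gapless calendar grid
#'
#' Builds the per-patient daily panel the biomarker algorithm operates on: a
#' consecutive run of calendar days from the patient's first to last active
#' day, one column per question (`NA` where unanswered), the day's sobriety
#' status and AMI (`NA` where absent) and an activity flag. "Inactive tails"
#' — leading and trailing runs of days with neither a questionnaire answer
#' nor a sobriety record — are trimmed; interior gaps are kept because the
#' missingness itself is the signal the method exploits.
#'
#' @param q_table A `questionnaire_table` (may cover many patients).
#' @param s_table A `sobriety_table` or `NULL`.
#' @param patient_id Patient to extract.
#' @return A `daily_panel`: data.frame with columns `day` (0-based index),
#'   `date`, the 11 question columns, `status`, `ami`, `active`. Attribute
#'   `patient_id` records the patient.
#' @export
build_day_grid <- function(q_table, s_table = NULL, patient_id) {
  q <- q_table[q_table$patient_id == patient_id, , drop = FALSE]
  s <- if (is.null(s_table)) NULL else {
    s_table[s_table$patient_id == patient_id, , drop = FALSE]
  }
  dates <- c(q$date, if (!is.null(s)) s$date)
  if (!length(dates)) {
    stop("no records found for patient '", patient_id, "'", call. = FALSE)
  }
  first <- min(dates)
  last <- max(dates)
  span <- seq(first, last, by = "day")
  n <- length(span)

  panel <- data.frame(day = seq_len(n) - 1L, date = span)
  for (qid in question_ids) {
    col <- rep(NA_real_, n)
    rows <- q[q$question == qid, , drop = FALSE]
    if (nrow(rows)) {
      col[as.integer(rows$date - first) + 1L] <- rows$value
    }
    panel[[qid]] <- col
  }
  panel$status <- rep(NA_character_, n)
  panel$ami <- rep(NA_real_, n)
  if (!is.null(s) && nrow(s)) {
    idx <- as.integer(s$date - first) + 1L
    panel$status[idx] <- s$status
    if ("ami" %in% names(s)) {
      panel$ami[idx] <- s$ami
    }
  }
  answered_any <- rowSums(!is.na(panel[question_ids])) > 0
  panel$active <- answered_any | !is.na(panel$status)

  # tails are trimmed by construction of the span: first/last day have a
  # record, so active[1] and active[n] are TRUE already
  structure(panel,
            patient_id = patient_id,
            class = c("daily_panel", "data.frame"))
}

#' @export
print.daily_panel <- function(x, ...) {
  n_ans <- sum(!is.na(as.matrix(x[question_ids])))
  cat("<daily_panel> patient ", attr(x, "patient_id"),
      ": ", nrow(x), " days (", format(min(x$date)), " .. ",
      format(max(x$date)), "), ", n_ans, " answers, ",
      sum(!is.na(x$status)), " sobriety records\n", sep = "")
  invisible(x)
}
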