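#' The eleven daily monitoring questions, in canonical order
#'
#' Abbreviations for the 11 questions asked once per day by the eHealth
#' system, covering wellbeing and risk/lifestyle factors plus motivation and
#' self-confidence to stay sober. All tabular layouts in this package use
#' this column order.
#'
#' @format Character vector of length 11.
#' @export
question_ids <- c(
  "HowWas", "Sleep", "Eat", "WorkSchool", "Routine",
  "Exercise", "Socialized", "Angry", "Stress", "Motivation", "SelfConf"
)

#' Questions contributing to each digital biomarker
#'
#' `webe_questions` are the nine wellbeing items behind WeBe-i;
#' `motsc_questions` the motivation and self-confidence items behind MotSC-i.
#' These are the published groupings; [assign_questions()] re-derives them
#' from data.
#'
#' @format Character vectors.
#' @export
webe_questions <- setdiff(question_ids, c("Motivation", "SelfConf"))

#' @rdname webe_questions
#' @export
motsc_questions <- c("Motivation", "SelfConf")

# Questions offering only 3 answer alternatives (coded 0/50/100).
three_alt_questions <- c("Exercise", "Socialized", "Angry")

#' Ordinal answer coding for the daily questionnaire
#'
#' Returns the label-to-value coding used by the monitoring instrument: every
#' answer alternative maps onto the 0--100 scale on the grid
#' \{0, 25, 50, 75, 100\}, higher always meaning a more positive outcome.
#' Questions with five alternatives use all five grid values; the three
#' questions with three alternatives (`Exercise`, `Socialized`, `Angry`) use
#' \{0, 50, 100\}.
#'
#' @return An object of class `answer_coding`: a named list (one element per
#'   question id) of named numeric vectors mapping answer label to coded value.
#' @examples
#' coding <- answer_coding()
#' coding$Motivation
#' @export
answer_coding <- function() {
  five <- function(l0, l25, l50, l75, l100) {
    stats::setNames(c(0, 25, 50, 75, 100), c(l0, l25, l50, l75, l100))
  }
  three <- function(l0, l50, l100) {
    stats::setNames(c(0, 50, 100), c(l0, l50, l100))
  }
  out <- list(
    HowWas     = five("Very bad", "Bad", "So-so", "Good", "Very good"),
    Sleep      = five("Very badly", "Badly", "So-so", "Well", "Very well"),
    Eat        = five("Very badly", "Badly", "So-so", "Well", "Very well"),
    WorkSchool = five("Very bad", "Bad", "So-so", "Good", "Very good"),
    Routine    = five("Very badly", "Badly", "So-so", "Well", "Very well"),
    Exercise   = three("No", "In my everyday life", "Yes"),
    Socialized = three("No", "Just shortly", "Yes"),
    Angry      = three("Lots of people", "A few people", "No one"),
    Stress     = five("Yes, very much so", "Yes, quite a bit", "Yes, a little",
                      "Not so much", "Not at all"),
    Motivation = five("Not at all", "Rather unmotivated", "A little motivated",
                      "Strongly motivated", "Very strongly motivated"),
    SelfConf   = five("Not at all", "Not so much", "I think so", "Yes, I do",
                      "Yes, without any doubt")
  )
  structure(out[question_ids], class = "answer_coding")
}

#' Code an answer label to its database value
#'
#' @param question_id Question abbreviation, one of [question_ids].
#' @param answer_label Answer alternative exactly as presented to the patient.
#' @param coding An [answer_coding()] object.
#' @return The coded value (0, 25, 50, 75 or 100). Vectorized over
#'   `question_id`/`answer_label` pairs.
#' @examples
#' code_answer("Motivation", "Very strongly motivated")  # 100
#' code_answer("Exercise", "In my everyday life")        # 50
#' @export
code_answer <- function(question_id, answer_label, coding = answer_coding()) {
  n <- max(length(question_id), length(answer_label))
  question_id <- rep_len(as.character(question_id), n)
  answer_label <- rep_len(as.character(answer_label), n)
  vapply(seq_len(n), function(i) {
    q <- question_id[i]
    l <- answer_label[i]
    map <- coding[[q]]
    if (is.null(map)) {
      stop("unknown question id '", q, "'", call. = FALSE)
    }
    if (!l %in% names(map)) {
      stop("unknown answer label '", l, "' for question '", q, "'",
           call. = FALSE)
    }
    unname(map[[l]])
  }, numeric(1))
}

#' Decode a coded value back to its answer label
#'
#' Inverse of [code_answer()]; useful for display and round-trip checks.
#'
#' @inheritParams code_answer
#' @param value Coded value from the question's value set.
#' @return The answer label.
#' @export
decode_answer <- function(question_id, value, coding = answer_coding()) {
  n <- max(length(question_id), length(value))
  question_id <- rep_len(as.character(question_id), n)
  value <- rep_len(as.numeric(value), n)
  vapply(seq_len(n), function(i) {
    map <- coding[[question_id[i]]]
    if (is.null(map)) {
      stop("unknown question id '", question_id[i], "'", call. = FALSE)
    }
    hit <- which(map == value[i])
    if (length(hit) != 1L) {
      stop("value ", value[i], " is not in the coded set of question '",
           question_id[i], "'", call. = FALSE)
    }
    names(map)[hit]
  }, character(1))
}

coded_set <- function(question_id, coding = answer_coding()) {
  unname(coding[[question_id]])
}

#' @export
print.answer_coding <- function(x, ...) {
  cat("<answer_coding> ", length(x), " questions\n", sep = "")
  for (q in names(x)) {
    cat(sprintf("  %-10s %s\n", q,
                paste(sprintf("%s=%g", names(x[[q]]), x[[q]]), collapse = ", ")))
  }
  invisible(x)
}
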