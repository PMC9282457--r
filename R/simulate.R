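#' Synthetic cohort configuration
#'
#' Describes the generative world the method assumes: each patient carries a
#' latent 3-state Markov chain (stable / deteriorating / in-event). The
#' state drives (a) the probability of engaging with the daily questionnaire
#' — engagement drops sharply during deterioration, making the missingness
#' missing-not-at-random; (b) the level of the ordinal answers — all
#' questions shift down during deterioration, motivation/self-confidence
#' most; and (c) the daily breathalyzer outcome — in-event days show
#' detected alcohol or wholesale test omission. Defaults give stable-state
#' answer levels near those seen in AUD monitoring cohorts, roughly 1–2
#' exacerbation events per patient over 120 days, and a deterioration
#' prodrome of about a week.
#'
#' @param n_patients Number of patients.
#' @param days Treatment days per patient (>= 15: start-up plus minimum
#'   history).
#' @param p_answer Probability of an answering day in the stable state.
#' @param p_question Per-question answer probability given an answering day.
#' @param answer_mult Named multipliers on `p_answer` per state
#'   (`stable`, `deteriorating`, `in_ee`).
#' @param base_mean Named baseline answer means (0--100) per question.
#' @param state_shift Named additive mean shift per state.
#' @param motsc_extra_shift Extra shift applied to Motivation/SelfConf in
#'   the two degraded states.
#' @param answer_sd Dispersion of the latent answer value before snapping to
#'   the ordinal grid.
#' @param p_s2d,p_d2e,p_d2s,p_e2s Latent-state transition probabilities
#'   (stable->deteriorating, deteriorating->in_ee, deteriorating->stable,
#'   in_ee->stable).
#' @param p_omit_stable,p_omit_det Probability of omitting all breathalyzer
#'   tests on a non-event day (stable / deteriorating).
#' @param p_alcohol_ee Probability an in-event day shows detected alcohol
#'   (otherwise all tests are omitted); in-event days are always
#'   relapse-indicating.
#' @param start_date First treatment day.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_patients = 100L, days = 120L,
                         p_answer = 0.9, p_question = 0.85,
                         answer_mult = c(stable = 1, deteriorating = 1 / 3,
                                         in_ee = 0.25),
                         base_mean = c(HowWas = 73, Sleep = 69, Eat = 71,
                                       WorkSchool = 74, Routine = 79,
                                       Exercise = 54, Socialized = 76,
                                       Angry = 91, Stress = 77,
                                       Motivation = 89, SelfConf = 91),
                         state_shift = c(stable = 0, deteriorating = -30,
                                         in_ee = -40),
                         motsc_extra_shift = -10,
                         answer_sd = 20,
                         p_s2d = 0.02, p_d2e = 0.15, p_d2s = 0.10,
                         p_e2s = 0.30,
                         p_omit_stable = 0.03, p_omit_det = 0.10,
                         p_alcohol_ee = 0.5,
                         start_date = as.Date("2023-01-01"),
                         seed = 1L) {
  probs <- c(p_answer, p_question, unname(answer_mult) * p_answer,
             p_s2d, p_d2e, p_d2s, p_e2s,
             p_omit_stable, p_omit_det, p_alcohol_ee)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities (and answer_mult * p_answer) must lie in [0, 1]",
         call. = FALSE)
  }
  if (days < 15L) {
    stop("days must be >= 15 (start-up period plus minimum history)",
         call. = FALSE)
  }
  states <- c("stable", "deteriorating", "in_ee")
  if (!all(states %in% names(answer_mult)) ||
      !all(states %in% names(state_shift))) {
    stop("answer_mult and state_shift need entries for ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  if (!all(question_ids %in% names(base_mean))) {
    stop("base_mean needs an entry per question", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_patients", "days", "p_answer", "p_question", "answer_mult",
    "base_mean", "state_shift", "motsc_extra_shift", "answer_sd",
    "p_s2d", "p_d2e", "p_d2s", "p_e2s",
    "p_omit_stable", "p_omit_det", "p_alcohol_ee", "start_date", "seed"
  )], class = "synth_config")
}

#' Zero out all state effects on the questionnaire
#'
#' Convenience for null-signal experiments: answering probability and answer
#' levels become independent of the latent state (events still happen, but
#' the questionnaire carries no information about them). Used to check that
#' the forecaster finds no signal where none exists.
#'
#' @param config A [synth_config()].
#' @return The modified config.
#' @export
null_signal_config <- function(config) {
  config$answer_mult[] <- 1
  config$state_shift[] <- 0
  config$motsc_extra_shift <- 0
  config$p_omit_det <- config$p_omit_stable
  config
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

snap_to_grid <- function(x, grid) {
  grid[max.col(-abs(outer(x, grid, "-")), ties.method = "first")]
}

simulate_states <- function(days, cfg) {
  state <- character(days)
  s <- "stable"
  for (t in seq_len(days)) {
    state[t] <- s
    u <- stats::runif(1)
    s <- switch(s,
      stable = if (u < cfg$p_s2d) "deteriorating" else "stable",
      deteriorating = if (u < cfg$p_d2e) "in_ee"
        else if (u < cfg$p_d2e + cfg$p_d2s) "stable" else "deteriorating",
      in_ee = if (u < cfg$p_e2s) "stable" else "in_ee"
    )
  }
  state
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates the questionnaire and breathalyzer tables of a cohort together
#' with the ground-truth latent states, per the world described in
#' [synth_config()]. The emitted tables pass the package's own validators,
#' so every downstream stage runs on them unchanged; the ground truth is
#' kept separate and never fed to the pipeline.
#'
#' @param config A [synth_config()].
#' @return A `synth_cohort`: list with `questionnaire`
#'   (`questionnaire_table`), `sobriety` (`sobriety_table`), `truth`
#'   (data.frame `patient_id`, `date`, `day`, `state`), `ee_starts`
#'   (data.frame `patient_id`, `day` of each true event start, where a true
#'   event is a latent in-event run of length >= 2), and `config`.
#' @export
simulate_cohort <- function(config = synth_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    ids <- sprintf("P%04d", seq_len(cfg$n_patients))
    dates <- cfg$start_date + seq_len(cfg$days) - 1L
    q_rows <- vector("list", cfg$n_patients)
    s_rows <- vector("list", cfg$n_patients)
    truth_rows <- vector("list", cfg$n_patients)
    ee_rows <- vector("list", cfg$n_patients)
    grids <- lapply(stats::setNames(question_ids, question_ids), coded_set)

    for (p in seq_len(cfg$n_patients)) {
      state <- simulate_states(cfg$days, cfg)

      # breathalyzer outcome, one scheduled record per treatment day
      status <- character(cfg$days)
      for (t in seq_len(cfg$days)) {
        if (state[t] == "in_ee") {
          status[t] <- if (stats::runif(1) < cfg$p_alcohol_ee)
            "alcohol_detected" else "all_omitted"
        } else {
          p_omit <- if (state[t] == "stable") cfg$p_omit_stable else
            cfg$p_omit_det
          status[t] <- if (stats::runif(1) < p_omit) "all_omitted" else
            "no_alcohol"
        }
      }

      # questionnaire answers: MNAR day-level engagement, then per-question
      p_day <- cfg$p_answer * cfg$answer_mult[state]
      answered_day <- stats::runif(cfg$days) < p_day
      adays <- which(answered_day)
      if (length(adays)) {
        nq <- length(question_ids)
        # long layout: one row per (answered day, question) candidate
        day_idx <- rep(adays, each = nq)
        q_idx <- rep(seq_len(nq), times = length(adays))
        keep <- stats::runif(length(day_idx)) < cfg$p_question
        day_idx <- day_idx[keep]
        q_idx <- q_idx[keep]
        qs <- question_ids[q_idx]
        st <- state[day_idx]
        mu <- cfg$base_mean[qs] + cfg$state_shift[st] +
          ifelse(qs %in% motsc_questions & st != "stable",
                 cfg$motsc_extra_shift, 0)
        latent <- pmin(pmax(stats::rnorm(length(mu), mu, cfg$answer_sd), 0),
                       100)
        val <- numeric(length(latent))
        for (j in seq_len(nq)) {
          sel <- q_idx == j
          if (any(sel)) {
            val[sel] <- snap_to_grid(latent[sel], grids[[j]])
          }
        }
        q_rows[[p]] <- data.frame(patient_id = ids[p], date = dates[day_idx],
                                  question = qs, value = val)
      }
      s_rows[[p]] <- data.frame(patient_id = ids[p], date = dates,
                                status = status)
      truth_rows[[p]] <- data.frame(patient_id = ids[p], date = dates,
                                    day = seq_len(cfg$days) - 1L,
                                    state = state)
      r <- rle(state == "in_ee")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= 2L
      if (any(keep)) {
        ee_rows[[p]] <- data.frame(patient_id = ids[p],
                                   day = starts[keep] - 1L)
      }
    }

    q_df <- do.call(rbind, q_rows[!vapply(q_rows, is.null, logical(1))])
    structure(list(
      questionnaire = questionnaire_table(q_df),
      sobriety = sobriety_table(do.call(rbind, s_rows)),
      truth = do.call(rbind, truth_rows),
      ee_starts = {
        er <- ee_rows[!vapply(ee_rows, is.null, logical(1))]
        if (length(er)) do.call(rbind, er) else
          data.frame(patient_id = character(0), day = integer(0))
      },
      config = cfg
    ), class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", x$config$n_patients, " patients x ",
      x$config$days, " days; ", nrow(x$questionnaire), " answers, ",
      nrow(x$ee_starts), " true exacerbation events (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Labels from ground-truth event starts
#'
#' Bypasses status-based event detection and labels days directly from the
#' simulator's latent in-event run starts — the reference against which
#' detection-based labeling is validated.
#'
#' @param cohort A `synth_cohort`.
#' @param look_ahead Integer pair, as in [make_labels()].
#' @return Named list (per patient id) of `label_set` objects covering days
#'   `0..days-1`.
#' @export
ground_truth_labels <- function(cohort, look_ahead = c(1L, 3L)) {
  days <- cohort$config$days
  ids <- unique(cohort$truth$patient_id)
  out <- lapply(stats::setNames(ids, ids), function(p) {
    starts <- cohort$ee_starts$day[cohort$ee_starts$patient_id == p]
    events <- data.frame(start = starts, end = starts)
    cal <- structure(list(events = events, in_ee = rep(FALSE, days),
                          n_days = days), class = "event_calendar")
    make_labels(cal, look_ahead)
  })
  out
}
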