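#' Per-day feature matrices for the three forecaster input variants
#'
#' Builds the per-day feature vectors compared in the information-loss
#' study, all scaled to \[0, 1\]:
#' \describe{
#'   \item{`raw22`}{the 11 raw answer values (missing filled with 0,
#'     divided by 100) followed by 11 answered indicators — the indicator
#'     disambiguates a true 0 from a fill;}
#'   \item{`avg4`}{mean of the motivation/self-confidence answers, an
#'     any-answer indicator for that pair, mean of the wellbeing answers,
#'     and its indicator (means divided by 100, missing mean filled with 0);}
#'   \item{`biomarker2`}{the two digital biomarkers MotSC-i and WeBe-i
#'     divided by 100 (days before a series starts are filled with 0).}
#' }
#'
#' @param panel A [build_day_grid()] panel.
#' @param biomarkers Named list with elements `motsc` and `webe`
#'   (`biomarker_series`); required for `"biomarker2"`.
#' @param feature_set One of `"raw22"`, `"avg4"`, `"biomarker2"`.
#' @return Numeric matrix (days x n_features) with feature column names.
#' @export
build_feature_rows <- function(panel, biomarkers = NULL,
                               feature_set = c("biomarker2", "avg4", "raw22")) {
  feature_set <- match.arg(feature_set)
  n <- nrow(panel)
  if (feature_set == "raw22") {
    vals <- as.matrix(panel[, question_ids, drop = FALSE])
    answered <- 1 * !is.na(vals)
    vals[is.na(vals)] <- 0
    out <- cbind(vals / 100, answered)
    colnames(out) <- c(question_ids, paste0(question_ids, "_answered"))
    return(out)
  }
  if (feature_set == "avg4") {
    motsc <- raw_daily_series(panel, motsc_questions)
    webe <- raw_daily_series(panel, webe_questions)
    out <- cbind(
      ifelse(is.na(motsc), 0, motsc / 100), 1 * !is.na(motsc),
      ifelse(is.na(webe), 0, webe / 100), 1 * !is.na(webe)
    )
    colnames(out) <- c("MotSC_mean", "MotSC_answered",
                       "WeBe_mean", "WeBe_answered")
    return(out)
  }
  if (is.null(biomarkers) || is.null(biomarkers$motsc) ||
      is.null(biomarkers$webe)) {
    stop("feature set 'biomarker2' needs biomarkers = list(motsc =, webe =)",
         call. = FALSE)
  }
  if (nrow(biomarkers$motsc) != n || nrow(biomarkers$webe) != n) {
    stop("biomarker series are not aligned to the panel", call. = FALSE)
  }
  out <- cbind(
    ifelse(is.na(biomarkers$motsc$value), 0, biomarkers$motsc$value / 100),
    ifelse(is.na(biomarkers$webe$value), 0, biomarkers$webe$value / 100)
  )
  colnames(out) <- c("MotSC_i", "WeBe_i")
  out
}

#' Windowed forecasting samples for one patient
#'
#' One sample per eligible, labeled day with at least `min_hist` days of
#' history: the feature window covers the `min(t + 1, max_hist)` most recent
#' days ending at (and including) the anchor day `t`. Windows shorter than
#' `max_hist` are later padded at the old end with an explicit mask (see
#' [pack_samples()]).
#'
#' @param features Per-day feature matrix from [build_feature_rows()].
#' @param labels A [make_labels()] `label_set` (or integer vector).
#' @param eligibility Logical per-day flags from [eligibility_mask()].
#' @param patient_id Patient identifier carried into the sample metadata.
#' @param min_hist Minimum window length in days (default 7).
#' @param max_hist Maximum window length in days (default 93).
#' @return A `forecast_samples` object: list with `windows` (list of
#'   length-varying matrices, oldest day first) and `meta` (data.frame
#'   `patient_id`, `day`, `label`).
#' @export
make_samples <- function(features, labels, eligibility, patient_id = "p",
                         min_hist = 7L, max_hist = 93L) {
  label <- if (inherits(labels, "label_set")) labels$label else
    as.integer(labels)
  n <- nrow(features)
  if (length(label) != n || length(eligibility) != n) {
    stop("features, labels and eligibility are not aligned", call. = FALSE)
  }
  anchors <- which(eligibility & !is.na(label))
  anchors <- anchors[anchors >= min_hist]  # 1-based row t+1: t >= min_hist - 1
  windows <- vector("list", length(anchors))
  for (i in seq_along(anchors)) {
    t <- anchors[i]
    from <- max(1L, t - max_hist + 1L)
    windows[[i]] <- features[from:t, , drop = FALSE]
  }
  meta <- data.frame(
    patient_id = rep(patient_id, length(anchors)),
    day = anchors - 1L,
    label = label[anchors]
  )
  structure(list(windows = windows, meta = meta,
                 n_features = ncol(features)),
            class = "forecast_samples")
}

#' Concatenate forecast samples across patients
#'
#' @param ... `forecast_samples` objects (or a single list of them).
#' @return A combined `forecast_samples` object.
#' @export
bind_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "forecast_samples")) {
    parts <- parts[[1]]
  }
  parts <- parts[vapply(parts, function(p) nrow(p$meta) > 0, logical(1))]
  if (!length(parts)) {
    stop("no samples to bind", call. = FALSE)
  }
  nf <- unique(vapply(parts, `[[`, integer(1), "n_features"))
  if (length(nf) != 1L) {
    stop("feature counts differ across sample sets", call. = FALSE)
  }
  structure(list(
    windows = do.call(c, lapply(parts, `[[`, "windows")),
    meta = do.call(rbind, lapply(parts, `[[`, "meta")),
    n_features = nf
  ), class = "forecast_samples")
}

#' @export
print.forecast_samples <- function(x, ...) {
  lens <- vapply(x$windows, nrow, integer(1))
  cat("<forecast_samples> ", length(x$windows), " samples, ",
      x$n_features, " features/day, window length ",
      if (length(lens)) paste0(min(lens), "..", max(lens)) else "-",
      ", positives ", sum(x$meta$label), "\n", sep = "")
  invisible(x)
}

#' Pack samples into padded arrays for the sequence model
#'
#' Pads every window at the old end to the longest window present and
#' builds the 3-d feature array plus a validity mask the LSTM honors
#' (masked steps carry the state through unchanged).
#'
#' @param samples A `forecast_samples` object.
#' @return List with `x` (array features x time x samples), `mask`
#'   (matrix time x samples, 1 = real day), `y` (integer labels), `meta`.
#' @export
pack_samples <- function(samples) {
  lens <- vapply(samples$windows, nrow, integer(1))
  n <- length(lens)
  t_max <- max(lens)
  f <- samples$n_features
  x <- array(0, dim = c(f, t_max, n))
  mask <- matrix(0, nrow = t_max, ncol = n)
  for (i in seq_len(n)) {
    w <- samples$windows[[i]]
    from <- t_max - lens[i] + 1L
    x[, from:t_max, i] <- t(w)
    mask[from:t_max, i] <- 1
  }
  list(x = x, mask = mask, y = samples$meta$label, meta = samples$meta)
}

#' Random patient-level partition into train / validation / test
#'
#' Splits *patients* (never days) so no patient contributes to more than one
#' partition. Either fractional (`fractions`, largest-remainder rounding) or
#' exact counts (`counts`). Deterministic given `seed`; the RNG state of the
#' session is left untouched.
#'
#' @param patient_ids Character vector of distinct patient ids.
#' @param fractions Numeric triple summing to 1 (default 0.70/0.15/0.15).
#' @param counts Optional integer triple (train, validation, test) summing
#'   to the number of patients; overrides `fractions`.
#' @param seed Integer seed for the shuffle.
#' @return Named character vector: partition (`"train"`, `"validation"`,
#'   `"test"`) per patient id.
#' @export
split_patients <- function(patient_ids, fractions = c(0.70, 0.15, 0.15),
                           counts = NULL, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  n <- length(ids)
  if (n < 3L) {
    stop("need at least 3 patients to split", call. = FALSE)
  }
  if (is.null(counts)) {
    if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
      stop("fractions must be three numbers summing to 1", call. = FALSE)
    }
    raw <- fractions * n
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1L
    }
  }
  counts <- as.integer(counts)
  if (length(counts) != 3L || sum(counts) != n || any(counts < 0L)) {
    stop("counts must be three non-negative integers summing to ", n,
         call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  shuffled <- sample(ids)
  part <- rep(c("train", "validation", "test"), times = counts)
  stats::setNames(part, shuffled)[ids]
}
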