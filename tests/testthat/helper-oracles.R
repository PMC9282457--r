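# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity with the most literal (often brute-force) method
# available and stay independent of the package's code paths.

# Literal transcription of the biomarker construction for one raw series
# (NA = unanswered day): imputation by days-since-last-answer, then the
# smoothing recursion, one day at a time.
oracle_biomarker <- function(raw, alpha) {
  n <- length(raw)
  x <- numeric(n)
  last_answered <- NA_integer_
  for (t in seq_len(n)) {
    if (!is.na(raw[t])) {
      x[t] <- raw[t]
      last_answered <- t
    } else {
      stopifnot(!is.na(last_answered))  # oracle requires an observed start
      k <- t - last_answered
      x[t] <- if (k == 1) 2 / 3 * x[last_answered]
      else if (k == 2) 1 / 3 * x[last_answered]
      else 0
    }
  }
  s <- numeric(n)
  s[1] <- x[1]
  if (n > 1) {
    for (t in 2:n) {
      s[t] <- alpha * x[t] + (1 - alpha) * s[t - 1]
    }
  }
  s
}

# Pair-counting AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counted 1/2.
oracle_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# MCC as the Pearson correlation between binary prediction and truth.
oracle_mcc <- function(pred, truth) {
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    return(0)
  }
  stats::cor(pred, truth)
}

# Varimax criterion (Kaiser-normalized) of a loadings matrix, written from
# the definition: sum over factors of the variance of squared loadings.
oracle_varimax_criterion <- function(l) {
  h <- sqrt(rowSums(l^2))
  h[h == 0] <- 1
  sq <- (l / h)^2
  sum(apply(sq, 2, stats::var) * (nrow(l) - 1) / nrow(l))
}

# Exhaustive 1-parameter varimax for k = 2: grid over the rotation angle.
oracle_varimax_k2 <- function(l, step = 1e-4) {
  angles <- seq(0, pi / 2, by = step)
  best <- -Inf
  best_rot <- l
  best_theta <- 0
  for (theta in angles) {
    r <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    cand <- l %*% r
    v <- oracle_varimax_criterion(cand)
    if (v > best) {
      best <- v
      best_rot <- cand
      best_theta <- theta
    }
  }
  list(loadings = best_rot, criterion = best, theta = best_theta)
}

# Random raw daily series with an observed first day.
random_raw_series <- function(n, p_missing = 0.4) {
  raw <- ifelse(stats::runif(n) < p_missing, NA_real_,
                stats::runif(n, 0, 100))
  raw[1] <- stats::runif(1, 0, 100)
  raw
}

# Small questionnaire/sobriety fixture tables built in code.
tiny_q_table <- function() {
  questionnaire_table(data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-04", "2020-01-02")),
    question = c("Sleep", "Motivation", "Sleep", "HowWas"),
    value = c(50, 100, 75, 25)
  ))
}

tiny_s_table <- function() {
  sobriety_table(data.frame(
    patient_id = c("p1", "p1", "p1"),
    date = as.Date(c("2020-01-01", "2020-01-02", "2020-01-03")),
    status = c("no_alcohol", "all_omitted", "alcohol_detected")
  ))
}

# Data generated from a planted orthogonal 3-factor model over the 11
# questions: block 1 = the six 5-alternative wellbeing items, block 2 =
# motivation/self-confidence (highest loadings), block 3 = the three
# 3-alternative items.
planted_factor_blocks <- function() {
  list(
    setdiff(webe_questions, c("Exercise", "Socialized", "Angry")),
    motsc_questions,
    c("Exercise", "Socialized", "Angry")
  )
}

simulate_planted_factors <- function(n = 2000, loading = 0.7,
                                     motsc_loading = 0.85) {
  blocks <- planted_factor_blocks()
  f <- matrix(stats::rnorm(n * 3), n, 3)
  x <- matrix(NA_real_, n, length(question_ids),
              dimnames = list(NULL, question_ids))
  for (b in seq_along(blocks)) {
    for (q in blocks[[b]]) {
      l <- if (b == 2) motsc_loading else loading
      x[, q] <- l * f[, b] + sqrt(1 - l^2) * stats::rnorm(n)
    }
  }
  x
}

# Synthetic forecast_samples with a monotone signal for sanity checks.
toy_sequence_samples <- function(n_pos, n_neg, signal = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(n, pos) {
    lapply(seq_len(n), function(i) {
      len <- sample(7:25, 1)
      base <- if (pos) seq(0.2, 0.2 + 0.6 * signal, length.out = len) else
        rep(0.35, len)
      matrix(pmin(pmax(base + stats::rnorm(len, 0, 0.05), 0), 1), ncol = 1)
    })
  }
  structure(list(
    windows = c(mk(n_pos, TRUE), mk(n_neg, FALSE)),
    meta = data.frame(patient_id = "p",
                      day = seq_len(n_pos + n_neg),
                      label = c(rep(1L, n_pos), rep(0L, n_neg))),
    n_features = 1L
  ), class = "forecast_samples")
}
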