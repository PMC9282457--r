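test_that("bad-day predicate counts detection and wholesale omission", {
  expect_true(daily_bad_day("alcohol_detected"))
  expect_true(daily_bad_day("all_omitted"))
  expect_false(daily_bad_day("no_alcohol"))
  expect_true(is.na(daily_bad_day(NA_character_)))
  expect_error(daily_bad_day("tipsy"), "unknown sobriety status")
})

test_that("exacerbation events are maximal bad runs of length >= 2", {
  g <- "no_alcohol"; b <- "alcohol_detected"; o <- "all_omitted"

  cal <- detect_exacerbation_events(c(g, b, b, g))
  expect_equal(cal$events, data.frame(start = 1L, end = 2L))
  expect_equal(cal$in_ee, c(FALSE, TRUE, TRUE, FALSE))

  # single bad day is no event
  expect_equal(nrow(detect_exacerbation_events(c(g, b, g))$events), 0)

  # all-bad series is one long event; omission and detection both count
  cal5 <- detect_exacerbation_events(c(b, o, b, o, b))
  expect_equal(cal5$events, data.frame(start = 0L, end = 4L))

  # two bad runs separated by one good day never merge
  cal2 <- detect_exacerbation_events(c(b, b, g, o, o))
  expect_equal(nrow(cal2$events), 2)

  # pluggable predicate: only detection counts
  cal3 <- detect_exacerbation_events(
    c(g, o, o, g), bad_day = function(s) s == "alcohol_detected")
  expect_equal(nrow(cal3$events), 0)
})

test_that("sobriety index shares the biomarker mechanics", {
  g <- "no_alcohol"; o <- "all_omitted"

  expect_equal(sobriety_index(rep(g, 10)), rep(100, 10))

  # no-alcohol then permanent omission: 2/3, 1/3, 0 then geometric smoothing
  s <- sobriety_index(c(g, rep(o, 6)), smoothing_params(0.21))
  raw <- c(100, 200 / 3, 100 / 3, 0, 0, 0, 0)
  expect_equal(s, oracle_biomarker(raw, 0.21), tolerance = 1e-9)
  expect_true(all(diff(s) < 0))

  # mixed series matches the shared brute-force oracle
  set.seed(77)
  for (rep in 1:20) {
    st <- sample(c("no_alcohol", "alcohol_detected", "all_omitted"), 30,
                 replace = TRUE, prob = c(0.6, 0.2, 0.2))
    st[1] <- "no_alcohol"
    raw <- ifelse(st == "all_omitted", NA_real_,
                  ifelse(st == "no_alcohol", 100, 0))
    expect_equal(sobriety_index(st, smoothing_params(0.21)),
                 oracle_biomarker(raw, 0.21), tolerance = 1e-9)
  }
})

test_that("labels mark days whose look-ahead window contains an event start", {
  g <- "no_alcohol"; b <- "alcohol_detected"
  status <- c(rep(g, 10), b, b, rep(g, 8))  # EE starts day 10 (0-based)
  cal <- detect_exacerbation_events(status)
  expect_equal(cal$events$start, 10L)

  l13 <- make_labels(cal, c(1, 3))
  expect_equal(which(l13$label == 1) - 1L, c(7L, 8L, 9L))
  l57 <- make_labels(cal, c(5, 7))
  expect_equal(which(l57$label == 1) - 1L, c(3L, 4L, 5L))

  # right edge: the window must fit inside the panel
  expect_true(all(is.na(l13$label[18:20])))
  expect_false(anyNA(l13$label[1:17]))

  # no events -> all defined labels are 0
  l0 <- make_labels(detect_exacerbation_events(rep(g, 15)), c(1, 3))
  expect_true(all(l0$label[!is.na(l0$label)] == 0))

  expect_error(make_labels(cal, c(2, 4)), "allow_custom")
  l24 <- make_labels(cal, c(2, 4), allow_custom = TRUE)
  expect_equal(which(l24$label == 1) - 1L, c(6L, 7L, 8L))
})

test_that("label prevalence matches a brute-force scan on random series", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    status <- sample(c("no_alcohol", "alcohol_detected", "all_omitted"), n,
                     replace = TRUE, prob = c(0.7, 0.15, 0.15))
    cal <- detect_exacerbation_events(status)
    lab <- make_labels(cal, c(1, 3))$label
    starts <- cal$events$start
    brute <- vapply(seq_len(n) - 1L, function(t) {
      if (t + 3 > n - 1) return(NA_integer_)
      as.integer(any(starts %in% (t + 1):(t + 3)))
    }, integer(1))
    expect_identical(lab, brute)
  }
})

test_that("eligibility excludes start-up, in-event and low/missing-AMI days", {
  g <- "no_alcohol"; b <- "alcohol_detected"
  status <- c(rep(g, 9), b, b, rep(g, 14))
  cal <- detect_exacerbation_events(status)
  ami <- rep(80, 25)
  elig <- eligibility_mask(cal, ami)

  expect_false(any(elig[1:7]))           # days 0..6: start-up
  expect_true(elig[8])                   # day 7 is the first eligible
  expect_false(elig[10] || elig[11])     # in-event days, despite high AMI

  # AMI threshold is inclusive at 40
  ami2 <- ami; ami2[21] <- 39; ami2[22] <- 40
  elig2 <- eligibility_mask(cal, ami2)
  expect_false(elig2[21])
  expect_true(elig2[22])

  # missing AMI -> ineligible
  ami3 <- ami; ami3[20] <- NA
  expect_false(eligibility_mask(cal, ami3)[20])

  expect_error(eligibility_mask(cal, ami[1:10]), "does not match")
})

test_that("eligibility and labels commute with right-edge truncation", {
  set.seed(123)
  status <- sample(c("no_alcohol", "alcohol_detected", "all_omitted"), 60,
                   replace = TRUE, prob = c(0.75, 0.1, 0.15))
  idx <- sobriety_index(status)
  full_cal <- detect_exacerbation_events(status)
  full_lab <- make_labels(full_cal, c(1, 3))$label
  full_elig <- eligibility_mask(full_cal, idx)
  # truncate the panel at day 40: everything up to day 36 (= 40 - hi - 1,
  # where labels are defined in both) must be unchanged
  tr_cal <- detect_exacerbation_events(status[1:40])
  tr_lab <- make_labels(tr_cal, c(1, 3))$label
  tr_elig <- eligibility_mask(tr_cal, sobriety_index(status[1:40]))
  keep <- 1:36
  expect_identical(tr_lab[keep], full_lab[keep])
  expect_identical(tr_elig[keep], full_elig[keep])
})
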