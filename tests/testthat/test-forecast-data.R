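make_test_panel <- function(days = 30, seed = 3) {
  co <- simulate_cohort(synth_config(n_patients = 1, days = days, seed = seed))
  build_day_grid(co$questionnaire, co$sobriety, "P0001")
}

test_that("feature rows follow the three published layouts", {
  q <- questionnaire_table(data.frame(
    patient_id = "p",
    date = as.Date("2020-01-01") + c(rep(0, 11), 1, 1),
    question = c(question_ids, "Motivation", "SelfConf"),
    value = c(rep(100, 11), 100, 50)
  ))
  s <- sobriety_table(data.frame(patient_id = "p",
                                 date = as.Date("2020-01-01") + 0:2,
                                 status = "no_alcohol"))
  panel <- build_day_grid(q, s, "p")

  r <- build_feature_rows(panel, feature_set = "raw22")
  expect_equal(dim(r), c(3, 22))
  expect_equal(unname(r[1, ]), c(rep(1, 11), rep(1, 11)))  # all answered at 100
  expect_equal(unname(r[3, ]), rep(0, 22))                 # unanswered day

  a <- build_feature_rows(panel, feature_set = "avg4")
  expect_equal(dim(a), c(3, 4))
  # day 2: Motivation 100, SelfConf 50, no wellbeing answers
  expect_equal(unname(a[2, ]), c(0.75, 1, 0, 0))

  bm <- list(motsc = build_biomarker(panel, motsc_questions),
             webe = build_biomarker(panel, webe_questions))
  b <- build_feature_rows(panel, bm, "biomarker2")
  expect_equal(dim(b), c(3, 2))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(unname(b[1, "MotSC_i"]), 1)

  expect_error(build_feature_rows(panel, NULL, "biomarker2"), "needs")
})

test_that("sample windows respect history bounds and anchor alignment", {
  panel <- make_test_panel(days = 130)
  feats <- build_feature_rows(panel, feature_set = "avg4")
  n <- nrow(feats)
  labels <- rep(0L, n)
  eligible <- rep(TRUE, n)

  s <- make_samples(feats, labels, eligible, patient_id = "P0001")
  lens <- vapply(s$windows, nrow, integer(1))
  expect_true(all(lens >= 7 & lens <= 93))
  # eligible day at t = 5 yields no sample; no anchor below day 6
  expect_true(min(s$meta$day) >= 6)
  # day 100 has a window of exactly 93 days ending at the anchor
  i <- which(s$meta$day == 100)
  expect_equal(nrow(s$windows[[i]]), 93)
  expect_equal(s$windows[[i]][93, ], feats[101, ])
  expect_equal(s$windows[[i]][1, ], feats[9, ])

  # all-ineligible patient -> zero samples
  s0 <- make_samples(feats, labels, rep(FALSE, n))
  expect_equal(length(s0$windows), 0)

  # NA labels (unfittable look-ahead) never become samples
  labels2 <- labels; labels2[50:60] <- NA
  s2 <- make_samples(feats, labels2, eligible)
  expect_false(any(s2$meta$day %in% 49:59))
})

test_that("no temporal leakage: windows end at the anchor day", {
  panel <- make_test_panel(days = 60, seed = 9)
  feats <- build_feature_rows(panel, feature_set = "raw22")
  cal <- detect_exacerbation_events(panel$status)
  lab <- make_labels(cal, c(1, 3))
  elig <- eligibility_mask(cal, sobriety_index(panel$status))
  s <- make_samples(feats, lab, elig)
  for (i in seq_along(s$windows)) {
    t <- s$meta$day[i]
    w <- s$windows[[i]]
    # the window rows are exactly the feature rows of days <= t
    expect_equal(w, feats[(t + 1 - nrow(w) + 1):(t + 1), , drop = FALSE])
  }
})

test_that("packing pads at the old end with a correct mask", {
  s <- toy_sequence_samples(3, 3, seed = 21)
  pk <- pack_samples(s)
  t_max <- dim(pk$x)[2]
  lens <- vapply(s$windows, nrow, integer(1))
  for (i in seq_along(lens)) {
    expect_equal(sum(pk$mask[, i]), lens[i])
    # padding strictly precedes data
    expect_equal(pk$mask[, i], c(rep(0, t_max - lens[i]), rep(1, lens[i])))
    expect_equal(pk$x[1, (t_max - lens[i] + 1):t_max, i],
                 as.numeric(s$windows[[i]]))
  }
})

test_that("patient split is disjoint, deterministic and exact", {
  ids <- sprintf("pt%03d", 1:97)
  part <- split_patients(ids, seed = 42)
  expect_setequal(names(part), ids)
  expect_equal(anyDuplicated(names(part)), 0)
  expect_equal(unname(table(part)[c("train", "validation", "test")]),
               c(68, 15, 14), ignore_attr = TRUE)

  # same seed -> identical; different seed -> (almost surely) different
  expect_identical(part, split_patients(ids, seed = 42))
  expect_false(identical(part, split_patients(ids, seed = 43)))

  # exact-counts mode reproduces a 527/112/112 design
  ids751 <- sprintf("pt%03d", 1:751)
  p751 <- split_patients(ids751, counts = c(527, 112, 112), seed = 1)
  expect_equal(unname(table(p751)[c("train", "validation", "test")]),
               c(527, 112, 112), ignore_attr = TRUE)

  expect_error(split_patients(ids, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(split_patients(ids[1:2]), "at least 3")
  # split does not disturb the session RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(split_patients(ids, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})
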