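test_that("answer coding matches the instrument's value grid", {
  coding <- answer_coding()
  expect_named(coding, question_ids)

  expect_equal(code_answer("Motivation", "Very strongly motivated"), 100)
  expect_equal(code_answer("Exercise", "In my everyday life"), 50)
  expect_equal(code_answer("Sleep", "So-so"), 50)
  expect_equal(code_answer("Angry", "No one"), 100)
  expect_equal(code_answer("Stress", "Yes, very much so"), 0)

  # 5-alternative questions span the full grid; 3-alternative ones {0,50,100}
  for (q in question_ids) {
    vals <- sort(unname(coding[[q]]))
    if (q %in% c("Exercise", "Socialized", "Angry")) {
      expect_equal(vals, c(0, 50, 100), info = q)
    } else {
      expect_equal(vals, c(0, 25, 50, 75, 100), info = q)
    }
  }

  expect_error(code_answer("Sleep", "Amazing"), "unknown answer label")
  expect_error(code_answer("Mood", "Good"), "unknown question")
})

test_that("coding round-trips through decode for every label", {
  coding <- answer_coding()
  for (q in question_ids) {
    for (label in names(coding[[q]])) {
      v <- code_answer(q, label, coding)
      expect_identical(decode_answer(q, v, coding), label)
    }
  }
})

test_that("questionnaire reading validates values, dates and duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,date,question,answer",
    "p1,2020-01-01,Sleep,Well",
    "p1,2020-01-01,Motivation,Very strongly motivated",
    "p1,2020-01-02,Sleep,So-so"
  ), path)
  tab <- read_questionnaire(path)
  expect_s3_class(tab, "questionnaire_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$value, c(75, 100, 50))

  # out-of-set coded value
  writeLines(c(
    "patient_id,date,question,value",
    "p1,2020-01-01,HowWas,37"
  ), path)
  expect_error(read_questionnaire(path), "not in the coded set")

  # duplicate (patient, date, question)
  writeLines(c(
    "patient_id,date,question,value",
    "p1,2020-01-01,Sleep,50",
    "p1,2020-01-01,Sleep,75"
  ), path)
  expect_error(read_questionnaire(path), "duplicate")

  # malformed date names the row
  writeLines(c(
    "patient_id,date,question,value",
    "p1,01/02/2020,Sleep,50"
  ), path)
  expect_error(read_questionnaire(path), "malformed")
})

test_that("sobriety reading collapses same-day tests by severity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,date,status",
    "p1,2020-01-01,no_alcohol",
    "p1,2020-01-01,alcohol_detected",
    "p1,2020-01-02,all_omitted",
    "p1,2020-01-02,no_alcohol"
  ), path)
  tab <- read_sobriety(path)
  expect_equal(nrow(tab), 2)
  # one detected test marks the day; one performed test beats omission
  expect_equal(tab$status, c("alcohol_detected", "no_alcohol"))

  writeLines(c("patient_id,date,status", "p1,2020-01-01,drunk"), path)
  expect_error(read_sobriety(path), "unknown sobriety status")

  writeLines(c("patient_id,date,status,ami",
               "p1,2020-01-01,no_alcohol,140"), path)
  expect_error(read_sobriety(path), "outside")
})

test_that("day grid is gapless, 0-indexed and trims only the tails", {
  q <- tiny_q_table()
  s <- tiny_s_table()

  # answers on days d and d+3 -> 4-day grid with 2 all-missing middle days
  p1 <- build_day_grid(q, NULL, "p1")
  expect_equal(nrow(p1), 4)
  expect_equal(p1$day, 0:3)
  expect_equal(p1$Sleep, c(50, NA, NA, 75))
  expect_false(any(p1$active[c(2, 3)]))
  expect_true(all(p1$active[c(1, 4)]))

  # single answered day -> length-1 grid
  p2 <- build_day_grid(q, NULL, "p2")
  expect_equal(nrow(p2), 1)
  expect_equal(p2$HowWas, 25)

  # stray record far in the future extends the span; no interior trimming
  q3 <- questionnaire_table(data.frame(
    patient_id = "p3",
    date = as.Date("2021-01-01") + c(0:5, 205),
    question = "Sleep", value = 50
  ))
  p3 <- build_day_grid(q3, NULL, "p3")
  expect_equal(nrow(p3), 206)

  expect_error(build_day_grid(q, s, "nobody"), "no records")

  # sobriety records count as activity and carry status/ami onto the grid
  p1s <- build_day_grid(q, s, "p1")
  expect_equal(p1s$status[1:3], c("no_alcohol", "all_omitted",
                                  "alcohol_detected"))
})

test_that("panel invariants hold on simulated cohorts", {
  co <- simulate_cohort(synth_config(n_patients = 6, days = 30, seed = 42))
  for (p in unique(co$sobriety$patient_id)) {
    panel <- build_day_grid(co$questionnaire, co$sobriety, p)
    # grid length = last - first active date + 1
    expect_equal(nrow(panel),
                 as.integer(max(panel$date) - min(panel$date)) + 1L)
    expect_equal(panel$day, seq_len(nrow(panel)) - 1L)
    # non-missing cells equal the patient's records
    n_ans <- sum(!is.na(as.matrix(panel[question_ids])))
    expect_equal(n_ans, sum(co$questionnaire$patient_id == p))
    expect_equal(sum(!is.na(panel$status)),
                 sum(co$sobriety$patient_id == p))
    # tails trimmed: first and last day active
    expect_true(panel$active[1] && panel$active[nrow(panel)])
  }
})
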