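# Rotated factor loadings reported for the 11-question instrument on the
# clinical cohort; used as a worked input for the assignment step.
reference_rotated_loadings <- function() {
  m <- rbind(
    HowWas     = c(0.79, 0.19,  0.21),
    Stress     = c(0.72, 0.27, -0.09),
    Eat        = c(0.74, 0.04,  0.18),
    Routine    = c(0.62, 0.27,  0.19),
    WorkSchool = c(0.67, 0.17,  0.16),
    Sleep      = c(0.71, 0.06,  0.17),
    Motivation = c(0.26, 0.85,  0.08),
    Socialized = c(0.12, 0.09,  0.74),
    SelfConf   = c(0.15, 0.89,  0.06),
    Angry      = c(0.54, 0.10, -0.37),
    Exercise   = c(0.19, 0.05,  0.70)
  )
  colnames(m) <- paste0("Factor", 1:3)
  m
}

test_that("complete-day selection keeps only fully answered patient-days", {
  mk_day <- function(p, d, qs) {
    data.frame(patient_id = p, date = as.Date("2020-01-01") + d,
               question = qs, value = 50)
  }
  q <- questionnaire_table(rbind(
    mk_day("a", 0, question_ids),            # complete
    mk_day("a", 1, question_ids[1:5]),       # partial
    mk_day("b", 0, question_ids),            # complete
    mk_day("b", 1, "Sleep"),                 # partial
    mk_day("b", 2, question_ids[-1])         # partial (10 of 11)
  ))
  m <- select_complete_days(q)
  expect_equal(nrow(m), 2)
  expect_equal(colnames(m), question_ids)
  expect_false(anyNA(m))

  q_partial <- questionnaire_table(mk_day("c", 0, "Sleep"))
  expect_equal(nrow(select_complete_days(q_partial)), 0)
})

test_that("correlation-matrix PCA has the expected eigenstructure", {
  set.seed(11)
  # independent standardized columns: all eigenvalues near 1
  x <- matrix(rnorm(20000 * 11), ncol = 11,
              dimnames = list(NULL, question_ids))
  pc <- principal_components(x, k = 11)
  expect_equal(pc$eigenvalues, rep(1, 11), tolerance = 0.05)
  expect_equal(sum(pc$eigenvalues), 11, tolerance = 1e-8)

  # two perfectly correlated columns: eigenvalues (2, 0)
  z <- rnorm(500)
  pc2 <- principal_components(cbind(a = z, b = 2 * z), k = 2)
  expect_equal(pc2$eigenvalues, c(2, 0), tolerance = 1e-10)

  # loadings scaled so squared loadings per component sum to the eigenvalue
  x3 <- simulate_planted_factors(800)
  pc3 <- principal_components(x3, k = 3)
  expect_equal(colSums(pc3$loadings^2),
               unname(pc3$eigenvalues[1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(principal_components(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero variance")
})

test_that("planted 2-block structure is recovered by the loadings", {
  set.seed(12)
  n <- 3000
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(
    v1 = 0.8 * f1 + 0.6 * rnorm(n), v2 = 0.8 * f1 + 0.6 * rnorm(n),
    v3 = 0.8 * f2 + 0.6 * rnorm(n), v4 = 0.8 * f2 + 0.6 * rnorm(n)
  )
  pc <- principal_components(x)
  expect_equal(pc$k, 2)
  rot <- varimax_rotate(pc)
  best <- apply(abs(rot$loadings), 1, which.max)
  expect_equal(length(unique(best[1:2])), 1)
  expect_equal(length(unique(best[3:4])), 1)
  expect_false(best[1] == best[3])
})

test_that("varimax rotation is orthonormal, preserves communalities and
           matches the k = 2 grid-search oracle", {
  set.seed(13)
  x <- simulate_planted_factors(1500)
  pc <- principal_components(x, k = 3)
  rot <- varimax_rotate(pc)

  # orthonormal rotation matrix
  expect_equal(crossprod(rot$rotmat), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # communalities unchanged
  expect_equal(rowSums(rot$loadings^2), rowSums(pc$loadings^2),
               tolerance = 1e-8)

  # perfect simple structure is left alone (up to sign/permutation)
  simple <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.8), c(0, 0.95))
  r <- varimax_rotate(simple)
  recovered <- abs(r$loadings)
  expect_equal(sort(recovered[recovered > 0.5]),
               sort(c(0.9, 0.85, 0.8, 0.95)), tolerance = 1e-6)
  expect_lt(max(recovered[recovered < 0.5]), 1e-6)

  # k = 2: exhaustive angle search agrees to 1e-4
  l2 <- pc$loadings[, 1:2]
  got <- varimax_rotate(l2)
  oracle <- oracle_varimax_k2(l2, step = 1e-4)
  expect_lt(abs(got$criterion - oracle$criterion), 1e-4)
  # same optimum up to column sign/permutation: the objective is flat near
  # its maximum, so agreement of the criterion to 1e-4 only pins the angle
  # (hence the loadings) to a few 1e-3 — this bound detects a wrong
  # optimum, not rounding
  align <- function(m) m[, order(-colSums(m^2)), drop = FALSE]
  expect_lt(max(abs(abs(align(got$loadings)) - abs(align(oracle$loadings)))),
            0.01)

  expect_error(varimax_rotate(pc$loadings[, 1, drop = FALSE]),
               "at least 2")
})

test_that("question assignment reproduces the deployed grouping from the
           reference rotated loadings", {
  defs <- assign_questions(reference_rotated_loadings())
  expect_named(defs, c("WeBe-i", "MotSC-i"))
  expect_setequal(defs[["MotSC-i"]]$questions, c("Motivation", "SelfConf"))
  expect_setequal(defs[["WeBe-i"]]$questions, webe_questions)

  # one-factor-per-biomarker map gives three disjoint definitions
  defs3 <- assign_questions(reference_rotated_loadings(),
                            merge_map = list(A = 1L, B = 2L, C = 3L))
  qs <- lapply(defs3, `[[`, "questions")
  expect_equal(length(unlist(qs)), 11)
  expect_equal(anyDuplicated(unlist(qs)), 0)

  # tie in absolute loadings goes to the lowest factor index
  tie <- rbind(Sleep = c(0.5, -0.5, 0.1), Motivation = c(0.2, 0.6, 0.1))
  d <- assign_questions(tie, merge_map = list(A = 1L, B = 2L, C = 3L))
  expect_equal(d$A$questions, "Sleep")

  expect_error(assign_questions(reference_rotated_loadings(),
                                merge_map = list(A = 5L)),
               "outside")
})
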