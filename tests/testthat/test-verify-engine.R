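test_that("question generation follows the reference trace", {
  g <- demo_guideline()
  case <- demo_cases()$demo_case_n2a
  qs <- make_questions(g, case, seed = 42L)
  kinds <- vapply(qs, `[[`, character(1), "kind")
  expect_identical(kinds, c("next_action", "next_action", "data_items",
                            "decision_outcome", "next_action", "data_items",
                            "decision_outcome"))
  # the N decision question offers every conclusion successor
  nq <- qs[[which(vapply(qs, `[[`, character(1), "node") == "evaluation_of_n")]]
  ids <- vapply(nq$options, `[[`, character(1), "id")
  expect_setequal(ids, c("n0", "n1a", "n2a", "n3a"))
  expect_identical(nq$correct, "n2a")
  # choice questions have >= 2 options including the key, duplicate-free
  for (q in qs) {
    if (q$kind != "data_items") {
      oids <- vapply(q$options, `[[`, character(1), "id")
      expect_gte(length(oids), 2L)
      expect_true(q$correct %in% oids)
      expect_identical(anyDuplicated(oids), 0L)
    }
  }
  # next_action distractors come from the same hierarchy level
  q1 <- qs[[2]]  # dermoscopy, inside the assessment composite
  expect_identical(q1$node, "dermoscopy")
  expect_true(all(vapply(q1$options, `[[`, character(1), "id") %in%
                  c("dermoscopy", "biopsy_report")))
  # determinism in the seed
  expect_identical(make_questions(g, case, seed = 42L), qs)
  expect_error(make_questions(g, case_study("empty"), seed = 1L),
               class = "cig_blocked")
})

test_that("a guideline of only work nodes yields only next_action questions", {
  g <- straight_line_guideline(4)
  qs <- make_questions(g, case_study("c", guideline_id = "line"), seed = 1L)
  expect_length(qs, 4L)
  expect_true(all(vapply(qs, `[[`, character(1), "kind") == "next_action"))
})

test_that("answer checking uses set semantics and attaches explanations", {
  g <- demo_guideline()
  case <- demo_cases()$demo_case_n2a
  qs <- make_questions(g, case, seed = 42L)
  dq <- qs[[which(vapply(qs, `[[`, character(1), "kind") == "data_items")[1]]]
  # reversed order is still correct
  r <- check_answer(dq, rev(dq$correct))
  expect_true(r$correct)
  expect_identical(r$category, "required_data")
  expect_false(check_answer(dq, dq$correct[-1])$correct)
  expect_false(check_answer(dq, character())$correct)
  expect_false(check_answer(dq, c(dq$correct, "extra_item"))$correct)

  nq <- qs[[which(vapply(qs, `[[`, character(1), "node") == "evaluation_of_n")]]
  wrong <- check_answer(nq, "n3a")
  expect_false(wrong$correct)
  expect_s3_class(wrong$explanation, "cig_explanation")
  expect_identical(wrong$explanation$correct_leaf, "n2a")
  expect_identical(wrong$explanation$learner_leaf, "n3a")
  right <- check_answer(nq, "n2a")
  expect_true(right$correct)
  expect_null(right$explanation)
  # wrong next_action answers carry no explanation
  aq <- qs[[1]]
  other <- setdiff(vapply(aq$options, `[[`, character(1), "id"), aq$correct)[1]
  expect_null(check_answer(aq, other)$explanation)
  expect_error(check_answer(nq, c("n1a", "n2a")), class = "cig_format_error")
  expect_error(check_answer(dq, list(1, 2)), class = "cig_format_error")
})

test_that("perfect, adversarial and mixed scripts score as expected", {
  g <- demo_guideline()
  case <- demo_cases()$demo_case_n2a
  qs <- make_questions(g, case, seed = 7L)

  s <- run_session(g, case, perfect_answers(qs), seed = 7L)
  expect_true(all(s$summary$percent == 100.0))
  expect_setequal(s$summary$category,
                  c("activities", "required_data", "decisions"))

  s0 <- run_session(g, case, adversarial_answers(qs), seed = 7L)
  expect_true(all(s0$summary$percent == 0.0))

  # exactly one wrong decision: decisions percent = 100 (d-1)/d
  mixed <- perfect_answers(qs)
  di <- which(vapply(qs, `[[`, character(1), "kind") == "decision_outcome")
  d <- length(di)
  mixed[[di[1]]] <- adversarial_answers(qs)[[di[1]]]
  sm <- run_session(g, case, mixed, seed = 7L)
  expect_identical(sm$summary$percent[sm$summary$category == "decisions"],
                   cigsim:::round_half_up(100 * (d - 1) / d, 1))
  expect_true(all(sm$summary$percent[sm$summary$category != "decisions"] == 100))
  # discrepancy count = wrong results; decision discrepancies = explanations
  wrongs <- Filter(function(r) !r$correct, sm$results)
  expect_length(wrongs, 1L)
  expect_length(Filter(function(r) !is.null(r$explanation), sm$results), 1L)

  expect_error(run_session(g, case, mixed[-1], seed = 7L),
               class = "cig_format_error")

  # a callback is asked once per question, in order
  seen <- character()
  cb <- function(q) { seen <<- c(seen, q$kind); q$correct }
  sc <- run_session(g, case, cb, seed = 7L)
  expect_identical(seen, vapply(qs, `[[`, character(1), "kind"))
  expect_true(all(sc$summary$percent == 100))
})

test_that("summaries aggregate per category with one-decimal percentages", {
  empty <- structure(list(results = list()), class = "cig_verification")
  expect_identical(nrow(summarize_session(empty)), 0L)

  fake_result <- function(cat, ok) {
    structure(list(question = NULL, answer = NULL, correct = ok,
                   explanation = NULL, category = cat),
              class = "cig_step_result")
  }
  s <- structure(list(results = c(
    lapply(c(TRUE, TRUE, FALSE, FALSE), function(ok) fake_result("activities", ok)),
    list(fake_result("decisions", TRUE)))), class = "cig_verification")
  sum <- summarize_session(s)
  expect_identical(sum$percent[sum$category == "activities"], 50.0)
  expect_identical(sum$n_total[sum$category == "activities"], 4L)
  expect_false("required_data" %in% sum$category)
})

test_that("session reports list each discrepancy with its explanation", {
  g <- demo_guideline()
  case <- demo_cases()$demo_case_n2a
  qs <- make_questions(g, case, seed = 7L)
  answers <- perfect_answers(qs)
  ni <- which(vapply(qs, `[[`, character(1), "node") == "evaluation_of_n")
  answers[[ni]] <- "n3a"
  s <- run_session(g, case, answers, seed = 7L)
  report <- format_session_report(s)
  expect_match(report, "Discrepancies:")
  expect_match(report, "num_positive_nodes = 3 satisfies")
  expect_match(report, "\\[X\\] n3a")
  expect_match(report, "\\[\\*\\] n2a")
})
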