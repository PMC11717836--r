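# Learner verification: question generation along the reference trace,
# answer checking, explanations for wrong decisions, per-category scoring.
#
# The reference path is fixed by the case data (the same path the automated
# simulation takes); learner answers are compared step-by-step against it
# and never alter the subsequent questions. Question kinds map onto scoring
# categories: next_action -> activities, data_items -> required_data,
# decision_outcome -> decisions.

QUESTION_CATEGORY <- c(next_action = "activities",
                       data_items = "required_data",
                       decision_outcome = "decisions")

#' Generate the verification questions for a case
#'
#' Walks the reference simulation trace. Before each work or composite
#' action a `next_action` multiple-choice question is emitted (the correct
#' node plus up to three seeded distractor actions drawn from the same
#' hierarchy level, option order shuffled); each data request yields a
#' `data_items` question whose key is the node's requested parameter set
#' (free entry, no options); each decision yields a `decision_outcome`
#' question over all conclusion successors.
#'
#' @param g a valid guideline.
#' @param case a complete case study.
#' @param seed integer; fixes distractor choice and option order.
#' @return list of `cig_question` objects.
#' @export
make_questions <- function(g, case, seed = 0L) {
  tr <- simulate_case(g, case)
  if (!identical(tr$status, "completed")) {
    cig_abort(sprintf("cannot quiz on an incomplete case (%s at '%s')",
                      tr$reason, tr$location), "cig_blocked")
  }
  levels <- level_subgraphs(g)
  questions <- list()
  env <- list()
  with_seed(seed, {
    for (i in seq_along(tr$steps)) {
      st <- tr$steps[[i]]
      sg <- levels[[st$level]]
      n <- sg$nodes[[st$node]]
      q <- NULL
      if (st$kind %in% c("work", "descend")) {
        pool <- Filter(function(m) {
          !identical(m$id, st$node) && !identical(m$kind, "conclusion")
        }, sg$nodes)
        k <- min(3L, length(pool))
        distractors <- if (k > 0) sample(pool, k) else list()
        opts <- c(list(list(id = n$id, label = n$label)),
                  lapply(distractors, function(m) list(id = m$id, label = m$label)))
        opts <- sample(opts, length(opts))
        q <- new_question("next_action", i, n,
                          prompt = "Which action should be performed next?",
                          options = opts, correct = n$id)
      } else if (identical(st$kind, "data_request")) {
        q <- new_question("data_items", i, n,
                          prompt = sprintf(
                            "Which data items must be collected at '%s'?", n$label),
                          options = list(), correct = n$requests)
      } else if (identical(st$kind, "decision")) {
        concl <- successors(sg, n$id)
        opts <- lapply(concl, function(cid) {
          list(id = cid, label = sg$nodes[[cid]]$label)
        })
        q <- new_question("decision_outcome", i, n,
                          prompt = sprintf(
                            "Given the case data so far, what is the outcome of '%s'?",
                            n$label),
                          options = opts, correct = st$payload$leaf,
                          tree = n$tree, data = env)
      }
      if (identical(st$kind, "data_request")) {
        for (p in names(st$payload)) env[[p]] <- st$payload[[p]]
      }
      if (!is.null(q)) questions[[length(questions) + 1L]] <- q
    }
  })
  questions
}

new_question <- function(kind, step_index, node, prompt, options, correct,
                         tree = NULL, data = NULL) {
  structure(list(kind = kind, step_index = step_index, node = node$id,
                 label = node$label, prompt = prompt, options = options,
                 correct = correct, tree = tree, data = data),
            class = "cig_question")
}

#' @export
print.cig_question <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$kind, x$prompt))
  for (o in x$options) cat(sprintf("  - %s (%s)\n", o$label, o$id))
  invisible(x)
}

# Named list: "top" and every composite id -> its subgraph.
level_subgraphs <- function(g) {
  out <- list(top = g$body)
  rec <- function(sg) {
    for (n in sg$nodes) {
      if (identical(n$kind, "composite")) {
        out[[n$id]] <<- n$body
        rec(n$body)
      }
    }
  }
  rec(g$body)
  out
}

#' Check a learner's answer to one question
#'
#' Selection questions are correct iff the chosen id equals the hidden key;
#' `data_items` answers are compared as sets (order-insensitive exact
#' equality with the requested parameter set, no partial credit). A wrong
#' `decision_outcome` answer gets a [explain_decision()] explanation
#' attached; other wrong answers carry none.
#'
#' @param q a `cig_question`.
#' @param answer a single option id (`next_action`, `decision_outcome`) or
#'   a character vector of parameter names (`data_items`; may be empty).
#' @return object of class `cig_step_result`: `question`, `answer`,
#'   `correct`, `explanation` (or `NULL`), `category`.
#' @export
check_answer <- function(q, answer) {
  if (identical(q$kind, "data_items")) {
    if (!is.character(answer) && !(is.null(answer) || length(answer) == 0)) {
      cig_abort("data_items answer must be a character vector of parameter names",
                "cig_format_error")
    }
    answer <- as.character(answer %||% character())
    correct <- setequal(answer, q$correct)
    expl <- NULL
  } else {
    if (!is.character(answer) || length(answer) != 1) {
      cig_abort(sprintf("%s answer must be a single option id", q$kind),
                "cig_format_error")
    }
    correct <- identical(answer, q$correct)
    expl <- if (identical(q$kind, "decision_outcome") && !correct) {
      explain_decision(q$tree, q$data, answer)
    }
  }
  structure(list(question = q, answer = answer, correct = correct,
                 explanation = expl,
                 category = QUESTION_CATEGORY[[q$kind]]),
            class = "cig_step_result")
}

#' Run a full verification session
#'
#' Generates the question list for the case, pairs it with the learner's
#' answers in order, checks each, and attaches the per-category score
#' summary. Scripted answers must cover every question; the length is
#' checked before any answer is graded.
#'
#' @param g a valid guideline.
#' @param case a complete case study.
#' @param answers either a list of answers (one per question, in order) or
#'   a callback `function(question)` returning the answer.
#' @param seed integer passed to [make_questions()].
#' @return object of class `cig_verification`: `guideline_id`, `case_id`,
#'   `seed`, `results` (list of `cig_step_result`), `summary` (a
#'   `cig_score_summary`).
#' @export
run_session <- function(g, case, answers, seed = 0L) {
  qs <- make_questions(g, case, seed)
  if (!is.function(answers)) {
    if (length(answers) != length(qs)) {
      cig_abort(sprintf("scripted answers (%d) do not match questions (%d)",
                        length(answers), length(qs)), "cig_format_error")
    }
  }
  results <- vector("list", length(qs))
  for (i in seq_along(qs)) {
    a <- if (is.function(answers)) answers(qs[[i]]) else answers[[i]]
    results[[i]] <- check_answer(qs[[i]], a)
  }
  session <- structure(list(guideline_id = g$id, case_id = case$id,
                            seed = as.integer(seed), results = results),
                       class = "cig_verification")
  session$summary <- summarize_session(session)
  session
}

#' Per-category score summary of a verification session
#'
#' Counts correct answers per category (activities, required_data,
#' decisions) and reports percentages to one decimal (half-up). Categories
#' with no questions are absent from the summary.
#'
#' @param s a `cig_verification`.
#' @return object of class `cig_score_summary`: a data frame with columns
#'   `category`, `n_correct`, `n_total`, `percent`.
#' @export
summarize_session <- function(s) {
  cats <- vapply(s$results, `[[`, character(1), "category")
  oks <- vapply(s$results, `[[`, logical(1), "correct")
  present <- intersect(unname(QUESTION_CATEGORY), unique(cats))
  out <- data.frame(category = present,
                    n_correct = vapply(present, function(cc) sum(oks[cats == cc]),
                                       integer(1)),
                    n_total = vapply(present, function(cc) sum(cats == cc),
                                     integer(1)),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$n_correct / pmax(out$n_total, 1L), 1)
  rownames(out) <- NULL
  structure(out, class = c("cig_score_summary", "data.frame"))
}

#' Render a verification session report
#'
#' Lists the score table and, for every wrong step, the question, the
#' learner's answer against the key, and — for decisions — the explanation
#' narrative plus the marked decision tree.
#'
#' @param s a `cig_verification`.
#' @return a single string.
#' @export
format_session_report <- function(s) {
  lines <- c(sprintf("Verification of case '%s' against guideline '%s'",
                     s$case_id, s$guideline_id), "")
  for (i in seq_len(nrow(s$summary))) {
    lines <- c(lines, sprintf("  %-13s %d/%d correct (%.1f%%)",
                              s$summary$category[i], s$summary$n_correct[i],
                              s$summary$n_total[i], s$summary$percent[i]))
  }
  wrong <- Filter(function(r) !r$correct, s$results)
  if (length(wrong) > 0) lines <- c(lines, "", "Discrepancies:")
  for (r in wrong) {
    q <- r$question
    lines <- c(lines, sprintf("- [%s] %s", q$kind, q$prompt),
               sprintf("    answered: %s | correct: %s",
                       paste(r$answer, collapse = ", "),
                       paste(q$correct, collapse = ", ")))
    if (!is.null(r$explanation)) {
      e <- r$explanation
      lines <- c(lines, vapply(e$narrative, function(x) paste0("    ", x),
                               character(1)),
                 strsplit(render_tree(q$tree, marks = list(
                   result = structure(list(leaf = e$correct_leaf,
                                           path = e$visited),
                                      class = "cig_evaluation"),
                   learner_leaf = e$learner_leaf)), "\n")[[1]])
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.cig_verification <- function(x, ...) {
  cat(format_session_report(x), "\n")
  invisible(x)
}
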