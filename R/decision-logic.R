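# Decision trees attached to decision nodes.
#
# A tree is either a leaf, list(leaf = <conclusion id>), or a test,
# list(test = <parameter name>, branches = list(list(when = <predicate>,
# child = <tree>), ...)). Predicates come in three forms:
#   list(op = "eq", value = <string>)                      -- categorical
#   list(op = "in", values = <character vector>)           -- categorical
#   list(op = "interval", lo, hi, lo_closed, hi_closed)    -- numeric
# The interval convention is closed-open [lo, hi) by default so adjacent
# thresholds tile the real line without overlap; infinities are allowed.

new_predicate_eq <- function(value) list(op = "eq", value = as.character(value))
new_predicate_in <- function(values) list(op = "in", values = as.character(values))
new_predicate_interval <- function(lo, hi, lo_closed = TRUE, hi_closed = FALSE) {
  list(op = "interval", lo = as.numeric(lo), hi = as.numeric(hi),
       lo_closed = isTRUE(lo_closed), hi_closed = isTRUE(hi_closed))
}

tree_leaf <- function(conclusion) list(leaf = as.character(conclusion))
tree_test <- function(parameter, branches) {
  list(test = as.character(parameter), branches = branches)
}
tree_branch <- function(when, child) list(when = when, child = child)

is_leaf <- function(t) !is.null(t$leaf)

# All conclusion ids named by leaves of a tree.
tree_leaves <- function(t) {
  if (is_leaf(t)) return(t$leaf)
  unique(unlist(lapply(t$branches, function(b) tree_leaves(b$child))))
}

match_predicate <- function(pred, value) {
  switch(pred$op,
    eq = identical(as.character(value), pred$value),
    `in` = as.character(value) %in% pred$values,
    interval = {
      v <- as.numeric(value)
      lo_ok <- if (pred$lo_closed) v >= pred$lo else v > pred$lo
      hi_ok <- if (pred$hi_closed) v <= pred$hi else v < pred$hi
      isTRUE(lo_ok && hi_ok)
    },
    cig_abort(sprintf("unknown predicate op '%s'", pred$op), "cig_format_error")
  )
}

predicate_text <- function(pred) {
  switch(pred$op,
    eq = paste0("= ", pred$value),
    `in` = paste0("in {", paste(pred$values, collapse = ", "), "}"),
    interval = paste0(
      if (pred$lo_closed) "[" else "(",
      if (is.infinite(pred$lo)) "-inf" else format(pred$lo), ", ",
      if (is.infinite(pred$hi)) "inf" else format(pred$hi),
      if (pred$hi_closed) "]" else ")"
    )
  )
}

#' Check a decision tree for well-formedness over a parameter set
#'
#' At every internal test node the branch predicates must be mutually
#' exclusive and jointly exhaustive over the tested parameter's domain:
#' categorical branches must partition `allowed_values`; numeric interval
#' branches must partition the whole real line. A tree that passes can never
#' dead-end or face an ambiguous branch during simulation, whatever the case
#' data, which is what makes automated stepping total.
#'
#' @param tree a decision tree (see package format documentation).
#' @param params named list of parameter specs (as in a guideline's
#'   `parameters`).
#' @param location prefix used in issue locations (set by the guideline
#'   validator to the owning node id).
#' @return a data frame of issues with columns `code`, `location`,
#'   `message`; zero rows means the tree is clean. Codes used:
#'   `UNKNOWN_PARAMETER`, `OVERLAPPING_BRANCHES`, `NON_EXHAUSTIVE_TREE`,
#'   `BAD_PREDICATE`.
#' @export
check_tree <- function(tree, params, location = "tree") {
  if (is_leaf(tree)) return(no_issues())
  issues <- no_issues()
  p <- params[[tree$test]]
  loc <- paste0(location, "/", tree$test)
  if (is.null(p)) {
    return(issue_row("UNKNOWN_PARAMETER", loc,
                     sprintf("test references unknown parameter '%s'", tree$test)))
  }
  preds <- lapply(tree$branches, `[[`, "when")
  if (identical(p$kind, "categorical")) {
    sets <- lapply(preds, function(pr) {
      switch(pr$op, eq = pr$value, `in` = pr$values, NULL)
    })
    if (any(vapply(sets, is.null, logical(1)))) {
      issues <- bind_issues(issues, issue_row(
        "BAD_PREDICATE", loc, "interval predicate on a categorical parameter"))
    } else {
      allv <- unlist(sets)
      outside <- setdiff(allv, p$allowed_values)
      if (length(outside) > 0) {
        issues <- bind_issues(issues, issue_row(
          "BAD_PREDICATE", loc,
          sprintf("values outside the parameter domain: %s",
                  paste(outside, collapse = ", "))))
      }
      if (anyDuplicated(allv) > 0) {
        issues <- bind_issues(issues, issue_row(
          "OVERLAPPING_BRANCHES", loc,
          sprintf("value(s) %s matched by more than one branch",
                  paste(unique(allv[duplicated(allv)]), collapse = ", "))))
      }
      missing <- setdiff(p$allowed_values, allv)
      if (length(missing) > 0) {
        issues <- bind_issues(issues, issue_row(
          "NON_EXHAUSTIVE_TREE", loc,
          sprintf("no branch matches value(s): %s", paste(missing, collapse = ", "))))
      }
    }
  } else { # numeric
    ivs <- lapply(preds, function(pr) {
      switch(pr$op,
        interval = pr,
        # point predicate on a numeric axis: treat eq v as [v, v]
        eq = new_predicate_interval(as.numeric(pr$value), as.numeric(pr$value),
                                    TRUE, TRUE),
        NULL)
    })
    if (any(vapply(ivs, is.null, logical(1)))) {
      issues <- bind_issues(issues, issue_row(
        "BAD_PREDICATE", loc, "set predicate on a numeric parameter"))
    } else {
      issues <- bind_issues(issues, check_interval_partition(ivs, loc))
    }
  }
  for (b in tree$branches) {
    issues <- bind_issues(issues, check_tree(b$child, params, loc))
  }
  issues
}

# Do the intervals partition (-inf, inf)? Sort by lower endpoint, then walk
# the chain: consecutive endpoints must abut with exactly one side closed.
check_interval_partition <- function(ivs, loc) {
  ord <- order(vapply(ivs, `[[`, numeric(1), "lo"),
               !vapply(ivs, `[[`, logical(1), "lo_closed"))
  ivs <- ivs[ord]
  issues <- no_issues()
  first <- ivs[[1]]
  if (!is.infinite(first$lo)) {
    issues <- bind_issues(issues, issue_row(
      "NON_EXHAUSTIVE_TREE", loc,
      sprintf("values below %s match no branch", format(first$lo))))
  }
  for (i in seq_along(ivs)[-1]) {
    prev <- ivs[[i - 1]]; cur <- ivs[[i]]
    if (cur$lo < prev$hi || (cur$lo == prev$hi && prev$hi_closed && cur$lo_closed)) {
      issues <- bind_issues(issues, issue_row(
        "OVERLAPPING_BRANCHES", loc,
        sprintf("branches %s and %s overlap",
                predicate_text(prev), predicate_text(cur))))
    } else if (cur$lo > prev$hi || (cur$lo == prev$hi &&
                                    !prev$hi_closed && !cur$lo_closed)) {
      issues <- bind_issues(issues, issue_row(
        "NON_EXHAUSTIVE_TREE", loc,
        sprintf("gap between %s and %s",
                predicate_text(prev), predicate_text(cur))))
    }
  }
  last <- ivs[[length(ivs)]]
  if (!is.infinite(last$hi)) {
    issues <- bind_issues(issues, issue_row(
      "NON_EXHAUSTIVE_TREE", loc,
      sprintf("values above %s match no branch", format(last$hi))))
  }
  issues
}

#' Evaluate a decision tree on case data
#'
#' Deterministic descent from the root: at each test node the unique branch
#' whose predicate matches the current value of the tested parameter is
#' followed, until a leaf (a conclusion id) is reached.
#'
#' @param tree a decision tree that passed [check_tree()].
#' @param data named list mapping parameter names to values.
#' @return an object of class `cig_evaluation`: a list with `leaf` (the
#'   conclusion id) and `path`, a list with one entry per visited test
#'   carrying `parameter`, `branch` (matched branch index), `predicate`, and
#'   the observed `value`.
#' @section Errors: a missing parameter at a visited test raises a condition
#'   of class `cig_missing_data` naming the parameter (the signal that a
#'   case study is incomplete).
#' @export
evaluate_tree <- function(tree, data) {
  path <- list()
  node <- tree
  while (!is_leaf(node)) {
    value <- data[[node$test]]
    if (is.null(value)) {
      cig_abort(sprintf("no value for parameter '%s' at decision test", node$test),
                "cig_missing_data", parameter = node$test)
    }
    hit <- 0L
    for (i in seq_along(node$branches)) {
      if (match_predicate(node$branches[[i]]$when, value)) { hit <- i; break }
    }
    if (hit == 0L) {
      cig_abort(sprintf("no branch matches %s = %s (tree not validated?)",
                        node$test, fmt_value(value)), "cig_format_error")
    }
    path[[length(path) + 1L]] <- list(parameter = node$test, branch = hit,
                                      predicate = node$branches[[hit]]$when,
                                      value = value)
    node <- node$branches[[hit]]$child
  }
  structure(list(leaf = node$leaf, path = path), class = "cig_evaluation")
}

# Predicates along the first root->leaf path reaching `leaf`, in branch order.
path_predicates <- function(tree, leaf) {
  if (is_leaf(tree)) {
    if (identical(tree$leaf, leaf)) return(list()) else return(NULL)
  }
  for (b in tree$branches) {
    sub <- path_predicates(b$child, leaf)
    if (!is.null(sub)) {
      return(c(list(list(parameter = tree$test, when = b$when)), sub))
    }
  }
  NULL
}

#' Synthesize case data that drives a tree to a chosen leaf
#'
#' Produces one value per parameter tested on the root-to-leaf path such
#' that every predicate on that path is satisfied. Values are picked by a
#' fixed deterministic policy so generated case studies are reproducible:
#' `eq` takes the stated value, `in` takes a seeded choice from the set, and
#' intervals take the midpoint (finite), `lo + 1` / `hi - 1` (half-infinite)
#' or 0 (unbounded). Constraints on the same parameter from repeated tests
#' are intersected first.
#'
#' @param tree a clean decision tree.
#' @param leaf conclusion id of a leaf present in the tree.
#' @param params named list of parameter specs.
#' @param seed integer seed controlling the `in` choices.
#' @return named list of parameter values.
#' @section Errors: contradictory path constraints raise `cig_unsatisfiable`;
#'   a leaf absent from the tree is an error.
#' @export
witness_for <- function(tree, leaf, params, seed = 0L) {
  with_seed(seed, witness_values(tree, leaf, params))
}

witness_values <- function(tree, leaf, params) {
  preds <- path_predicates(tree, leaf)
  if (is.null(preds)) {
    cig_abort(sprintf("'%s' is not a leaf of this tree", leaf), "cig_format_error")
  }
  by_param <- split(preds, vapply(preds, `[[`, character(1), "parameter"))
  out <- list()
  for (pname in names(by_param)) {
    p <- params[[pname]]
    prs <- lapply(by_param[[pname]], `[[`, "when")
    if (identical(p$kind, "categorical")) {
      feasible <- p$allowed_values
      for (pr in prs) {
        feasible <- intersect(feasible, switch(pr$op, eq = pr$value, `in` = pr$values))
      }
      if (length(feasible) == 0) {
        cig_abort(sprintf("contradictory constraints on '%s'", pname),
                  "cig_unsatisfiable", parameter = pname)
      }
      only_eq <- all(vapply(prs, function(pr) pr$op == "eq", logical(1)))
      out[[pname]] <- if (length(feasible) == 1L || only_eq) feasible[[1]]
                      else sample(sort(feasible), 1L)
    } else {
      lo <- -Inf; hi <- Inf; lo_closed <- FALSE; hi_closed <- FALSE
      for (pr in prs) {
        iv <- if (pr$op == "interval") pr else
          new_predicate_interval(as.numeric(pr$value), as.numeric(pr$value), TRUE, TRUE)
        if (iv$lo > lo || (iv$lo == lo && !iv$lo_closed)) { lo <- iv$lo; lo_closed <- iv$lo_closed }
        if (iv$hi < hi || (iv$hi == hi && !iv$hi_closed)) { hi <- iv$hi; hi_closed <- iv$hi_closed }
      }
      if (lo > hi || (lo == hi && !(lo_closed && hi_closed))) {
        cig_abort(sprintf("contradictory constraints on '%s'", pname),
                  "cig_unsatisfiable", parameter = pname)
      }
      out[[pname]] <-
        if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
        else if (is.finite(lo)) lo + 1
        else if (is.finite(hi)) hi - 1
        else 0
    }
  }
  out
}

#' Explain a decision against a learner's choice
#'
#' Recomputes the correct evaluation of the tree on the case data and pairs
#' it with the learner's selected conclusion. The visited path plays the
#' "green" role of a highlighted explanation (the tests actually traversed,
#' with a per-step narrative), the learner's leaf the "red" role. An
#' explanation is produced whether or not the learner was right; callers
#' decide when to display it.
#'
#' @param tree a clean decision tree.
#' @param data named list of parameter values.
#' @param learner_choice conclusion id chosen by the learner; must be a leaf
#'   of `tree`.
#' @return object of class `cig_explanation` with fields `visited` (the
#'   evaluation path), `correct_leaf`, `learner_leaf`, and `narrative`
#'   (character vector, one sentence per visited test).
#' @export
explain_decision <- function(tree, data, learner_choice) {
  if (!(learner_choice %in% tree_leaves(tree))) {
    cig_abort(sprintf("'%s' is not a leaf of this tree", learner_choice),
              "cig_format_error")
  }
  res <- evaluate_tree(tree, data)
  narrative <- vapply(res$path, function(st) {
    sprintf("parameter %s = %s satisfies %s",
            st$parameter, fmt_value(st$value), predicate_text(st$predicate))
  }, character(1))
  structure(list(visited = res$path, correct_leaf = res$leaf,
                 learner_leaf = learner_choice, narrative = narrative),
            class = "cig_explanation")
}

#' Render a decision tree as an indented text diagram
#'
#' Without marks this is the plain outline shown when inspecting a decision
#' node. With `marks` (an evaluation result and optionally a learner leaf)
#' the tests on the visited path and the correct leaf are prefixed `[*]`
#' and the learner's leaf `[X]`, mirroring a green/red highlighted tree.
#' When the learner's leaf coincides with the correct one the `[X]` mark
#' takes precedence on that line.
#'
#' @param tree a decision tree.
#' @param marks optional list with `result` (a `cig_evaluation`) and
#'   `learner_leaf` (conclusion id).
#' @return a single string (lines separated by newlines).
#' @export
render_tree <- function(tree, marks = NULL) {
  visited <- if (!is.null(marks)) {
    vapply(marks$result$path, `[[`, integer(1), "branch")
  } else integer(0)
  learner <- if (!is.null(marks)) marks$learner_leaf else NULL
  # [X] goes on the first occurrence of the learner leaf so a rendering
  # always carries exactly one learner mark even if an id labels two leaves.
  learner_marked <- FALSE

  rec <- function(node, indent, on_path, depth) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      reached <- on_path && depth == length(visited) + 1L
      m <- ""
      if (!is.null(learner) && identical(node$leaf, learner) && !learner_marked) {
        learner_marked <<- TRUE
        m <- "[X] "
      } else if (reached) {
        m <- "[*] "
      }
      return(paste0(pad, m, node$leaf))
    }
    m <- if (on_path) "[*] " else ""
    lines <- paste0(pad, m, "? ", node$test)
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      child_on_path <- on_path && depth <= length(visited) && visited[depth] == i
      lines <- c(lines,
                 paste0(pad, "  - ", predicate_text(b$when), ":"),
                 rec(b$child, indent + 2L, child_on_path, depth + 1L))
    }
    paste(lines, collapse = "\n")
  }

  rec(tree, 0L, on_path = !is.null(marks) && length(visited) >= 0L, depth = 1L)
}

#' @export
print.cig_explanation <- function(x, ...) {
  cat(sprintf("Decision explanation: correct = %s, learner = %s\n",
              x$correct_leaf, x$learner_leaf))
  for (line in x$narrative) cat(" ", line, "\n")
  invisible(x)
}

# ---- tree (de)serialization ------------------------------------------------

predicate_to_list <- function(pred) {
  switch(pred$op,
    eq = list(op = "eq", value = pred$value),
    `in` = list(op = "in", values = as.list(pred$values)),
    interval = list(op = "interval",
                    lo = if (is.infinite(pred$lo)) "-inf" else pred$lo,
                    hi = if (is.infinite(pred$hi)) "inf" else pred$hi,
                    lo_closed = pred$lo_closed, hi_closed = pred$hi_closed))
}

predicate_from_list <- function(x) {
  op <- x$op %||% cig_abort("predicate without 'op'", "cig_format_error")
  switch(op,
    eq = new_predicate_eq(x$value),
    `in` = new_predicate_in(unlist(x$values)),
    interval = new_predicate_interval(
      if (identical(x$lo, "-inf")) -Inf else as.numeric(x$lo),
      if (identical(x$hi, "inf")) Inf else as.numeric(x$hi),
      isTRUE(x$lo_closed), isTRUE(x$hi_closed)),
    cig_abort(sprintf("unknown predicate op '%s'", op), "cig_format_error"))
}

tree_to_list <- function(t) {
  if (is_leaf(t)) return(list(leaf = t$leaf))
  list(test = t$test,
       branches = lapply(t$branches, function(b) {
         list(when = predicate_to_list(b$when), child = tree_to_list(b$child))
       }))
}

tree_from_list <- function(x) {
  if (!is.null(x$leaf)) return(tree_leaf(x$leaf))
  if (is.null(x$test) || is.null(x$branches)) {
    cig_abort("decision tree node must carry 'leaf' or 'test'+'branches'",
              "cig_format_error")
  }
  tree_test(x$test, lapply(x$branches, function(b) {
    tree_branch(predicate_from_list(b$when), tree_from_list(b$child))
  }))
}
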