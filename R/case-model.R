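# Case studies: virtual patients represented purely as data.
#
# A case binds parameter values to the data-request nodes of a guideline;
# at execution time each data request copies its bindings into the runtime
# environment (latest value wins). Keying values by data-request node —
# rather than globally by parameter — is what lets a case track clinical
# status changes: a parameter requested again later may carry a new value.

#' Construct a case study
#'
#' @param id,description identifying text.
#' @param guideline_id id of the guideline the case is written for.
#' @param bindings named list: data-request node id -> named list of
#'   parameter values.
#' @return object of class `cig_case`.
#' @export
case_study <- function(id, description = "", guideline_id = "", bindings = list()) {
  ord <- order(names(bindings) %||% character())
  bindings <- bindings[ord]
  bindings <- lapply(bindings, function(b) b[order(names(b))])
  structure(list(id = as.character(id), description = as.character(description),
                 guideline_id = as.character(guideline_id), bindings = bindings),
            class = "cig_case")
}

#' @export
print.cig_case <- function(x, ...) {
  cat(sprintf("<cig_case> %s (%d bound data request(s))\n", x$id,
              length(x$bindings)))
  invisible(x)
}

#' Serialize a case study to CASE-JSON
#'
#' Canonical form (sorted binding keys), so repeated saves are
#' byte-identical and load/save round-trips are stable.
#'
#' @param case a case study.
#' @param path optional file path to write to.
#' @return the CASE-JSON text, invisibly when `path` is given.
#' @export
save_case <- function(case, path = NULL) {
  doc <- list(id = case$id, description = case$description,
              guideline_id = case$guideline_id,
              bindings = case$bindings)
  txt <- paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                 digits = NA, null = "null"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

CASE_KEYS <- c("id", "description", "guideline_id", "bindings")

#' Load a case study from CASE-JSON
#'
#' @param source file path or a string of CASE-JSON text.
#' @return object of class `cig_case`.
#' @section Errors: malformed JSON raises a parse error; keys outside the
#'   CASE-JSON dialect raise a format error.
#' @export
load_case <- function(source) {
  txt <- if (length(source) == 1 && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  unknown <- setdiff(names(x), CASE_KEYS)
  if (length(unknown) > 0) {
    cig_abort(sprintf("unknown key(s) in case document: %s",
                      paste(unknown, collapse = ", ")), "cig_format_error")
  }
  case_study(id = x$id %||% "", description = x$description %||% "",
             guideline_id = x$guideline_id %||% "",
             bindings = lapply(x$bindings %||% list(), function(b) b))
}

# Type-check one value against a parameter spec; NULL when fine, else a
# message.
value_type_issue <- function(p, value) {
  if (identical(p$kind, "categorical")) {
    if (!is.character(value) && !is.factor(value)) {
      return(sprintf("value for categorical '%s' must be a string", p$name))
    }
    if (!(as.character(value) %in% p$allowed_values)) {
      return(sprintf("value '%s' not among allowed values of '%s'",
                     as.character(value), p$name))
    }
  } else {
    if (!is.numeric(value) || !is.finite(value)) {
      return(sprintf("value for numeric '%s' must be a finite number", p$name))
    }
  }
  NULL
}

#' Validate a case study against a guideline
#'
#' Type-checks every binding (unknown data-request nodes, values outside a
#' categorical domain, non-finite numerics) and then probes the case by
#' running the automated simulation: the case is *complete* iff the probe
#' run terminates at an end node without missing data.
#'
#' @param g a valid guideline.
#' @param case a case study.
#' @return object of class `cig_case_report`: `issues` data frame (codes
#'   `UNKNOWN_NODE`, `TYPE_MISMATCH`, `MISSING_BINDING`) and `complete`
#'   flag.
#' @export
validate_case <- function(g, case) {
  stop_if_invalid(g)
  issues <- no_issues()
  nodes <- all_nodes(g)
  for (nid in names(case$bindings)) {
    n <- nodes[[nid]]
    if (is.null(n) || !identical(n$kind, "data_request")) {
      issues <- bind_issues(issues, issue_row(
        "UNKNOWN_NODE", nid,
        sprintf("'%s' is not a data-request node of guideline '%s'", nid, g$id)))
      next
    }
    b <- case$bindings[[nid]]
    for (pname in names(b)) {
      p <- g$parameters[[pname]]
      if (is.null(p)) {
        issues <- bind_issues(issues, issue_row(
          "TYPE_MISMATCH", nid, sprintf("unknown parameter '%s'", pname)))
        next
      }
      msg <- value_type_issue(p, b[[pname]])
      if (!is.null(msg)) {
        issues <- bind_issues(issues, issue_row("TYPE_MISMATCH", nid, msg))
      }
    }
  }
  tr <- simulate_case(g, case)
  complete <- identical(tr$status, "completed")
  if (!complete) {
    issues <- bind_issues(issues, issue_row(
      "MISSING_BINDING", tr$location,
      if (identical(tr$reason, "MISSING_DATA")) {
        sprintf("decision '%s' needs parameter '%s', never supplied on the path",
                tr$location, tr$detail)
      } else {
        sprintf("no binding for data request '%s'", tr$location)
      }))
  }
  structure(list(issues = issues, complete = complete),
            class = "cig_case_report")
}

#' @export
print.cig_case_report <- function(x, ...) {
  cat(sprintf("case %s (%d issue(s))\n",
              if (x$complete) "complete" else "incomplete", nrow(x$issues)))
  for (i in seq_len(nrow(x$issues))) {
    cat(sprintf("  %s @ %s: %s\n", x$issues$code[i], x$issues$location[i],
                x$issues$message[i]))
  }
  invisible(x)
}

#' Acquire a case study interactively along one guideline path
#'
#' Walks the guideline from the start exactly like the simulation engine;
#' at each data request the `prompt` callback is asked for a value of each
#' requested parameter, and at each decision the tree is evaluated on the
#' values entered so far, steering the walk. The returned case is complete
#' by construction. A type-invalid answer is re-prompted up to three times
#' before the acquisition aborts.
#'
#' @param g a valid guideline.
#' @param prompt callback `function(node, param)` returning a value;
#'   `node` is the data-request node (use `node$label` for display),
#'   `param` the parameter spec. Character answers for numeric parameters
#'   are coerced with `as.numeric`.
#' @param id,description identity of the resulting case.
#' @return a complete case study.
#' @section Errors: three consecutive invalid answers for one parameter
#'   raise `cig_invalid_input`.
#' @export
acquire_case <- function(g, prompt, id = "acquired-case", description = "") {
  stop_if_invalid(g)
  bindings <- list()
  values <- list()

  ask <- function(node, p) {
    for (attempt in 1:3) {
      v <- prompt(node, p)
      if (identical(p$kind, "numeric") && is.character(v)) {
        v <- suppressWarnings(as.numeric(v))
      }
      if (is.null(value_type_issue(p, v))) return(v)
    }
    cig_abort(sprintf("three invalid answers for parameter '%s'", p$name),
              "cig_invalid_input", parameter = p$name)
  }

  walk <- function(sg, id_) {
    repeat {
      n <- sg$nodes[[id_]]
      if (identical(n$kind, "composite")) {
        walk(n$body, n$body$start)
      } else if (identical(n$kind, "data_request")) {
        b <- list()
        for (pname in n$requests) {
          v <- ask(n, g$parameters[[pname]])
          b[[pname]] <- v
          values[[pname]] <<- v
        }
        bindings[[n$id]] <<- b
      } else if (identical(n$kind, "decision")) {
        res <- evaluate_tree(n$tree, values)
        id_ <- res$leaf
        next
      }
      succ <- successors(sg, id_)
      if (length(succ) == 0) return(invisible())
      id_ <- succ[[1]]
    }
  }
  walk(g$body, g$body$start)
  case_study(id = id, description = description, guideline_id = g$id,
             bindings = bindings)
}

#' Synthesize a complete case study inducing a chosen control path
#'
#' Mechanized case authoring: for every decision on the path a witness
#' value assignment forcing the path's conclusion is computed with
#' [witness_for()], and each witness value is attached to the *last* data
#' request on the path that requests the parameter before the consuming
#' decision (so the latest-wins runtime environment sees exactly the
#' witness value). Requested parameters left unconstrained get seeded
#' domain samples. The result is complete and induces exactly `path`.
#'
#' @param g a valid guideline.
#' @param path one of [enumerate_paths()]'s node-id sequences.
#' @param seed integer controlling witness choices and domain samples.
#' @param id optional case id.
#' @return a complete case study.
#' @section Errors: a path whose decisions admit no witness raises
#'   `cig_unsatisfiable`; a path not in the enumeration is an error.
#' @export
synthesize_case <- function(g, path, seed = 0L, id = NULL) {
  flat <- flatten_guideline(g)
  known <- enumerate_paths(g)
  if (!any(vapply(known, identical, logical(1), y = as.character(path)))) {
    cig_abort("path is not an enumerated control path of this guideline",
              "cig_format_error")
  }
  assignments <- list()  # node id -> param -> value
  with_seed(seed, {
    for (i in seq_along(path)) {
      n <- flat$nodes[[path[i]]]
      if (!identical(n$kind, "decision")) next
      leaf <- path[i + 1L]
      w <- witness_values(n$tree, leaf, g$parameters)
      for (pname in names(w)) {
        req_at <- NA_character_
        for (j in seq_len(i - 1L)) {
          nj <- flat$nodes[[path[j]]]
          if (identical(nj$kind, "data_request") && pname %in% nj$requests) {
            req_at <- path[j]
          }
        }
        if (is.na(req_at)) {
          cig_abort(sprintf(
            "no data request before decision '%s' supplies parameter '%s'",
            n$id, pname), "cig_unsatisfiable", parameter = pname)
        }
        prev <- assignments[[req_at]][[pname]]
        if (!is.null(prev) && !identical(prev, w[[pname]])) {
          cig_abort(sprintf(
            "conflicting witness values for '%s' at data request '%s'",
            pname, req_at), "cig_unsatisfiable", parameter = pname)
        }
        if (is.null(assignments[[req_at]])) assignments[[req_at]] <- list()
        assignments[[req_at]][[pname]] <- w[[pname]]
      }
    }
    # fill remaining requested parameters with domain samples
    for (i in seq_along(path)) {
      n <- flat$nodes[[path[i]]]
      if (!identical(n$kind, "data_request")) next
      if (is.null(assignments[[n$id]])) assignments[[n$id]] <- list()
      for (pname in setdiff(n$requests, names(assignments[[n$id]]))) {
        p <- g$parameters[[pname]]
        assignments[[n$id]][[pname]] <-
          if (identical(p$kind, "categorical")) sample(p$allowed_values, 1L)
          else round(stats::runif(1, 0, 10), 2)
      }
    }
  })
  case_study(
    id = id %||% sprintf("case-%s-seed%d", path[length(path)], as.integer(seed)),
    description = sprintf("Synthesized case inducing path ending at '%s'.",
                          path[length(path)]),
    guideline_id = g$id, bindings = assignments)
}
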