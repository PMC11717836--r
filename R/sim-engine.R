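# Automated simulation: step-by-step execution of a guideline on a case.
#
# Execution walks the hierarchical graph. Work actions are recorded and
# passed; data requests copy the case's bindings for that node into the
# runtime environment (latest value wins); decisions evaluate their tree on
# the environment and jump to the selected conclusion; composites descend
# into their body (emitting descend/ascend markers around the nested walk).
# The learner never makes choices here — the case data fully determine the
# path.

#' Start a simulation session
#'
#' @param g a valid guideline.
#' @param case a case study for it.
#' @return an object of class `cig_session` (an environment) positioned
#'   before the guideline's start node, with an empty runtime environment
#'   and empty trace.
#' @export
sim_start <- function(g, case) {
  stop_if_invalid(g)
  s <- new.env(parent = emptyenv())
  s$g <- g
  s$case <- case
  s$values <- list()       # parameter name -> latest value
  s$steps <- list()
  s$stack <- list()        # frames: list(sg = parent subgraph, comp = composite id)
  s$cur_sg <- g$body
  s$current <- g$body$start
  s$status <- "running"
  s$reason <- NULL
  s$location <- NULL
  s$detail <- NULL
  class(s) <- "cig_session"
  s
}

session_level <- function(s) {
  if (length(s$stack) == 0) "top" else s$stack[[length(s$stack)]]$comp
}

record_step <- function(s, node, kind, payload = NULL) {
  rec <- list(node = node, kind = kind, payload = payload,
              level = session_level(s))
  s$steps[[length(s$steps) + 1L]] <- rec
  rec
}

block_session <- function(s, reason, location, detail = NULL) {
  s$status <- "blocked"
  s$reason <- reason
  s$location <- location
  s$detail <- detail
  invisible(NULL)
}

# Move past an executed node: follow its unique outgoing arc; when a body
# end finishes, pop back to the enclosing level (emitting an ascend marker)
# and continue from the composite.
advance_from <- function(s, id) {
  repeat {
    succ <- successors(s$cur_sg, id)
    if (length(succ) >= 1) {
      s$current <- succ[[1]]
      return(invisible(s))
    }
    if (length(s$stack) == 0) {
      s$status <- "completed"
      s$current <- NULL
      return(invisible(s))
    }
    frame <- s$stack[[length(s$stack)]]
    s$stack[[length(s$stack)]] <- NULL
    s$cur_sg <- frame$sg
    record_step(s, frame$comp, "ascend")
    id <- frame$comp
  }
}

#' Execute one simulation step
#'
#' Executes the session's current node and advances. Returns the step
#' record, or `NULL` when the step could not execute because the case lacks
#' data (the session is then `blocked` with reason `MISSING_BINDING` for an
#' unbound data request or `MISSING_DATA` for a decision parameter never
#' supplied).
#'
#' @param s a running `cig_session`.
#' @return the new step record (a list with `node`, `kind`, `payload`,
#'   `level`), invisibly `NULL` when the session blocks.
#' @export
sim_step <- function(s) {
  if (!identical(s$status, "running")) {
    cig_abort("session is not running", "cig_format_error")
  }
  id <- s$current
  node <- s$cur_sg$nodes[[id]]
  switch(node$kind,
    work = {
      rec <- record_step(s, id, "work")
      advance_from(s, id)
      rec
    },
    data_request = {
      binding <- s$case$bindings[[id]]
      if (is.null(binding)) {
        return(block_session(s, "MISSING_BINDING", id))
      }
      for (p in names(binding)) s$values[[p]] <- binding[[p]]
      rec <- record_step(s, id, "data_request", payload = binding)
      advance_from(s, id)
      rec
    },
    decision = {
      res <- tryCatch(evaluate_tree(node$tree, s$values),
                      cig_missing_data = function(e) e)
      if (inherits(res, "cig_missing_data")) {
        return(block_session(s, "MISSING_DATA", id, detail = res$parameter))
      }
      rec <- record_step(s, id, "decision", payload = res)
      s$current <- res$leaf
      rec
    },
    conclusion = {
      rec <- record_step(s, id, "conclusion")
      advance_from(s, id)
      rec
    },
    composite = {
      rec <- record_step(s, id, "descend")
      s$stack[[length(s$stack) + 1L]] <- list(sg = s$cur_sg, comp = id)
      s$cur_sg <- node$body
      s$current <- node$body$start
      rec
    })
}

session_trace <- function(s) {
  structure(list(steps = s$steps, status = s$status, reason = s$reason,
                 location = s$location, detail = s$detail,
                 guideline_id = s$g$id, case_id = s$case$id),
            class = "cig_trace")
}

#' Simulate a guideline on a case study
#'
#' Runs [sim_step()] to completion. Incomplete cases do not throw: the
#' returned trace carries a `blocked` status with the reason and location,
#' so authoring mistakes in teaching material surface with full context.
#'
#' @param g a valid guideline.
#' @param case a case study.
#' @return object of class `cig_trace`: `steps` (ordered step records),
#'   `status` (`"completed"` or `"blocked"`), `reason`/`location`/`detail`
#'   when blocked.
#' @export
simulate_case <- function(g, case) {
  s <- sim_start(g, case)
  while (identical(s$status, "running")) sim_step(s)
  session_trace(s)
}

#' @export
print.cig_trace <- function(x, ...) {
  cat(sprintf("<cig_trace> %s on %s: %d steps, %s\n", x$guideline_id, x$case_id,
              length(x$steps), x$status))
  if (identical(x$status, "blocked")) {
    cat(sprintf("  blocked: %s at '%s'%s\n", x$reason, x$location,
                if (is.null(x$detail)) "" else paste0(" (", x$detail, ")")))
  }
  invisible(x)
}

# Render a trace as step-per-line text; all executed steps are marked done,
# the blocking location (if any) is marked current.
format_trace_text <- function(g, trace) {
  lines <- character()
  for (st in trace$steps) {
    label <- find_node(g, st$node)$label
    extra <- if (identical(st$kind, "decision")) paste0(" -> ", st$payload$leaf)
             else ""
    lines <- c(lines, sprintf("[done] %-12s %s%s", st$kind, label, extra))
  }
  if (identical(trace$status, "blocked")) {
    label <- find_node(g, trace$location)$label %||% trace$location
    lines <- c(lines, sprintf("[current] %s (blocked: %s)", label, trace$reason))
  }
  paste(lines, collapse = "\n")
}

#' Atomic path induced by a case
#'
#' The subsequence of atomic node ids (work, data request, decision,
#' conclusion) visited by a completed simulation; descend/ascend markers
#' and composite ids are excluded.
#'
#' @param g a valid guideline.
#' @param case a complete case study.
#' @return character vector of node ids.
#' @export
induced_path <- function(g, case) {
  tr <- simulate_case(g, case)
  if (!identical(tr$status, "completed")) {
    cig_abort(sprintf("simulation blocked (%s at '%s')", tr$reason, tr$location),
              "cig_blocked", reason = tr$reason, location = tr$location)
  }
  trace_atomic_path(tr)
}

trace_atomic_path <- function(trace) {
  kinds <- vapply(trace$steps, `[[`, character(1), "kind")
  vapply(trace$steps[kinds %in% ATOMIC_KINDS], `[[`, character(1), "node")
}

#' Enumerate all atomic control paths of a guideline
#'
#' Brute-force oracle over the flattened graph: depth-first from the start,
#' branching at each decision over its conclusion successors, following
#' arcs in canonical (serialized) order. Acyclicity guarantees termination.
#'
#' @param g a valid guideline.
#' @return list of character vectors (node-id sequences), in deterministic
#'   order.
#' @export
enumerate_paths <- function(g) {
  flat <- flatten_guideline(g)
  paths <- list()
  walk <- function(id, acc) {
    acc <- c(acc, id)
    succ <- successors(flat, id)
    if (length(succ) == 0) {
      paths[[length(paths) + 1L]] <<- acc
    } else if (identical(flat$nodes[[id]]$kind, "decision")) {
      for (s in succ) walk(s, acc)
    } else {
      walk(succ[[1]], acc)
    }
  }
  walk(flat$start, character())
  paths
}
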