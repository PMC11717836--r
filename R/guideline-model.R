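# Hierarchical computer-interpretable guideline (CIG) model.
#
# A guideline is a hierarchical typed action graph: nodes are clinical
# actions (work, data_request, decision, conclusion, composite), arcs are
# control flow. Composite nodes carry a nested subgraph, giving the
# multi-level "conceptual map" view of a guideline. Decision nodes carry a
# decision tree whose leaves name conclusion successors.

NODE_KINDS <- c("work", "data_request", "decision", "conclusion", "composite")
ATOMIC_KINDS <- c("work", "data_request", "decision", "conclusion")

#' Construct a parameter specification
#'
#' @param name identifier, unique within a guideline.
#' @param kind `"categorical"` or `"numeric"`.
#' @param allowed_values character vector of admissible values (categorical
#'   parameters only).
#' @param unit free-text unit (numeric parameters only).
#' @return a parameter spec (plain list).
#' @export
parameter_spec <- function(name, kind, allowed_values = character(), unit = "") {
  stopifnot(kind %in% c("categorical", "numeric"))
  list(name = as.character(name), kind = kind,
       allowed_values = as.character(allowed_values), unit = as.character(unit))
}

#' Construct an action node
#'
#' @param id guideline-global identifier.
#' @param kind one of work, data_request, decision, conclusion, composite.
#' @param label display text (non-empty).
#' @param description free text.
#' @param media list of opaque attachment references, each
#'   `list(ref = , caption = )`.
#' @param requests (data_request) ordered character vector of parameter names.
#' @param tree (decision) a decision tree.
#' @param body (composite) a subgraph built with [subgraph()].
#' @return an action node (plain list).
#' @export
action_node <- function(id, kind, label, description = "", media = list(),
                        requests = NULL, tree = NULL, body = NULL) {
  if (!kind %in% NODE_KINDS) {
    cig_abort(sprintf("unknown node kind '%s' for node '%s'", kind, id),
              "cig_format_error")
  }
  node <- list(id = as.character(id), kind = kind, label = as.character(label),
               description = as.character(description), media = media)
  if (kind == "data_request") node$requests <- as.character(requests)
  if (kind == "decision") node$tree <- tree
  if (kind == "composite") node$body <- body
  node
}

#' Construct a subgraph
#'
#' Nodes and arcs are normalized to a canonical order (nodes by id, arcs by
#' from/to) at construction, so an in-memory guideline and its serialized
#' form agree on traversal order everywhere order matters (path
#' enumeration, DOT export).
#'
#' @param nodes list of action nodes.
#' @param arcs data frame with character columns `from`, `to` (or a list of
#'   two-element vectors).
#' @param start node id of the entry point.
#' @param ends character vector of terminal node ids.
#' @return a subgraph (plain list).
#' @export
subgraph <- function(nodes, arcs, start, ends) {
  if (is.list(arcs) && !is.data.frame(arcs)) {
    arcs <- if (length(arcs) == 0) data.frame(from = character(), to = character()) else
      data.frame(from = vapply(arcs, `[[`, character(1), 1),
                 to = vapply(arcs, `[[`, character(1), 2))
  }
  if (nrow(arcs) > 0) arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  ids <- vapply(nodes, `[[`, character(1), "id")
  nodes <- nodes[order(ids)]
  names(nodes) <- sort(ids)
  list(nodes = nodes, arcs = arcs, start = as.character(start),
       ends = sort(as.character(ends)))
}

#' Construct a guideline
#'
#' @param id,name,version identifying text.
#' @param parameters list of [parameter_spec()] objects.
#' @param body top-level [subgraph()].
#' @return object of class `cig_guideline`.
#' @export
guideline <- function(id, name, version, parameters, body) {
  pnames <- vapply(parameters, `[[`, character(1), "name")
  parameters <- parameters[order(pnames)]
  names(parameters) <- sort(pnames)
  structure(list(id = as.character(id), name = as.character(name),
                 version = as.character(version),
                 parameters = parameters, body = body),
            class = "cig_guideline")
}

#' @export
print.cig_guideline <- function(x, ...) {
  nn <- length(all_nodes(x))
  cat(sprintf("<cig_guideline> %s (%s, v%s): %d nodes, %d parameters\n",
              x$id, x$name, x$version, nn, length(x$parameters)))
  invisible(x)
}

# Named list of every node in the guideline, across all hierarchy levels.
all_nodes <- function(g) {
  collect <- function(sg) {
    out <- sg$nodes
    for (n in sg$nodes) {
      if (identical(n$kind, "composite") && !is.null(n$body)) {
        out <- c(out, collect(n$body))
      }
    }
    out
  }
  collect(g$body)
}

# Find a node anywhere in the hierarchy; NULL if absent.
find_node <- function(g, id) all_nodes(g)[[id]]

# Successor ids of `id` within a subgraph, in canonical arc order.
successors <- function(sg, id) sg$arcs$to[sg$arcs$from == id]

# ---- validation ------------------------------------------------------------

#' Validate a guideline
#'
#' Checks every structural invariant of the formalism and returns a report
#' rather than throwing: unique ids, arcs referencing member nodes, acyclic
#' control flow, reachability from the start, single successors outside
#' decisions, decision arcs targeting conclusions, well-formed start/end
#' sets, parameter resolution, and decision-tree discipline (leaves name
#' conclusion successors; branches partition each tested parameter's
#' domain, via [check_tree()]).
#'
#' @param g a guideline.
#' @return object of class `cig_validation_report`: list with `issues`
#'   (data frame of `code`, `location`, `message`) and `valid`
#'   (`TRUE` iff no issues).
#' @export
validate_guideline <- function(g) {
  issues <- no_issues()

  pnames <- vapply(g$parameters, `[[`, character(1), "name")
  if (anyDuplicated(pnames) > 0) {
    issues <- bind_issues(issues, issue_row(
      "BAD_PARAMETER", "parameters", "duplicate parameter names"))
  }
  for (p in g$parameters) {
    if (identical(p$kind, "categorical") &&
        (length(p$allowed_values) == 0 || anyDuplicated(p$allowed_values) > 0)) {
      issues <- bind_issues(issues, issue_row(
        "BAD_PARAMETER", p$name,
        "categorical allowed_values must be non-empty and duplicate-free"))
    }
  }

  nodes <- all_nodes(g)
  ids <- names(nodes)
  if (anyDuplicated(ids) > 0) {
    issues <- bind_issues(issues, issue_row(
      "DUPLICATE_ID", paste(unique(ids[duplicated(ids)]), collapse = ","),
      "node ids must be unique guideline-wide"))
  }
  for (n in nodes) {
    if (!nzchar(n$label)) {
      issues <- bind_issues(issues, issue_row(
        "BAD_PARAMETER", n$id, "node label must be non-empty"))
    }
  }

  check_sg <- function(sg, where) {
    iss <- no_issues()
    member <- names(sg$nodes)
    bad_from <- setdiff(sg$arcs$from, member)
    bad_to <- setdiff(sg$arcs$to, member)
    for (x in union(bad_from, bad_to)) {
      iss <- bind_issues(iss, issue_row(
        "DANGLING_ARC", x,
        sprintf("arc references '%s', not a member of level '%s'", x, where)))
    }
    ok_arcs <- sg$arcs[sg$arcs$from %in% member & sg$arcs$to %in% member, ,
                       drop = FALSE]
    if (length(member) > 0) {
      ig <- igraph::graph_from_data_frame(ok_arcs, directed = TRUE,
                                          vertices = member)
      if (!igraph::is_dag(ig)) {
        iss <- bind_issues(iss, issue_row(
          "CYCLE", where, "control-flow graph contains a cycle"))
      }
      if (sg$start %in% member) {
        reach <- names(igraph::subcomponent(ig, sg$start, mode = "out"))
        unreach <- setdiff(member, reach)
        for (x in unreach) {
          iss <- bind_issues(iss, issue_row(
            "UNREACHABLE_NODE", x,
            sprintf("'%s' is not reachable from start '%s'", x, sg$start)))
        }
      }
    }
    if (!(sg$start %in% member)) {
      iss <- bind_issues(iss, issue_row(
        "BAD_START", sg$start %||% where,
        sprintf("start '%s' is not a node of level '%s'", sg$start, where)))
    }
    if (length(sg$ends) == 0) {
      iss <- bind_issues(iss, issue_row("BAD_END", where, "empty end set"))
    }
    for (e in sg$ends) {
      if (!(e %in% member)) {
        iss <- bind_issues(iss, issue_row(
          "BAD_END", e, sprintf("end '%s' is not a node of level '%s'", e, where)))
      } else if (length(successors(sg, e)) > 0) {
        iss <- bind_issues(iss, issue_row(
          "BAD_END", e, sprintf("end node '%s' has outgoing arcs", e)))
      }
    }
    for (n in sg$nodes) {
      succ <- successors(sg, n$id)
      if (!identical(n$kind, "decision") && length(succ) > 1) {
        iss <- bind_issues(iss, issue_row(
          "MULTI_SUCCESSOR", n$id,
          sprintf("non-decision node '%s' has %d outgoing arcs", n$id, length(succ))))
      }
      if (identical(n$kind, "decision")) {
        for (s in succ) {
          if (!is.null(sg$nodes[[s]]) && !identical(sg$nodes[[s]]$kind, "conclusion")) {
            iss <- bind_issues(iss, issue_row(
              "BAD_DECISION_SUCCESSOR", n$id,
              sprintf("decision '%s' has non-conclusion successor '%s'", n$id, s)))
          }
        }
        if (!is.null(n$tree)) {
          iss <- bind_issues(iss, check_tree(n$tree, g$parameters, n$id))
          leaves <- tree_leaves(n$tree)
          concl <- succ[vapply(succ, function(s) {
            !is.null(sg$nodes[[s]]) && identical(sg$nodes[[s]]$kind, "conclusion")
          }, logical(1))]
          for (l in setdiff(leaves, concl)) {
            iss <- bind_issues(iss, issue_row(
              "ORPHAN_LEAF_CONCLUSION", n$id,
              sprintf("tree leaf '%s' is not a conclusion successor of '%s'", l, n$id)))
          }
          for (s in setdiff(concl, leaves)) {
            iss <- bind_issues(iss, issue_row(
              "UNREFERENCED_CONCLUSION", n$id,
              sprintf("conclusion successor '%s' is named by no tree leaf", s)))
          }
        }
      }
      if (identical(n$kind, "data_request")) {
        if (length(n$requests) == 0 || anyDuplicated(n$requests) > 0) {
          iss <- bind_issues(iss, issue_row(
            "BAD_DATA_REQUEST", n$id,
            "requests must be a non-empty, duplicate-free parameter list"))
        }
        for (r in setdiff(n$requests, names(g$parameters))) {
          iss <- bind_issues(iss, issue_row(
            "UNKNOWN_PARAMETER", n$id,
            sprintf("data request '%s' names unknown parameter '%s'", n$id, r)))
        }
      }
      if (identical(n$kind, "composite") && !is.null(n$body)) {
        iss <- bind_issues(iss, check_sg(n$body, n$id))
      }
    }
    iss
  }

  issues <- bind_issues(issues, check_sg(g$body, "top"))
  structure(list(issues = issues, valid = nrow(issues) == 0),
            class = "cig_validation_report")
}

#' @export
print.cig_validation_report <- function(x, ...) {
  if (x$valid) {
    cat("valid guideline (no issues)\n")
  } else {
    cat(sprintf("%d issue(s):\n", nrow(x$issues)))
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  %s @ %s: %s\n", x$issues$code[i], x$issues$location[i],
                  x$issues$message[i]))
    }
  }
  invisible(x)
}

stop_if_invalid <- function(g) {
  rep <- validate_guideline(g)
  if (!rep$valid) {
    cig_abort(sprintf("guideline fails validation (%d issue(s), first: %s @ %s)",
                      nrow(rep$issues), rep$issues$code[1], rep$issues$location[1]),
              "cig_invalid_guideline")
  }
  invisible(g)
}

# ---- serialization (CIG-JSON) ----------------------------------------------

node_to_list <- function(n) {
  out <- list(id = n$id, kind = n$kind, label = n$label)
  if (nzchar(n$description %||% "")) out$description <- n$description
  if (length(n$media) > 0) {
    out$media <- lapply(n$media, function(m) list(ref = m$ref, caption = m$caption %||% ""))
  }
  if (identical(n$kind, "data_request")) out$requests <- as.list(n$requests)
  if (identical(n$kind, "decision")) out$tree <- tree_to_list(n$tree)
  if (identical(n$kind, "composite")) out$body <- sg_to_list(n$body)
  out
}

sg_to_list <- function(sg) {
  list(start = sg$start,
       ends = as.list(sg$ends),
       nodes = lapply(unname(sg$nodes), node_to_list),
       arcs = lapply(seq_len(nrow(sg$arcs)), function(i) {
         list(from = sg$arcs$from[i], to = sg$arcs$to[i])
       }))
}

node_from_list <- function(x) {
  kind <- x$kind %||% cig_abort(
    sprintf("node '%s' has no kind", x$id %||% "?"), "cig_format_error")
  if (!kind %in% NODE_KINDS) {
    cig_abort(sprintf("unknown node kind '%s' in node '%s'", kind, x$id %||% "?"),
              "cig_format_error")
  }
  action_node(
    id = x$id, kind = kind, label = x$label %||% "",
    description = x$description %||% "",
    media = lapply(x$media %||% list(), function(m) {
      list(ref = m$ref, caption = m$caption %||% "")
    }),
    requests = if (kind == "data_request") unlist(x$requests),
    tree = if (kind == "decision") tree_from_list(x$tree),
    body = if (kind == "composite") sg_from_list(x$body))
}

sg_from_list <- function(x) {
  arcs <- if (length(x$arcs) == 0) {
    data.frame(from = character(), to = character())
  } else {
    data.frame(from = vapply(x$arcs, `[[`, character(1), "from"),
               to = vapply(x$arcs, `[[`, character(1), "to"))
  }
  subgraph(nodes = lapply(x$nodes, node_from_list), arcs = arcs,
           start = x$start, ends = unlist(x$ends %||% list()))
}

#' Serialize a guideline to CIG-JSON
#'
#' The serialization is canonical — keys in a fixed order, parameters and
#' nodes sorted by name/id, arcs sorted by endpoints — so saving the same
#' guideline twice is byte-identical and structural equality can be tested
#' on the serialized text.
#'
#' @param g a guideline.
#' @param path optional file path; when given the text is written there.
#' @return the CIG-JSON text, invisibly when `path` is given.
#' @export
save_guideline <- function(g, path = NULL) {
  doc <- list(id = g$id, name = g$name, version = g$version,
              parameters = lapply(unname(g$parameters), function(p) {
                out <- list(name = p$name, kind = p$kind)
                if (p$kind == "categorical") out$allowed_values <- as.list(p$allowed_values)
                if (p$kind == "numeric") out$unit <- p$unit
                out
              }),
              body = sg_to_list(g$body))
  txt <- paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                 digits = NA, null = "null"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Load a guideline from CIG-JSON
#'
#' Parses and builds the in-memory guideline without semantic validation;
#' call [validate_guideline()] afterwards. Malformed JSON raises a parse
#' error (with position information from the JSON parser); an unknown node
#' kind raises a format error naming the offending node.
#'
#' @param source file path or a single string of CIG-JSON text.
#' @return object of class `cig_guideline`.
#' @export
load_guideline <- function(source) {
  txt <- if (length(source) == 1 && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  guideline(id = x$id %||% "", name = x$name %||% "", version = x$version %||% "",
            parameters = lapply(x$parameters %||% list(), function(p) {
              parameter_spec(p$name, p$kind,
                             allowed_values = unlist(p$allowed_values %||% list()),
                             unit = p$unit %||% "")
            }),
            body = sg_from_list(x$body))
}

#' Structural equality of two guidelines
#'
#' Compares canonical serializations.
#'
#' @param a,b guidelines.
#' @return logical scalar.
#' @export
guideline_identical <- function(a, b) {
  identical(save_guideline(a), save_guideline(b))
}

# ---- flatten ---------------------------------------------------------------

#' Flatten a hierarchical guideline to a single-level subgraph
#'
#' Every composite node is recursively replaced by its body: arcs into the
#' composite are rewired to the body's start, the body's end nodes are
#' rewired to the composite's successor (or become ends of the enclosing
#' level if the composite was terminal). Atomic node ids are preserved, so
#' the flat graph is the reference semantics for path enumeration and
#' execution order.
#'
#' @param g a valid guideline.
#' @return a [subgraph()] containing only atomic nodes.
#' @export
flatten_guideline <- function(g) {
  stop_if_invalid(g)
  flatten_sg(g$body)
}

flatten_sg <- function(sg) {
  nodes <- sg$nodes
  arcs <- sg$arcs
  start <- sg$start
  ends <- sg$ends
  comp_ids <- names(nodes)[vapply(nodes, function(n) identical(n$kind, "composite"),
                                  logical(1))]
  for (cid in comp_ids) {
    bf <- flatten_sg(nodes[[cid]]$body)
    succ <- arcs$to[arcs$from == cid]
    arcs <- arcs[arcs$from != cid, , drop = FALSE]
    arcs$to[arcs$to == cid] <- bf$start
    arcs <- rbind(arcs, bf$arcs)
    if (length(succ) == 1) {
      arcs <- rbind(arcs, data.frame(from = bf$ends, to = succ))
    } else {
      # terminal composite: its body's ends become ends of this level
      ends <- union(ends, bf$ends)
    }
    ends <- setdiff(ends, cid)
    if (identical(start, cid)) start <- bf$start
    nodes[[cid]] <- NULL
    nodes <- c(nodes, bf$nodes)
  }
  subgraph(nodes = unname(nodes), arcs = arcs, start = start, ends = ends)
}

# Control-flow order of a subgraph's own nodes: depth-first from the start,
# following arcs in canonical order, each node listed once.
cf_order <- function(sg) {
  seen <- character()
  rec <- function(id) {
    if (id %in% seen) return(invisible())
    seen <<- c(seen, id)
    for (s in successors(sg, id)) rec(s)
  }
  rec(sg$start)
  seen
}

# ---- navigation / export ---------------------------------------------------

#' Text outline of a guideline's hierarchy
#'
#' One line per node in control-flow order; children of composite nodes are
#' indented one level deeper. Levels below `depth` are truncated: depth 0
#' shows the top level only.
#'
#' @param g a valid guideline.
#' @param depth non-negative integer, deepest level shown.
#' @return a single string (newline-separated lines).
#' @export
guideline_outline <- function(g, depth = 0L) {
  stop_if_invalid(g)
  emit <- function(sg, level) {
    lines <- character()
    for (id in cf_order(sg)) {
      n <- sg$nodes[[id]]
      lines <- c(lines, paste0(strrep("  ", level), n$label))
      if (identical(n$kind, "composite") && level + 1L <= depth) {
        lines <- c(lines, emit(n$body, level + 1L))
      }
    }
    lines
  }
  paste(emit(g$body, 0L), collapse = "\n")
}

DOT_SHAPES <- c(composite = "octagon", work = "ellipse",
                data_request = "parallelogram", decision = "diamond",
                conclusion = "triangle")
DOT_COLORS <- c(composite = "red", work = "blue", data_request = "green",
                decision = "yellow", conclusion = "orange")

#' Export one hierarchy level of a guideline as Graphviz DOT
#'
#' Renders the conventional flowchart view: red octagons for composites,
#' blue ellipses for work actions, green parallelograms for data requests,
#' yellow diamonds for decisions, orange triangles for conclusions.
#'
#' @param g a valid guideline.
#' @param level `"top"` for the top level, or the id of a composite node
#'   whose body should be rendered.
#' @return DOT text.
#' @export
guideline_to_dot <- function(g, level = "top") {
  stop_if_invalid(g)
  sg <- if (identical(level, "top")) {
    g$body
  } else {
    n <- find_node(g, level)
    if (is.null(n) || !identical(n$kind, "composite")) {
      cig_abort(sprintf("no composite node '%s' in guideline", level),
                "cig_format_error")
    }
    n$body
  }
  lines <- c("digraph cig {", "  rankdir=TB;")
  for (id in names(sg$nodes)) {
    n <- sg$nodes[[id]]
    lines <- c(lines, sprintf(
      '  "%s" [label="%s", shape=%s, style=filled, fillcolor=%s];',
      n$id, gsub('"', '\\\\"', n$label), DOT_SHAPES[[n$kind]], DOT_COLORS[[n$kind]]))
  }
  for (i in seq_len(nrow(sg$arcs))) {
    lines <- c(lines, sprintf('  "%s" -> "%s";', sg$arcs$from[i], sg$arcs$to[i]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Detail record for a single node
#'
#' The textual analogue of a "show details" view: label, kind, description,
#' media attachments (opaque references), and — for decision nodes — the
#' ASCII rendering of the decision tree.
#'
#' @param g a guideline.
#' @param id a node id anywhere in the hierarchy.
#' @return a list with fields `id`, `label`, `kind`, `description`, `media`,
#'   and `tree_rendering` (decision nodes only, else `NULL`).
#' @export
node_detail <- function(g, id) {
  n <- find_node(g, id)
  if (is.null(n)) cig_abort(sprintf("unknown node id '%s'", id), "cig_format_error")
  list(id = n$id, label = n$label, kind = n$kind, description = n$description,
       media = n$media,
       tree_rendering = if (identical(n$kind, "decision")) render_tree(n$tree))
}
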