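# Shared fixtures and independent oracles, all built in code at test time.

demo_guideline <- function() build_demo_guideline()
demo_cases <- function() build_demo_cases()

# Smallest valid guideline: one work node that is both start and end.
one_node_guideline <- function() {
  guideline("mini", "Minimal", "1", list(),
            subgraph(list(action_node("w1", "work", "Do the thing")),
                     list(), start = "w1", ends = "w1"))
}

# Straight line of n work nodes (no branching, no data).
straight_line_guideline <- function(n = 4) {
  ids <- sprintf("w%02d", seq_len(n))
  nodes <- lapply(ids, function(i) action_node(i, "work", paste("Step", i)))
  arcs <- if (n > 1) lapply(seq_len(n - 1), function(i) c(ids[i], ids[i + 1])) else list()
  guideline("line", "Straight line", "1", list(),
            subgraph(nodes, arcs, start = ids[1], ends = ids[n]))
}

# Two levels of nesting: outer composite contains an inner composite.
doubly_nested_guideline <- function() {
  inner <- subgraph(list(action_node("a1", "work", "Inner first"),
                         action_node("a2", "work", "Inner second")),
                    list(c("a1", "a2")), start = "a1", ends = "a2")
  mid <- subgraph(list(action_node("inner", "composite", "Inner block", body = inner),
                       action_node("b1", "work", "After inner")),
                  list(c("inner", "b1")), start = "inner", ends = "b1")
  top <- subgraph(list(action_node("outer", "composite", "Outer block", body = mid),
                       action_node("c1", "work", "Final")),
                  list(c("outer", "c1")), start = "outer", ends = "c1")
  guideline("nested", "Doubly nested", "1", list(), top)
}

# The decision trees of the demo guideline, with their parameter sets.
demo_trees <- function() {
  g <- demo_guideline()
  list(locoregional = find_demo_tree(g, "locoregional_staging"),
       evaluation_of_n = find_demo_tree(g, "evaluation_of_n"))
}

find_demo_tree <- function(g, id) node_detail_tree(g, id)

node_detail_tree <- function(g, id) {
  # reach through the public surface: decision nodes expose their tree in
  # the loaded structure
  g$body$nodes[[id]]$tree
}

demo_params <- function() demo_guideline()$parameters

# ---- random decision-tree generator (property tests) -----------------------

# Parameters used by generated trees.
random_tree_params <- function() {
  list(color = parameter_spec("color", "categorical", c("red", "green", "blue", "grey")),
       size = parameter_spec("size", "numeric", unit = "cm"))
}

# A random tree whose every test partitions its parameter's domain. A
# parameter is never re-tested further down the same path, so every leaf is
# reachable.
random_partition_tree <- function(params, depth = 2L, counter = new.env()) {
  if (is.null(counter$k)) counter$k <- 0L
  leaf <- function() {
    counter$k <- counter$k + 1L
    tree_leaf(sprintf("L%02d", counter$k))
  }
  if (depth == 0L || length(params) == 0L) return(leaf())
  pi <- sample(length(params), 1)
  p <- params[[pi]]
  rest <- params[-pi]
  child <- function() {
    if (stats::runif(1) < 0.5) leaf() else
      random_partition_tree(rest, depth - 1L, counter)
  }
  if (identical(p$kind, "categorical")) {
    vals <- sample(p$allowed_values)
    ngroups <- sample(2:min(3, length(vals)), 1)
    grp <- sort(rep_len(seq_len(ngroups), length(vals)))
    branches <- lapply(split(vals, grp), function(vs) {
      pred <- if (length(vs) == 1) new_predicate_eq(vs) else new_predicate_in(vs)
      tree_branch(pred, child())
    })
  } else {
    cuts <- sort(unique(round(stats::runif(sample(1:2, 1), -5, 5), 1)))
    bounds <- c(-Inf, cuts, Inf)
    branches <- lapply(seq_len(length(bounds) - 1), function(i) {
      tree_branch(new_predicate_interval(bounds[i], bounds[i + 1],
                                         lo_closed = is.finite(bounds[i]),
                                         hi_closed = FALSE),
                  child())
    })
  }
  tree_test(p$name, unname(branches))
}

# Random data point over the parameter domains.
random_data_point <- function(params) {
  out <- list()
  for (p in params) {
    out[[p$name]] <- if (identical(p$kind, "categorical")) {
      sample(p$allowed_values, 1)
    } else {
      round(stats::rnorm(1, 0, 4), 2)
    }
  }
  out
}

# Depth-first control-flow order over a subgraph, re-implemented from the
# definition to serve as the ordering oracle for flatten.
cig_cf_order_for_test <- function(sg) {
  seen <- character()
  rec <- function(id) {
    if (id %in% seen) return(invisible())
    seen <<- c(seen, id)
    for (s in sort(sg$arcs$to[sg$arcs$from == id])) rec(s)
  }
  rec(sg$start)
  seen
}

# ---- independent Fisher oracle ---------------------------------------------

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins via log-binomial coefficients (no dhyper, no fisher.test) and sum
# the probabilities not exceeding the observed table's.
fisher_enumeration_oracle <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, byrow = TRUE)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  pobs <- p[ks == tab[1, 1]]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# ---- validator fault-injection catalog -------------------------------------

# One mutation of the demo guideline per spec'd issue code.
fault_catalog <- function() {
  list(
    DANGLING_ARC = function(g) {
      g$body$arcs$to[g$body$arcs$from == "assessment"] <- "no_such_node"
      g
    },
    CYCLE = function(g) {
      g$body$arcs <- rbind(g$body$arcs,
                           data.frame(from = "tnm_report", to = "excision_slnb"))
      g
    },
    MULTI_SUCCESSOR = function(g) {
      g$body$arcs <- rbind(g$body$arcs,
                           data.frame(from = "excision_slnb", to = "n0"))
      g
    },
    ORPHAN_LEAF_CONCLUSION = function(g) {
      g$body$nodes$evaluation_of_n$tree$branches[[1]]$child$leaf <- "tis"
      g
    },
    NON_EXHAUSTIVE_TREE = function(g) {
      tr <- g$body$nodes$evaluation_of_n$tree
      tr$branches <- tr$branches[1:3]
      g$body$nodes$evaluation_of_n$tree <- tr
      g
    },
    OVERLAPPING_BRANCHES = function(g) {
      g$body$nodes$evaluation_of_n$tree$branches[[3]]$when$lo <- 1.5
      g
    },
    UNKNOWN_PARAMETER = function(g) {
      g$body$nodes$tnm_report$requests <-
        c(g$body$nodes$tnm_report$requests, "mystery_parameter")
      g
    },
    BAD_START = function(g) {
      g$body$start <- "no_such_node"
      g
    },
    BAD_END = function(g) {
      g$body$ends <- c(g$body$ends, "no_such_node")
      g
    }
  )
}

# Perfect / adversarial answer scripts for a question list.
perfect_answers <- function(questions) lapply(questions, `[[`, "correct")

adversarial_answers <- function(questions) {
  lapply(questions, function(q) {
    if (identical(q$kind, "data_items")) return(character())
    ids <- vapply(q$options, `[[`, character(1), "id")
    setdiff(ids, q$correct)[1]
  })
}
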