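test_that("demo guideline is valid and carries the expected top-level actions", {
  g <- demo_guideline()
  expect_true(validate_guideline(g)$valid)
  top_labels <- vapply(g$body$nodes, `[[`, character(1), "label")
  for (lab in c("Assessment", "Excision of sentinel lymph node",
                "Report for staging TNM", "Locoregional staging", "TIS")) {
    expect_true(lab %in% top_labels)
  }
  # repeated construction is deterministic
  expect_true(guideline_identical(g, demo_guideline()))
})

test_that("CIG-JSON round-trips and saves are byte-stable", {
  for (g in list(demo_guideline(), one_node_guideline(),
                 doubly_nested_guideline())) {
    txt <- save_guideline(g)
    g2 <- load_guideline(txt)
    expect_true(guideline_identical(g, g2))
    expect_identical(save_guideline(g2), txt)
  }
})

test_that("save/load can use files and a composite body nests under its node", {
  g <- demo_guideline()
  f <- withr::local_tempfile(fileext = ".json")
  save_guideline(g, f)
  g2 <- load_guideline(f)
  expect_true(guideline_identical(g, g2))
  # the composite's body is serialized under the composite node
  doc <- jsonlite::fromJSON(save_guideline(g), simplifyVector = FALSE)
  ids <- vapply(doc$body$nodes, `[[`, character(1), "id")
  assessment <- doc$body$nodes[[which(ids == "assessment")]]
  expect_identical(assessment$kind, "composite")
  nested_ids <- vapply(assessment$body$nodes, `[[`, character(1), "id")
  expect_setequal(nested_ids, c("dermoscopy", "biopsy_report"))
})

test_that("loading rejects malformed JSON and unknown node kinds", {
  expect_error(load_guideline("{ this is not json"))
  bad <- '{"id":"x","name":"x","version":"1","parameters":[],
           "body":{"start":"a","ends":["a"],
                   "nodes":[{"id":"a","kind":"banana","label":"A"}],"arcs":[]}}'
  expect_error(load_guideline(bad), "banana", class = "cig_format_error")
  expect_error(load_guideline(bad), "'a'")
})

test_that("each injected fault triggers its validator code; clean fixtures none", {
  g <- demo_guideline()
  expect_identical(nrow(validate_guideline(g)$issues), 0L)
  expect_identical(nrow(validate_guideline(one_node_guideline())$issues), 0L)
  catalog <- fault_catalog()
  for (code in names(catalog)) {
    broken <- catalog[[code]](g)
    rep <- validate_guideline(broken)
    expect_false(rep$valid, info = code)
    expect_true(code %in% rep$issues$code, info = code)
  }
})

test_that("flatten splices composites and preserves atomic nodes", {
  g <- demo_guideline()
  flat <- flatten_guideline(g)
  expect_false(any(vapply(flat$nodes, function(n) n$kind == "composite",
                          logical(1))))
  expect_true(all(c("dermoscopy", "biopsy_report") %in% names(flat$nodes)))
  expect_false("assessment" %in% names(flat$nodes))
  # incoming rewired to body start; body end rewired to composite successor
  expect_identical(flat$start, "dermoscopy")
  expect_true(any(flat$arcs$from == "biopsy_report" &
                  flat$arcs$to == "locoregional_staging"))
  # flat input is untouched
  line <- straight_line_guideline(3)
  flat_line <- flatten_guideline(line)
  expect_identical(names(flat_line$nodes), names(line$body$nodes))
  expect_identical(flat_line$arcs, line$body$arcs)
  # doubly nested flattens completely
  flat2 <- flatten_guideline(doubly_nested_guideline())
  expect_setequal(names(flat2$nodes), c("a1", "a2", "b1", "c1"))
  expect_identical(flat2$start, "a1")
  expect_identical(flat2$ends, "c1")
})

test_that("flatten preserves the hierarchical traversal order of atomic nodes", {
  for (g in list(demo_guideline(), doubly_nested_guideline())) {
    # hierarchical traversal, descending into composites
    walk <- function(sg) {
      out <- character()
      for (id in cig_cf_order_for_test(sg)) {
        n <- sg$nodes[[id]]
        out <- c(out, if (identical(n$kind, "composite")) walk(n$body) else id)
      }
      out
    }
    flat <- flatten_guideline(g)
    expect_identical(cig_cf_order_for_test(flat), walk(g$body))
  }
})

test_that("outline respects depth and lists every node when deep enough", {
  g <- demo_guideline()
  d0 <- strsplit(guideline_outline(g, 0), "\n")[[1]]
  expect_identical(d0[1], "Assessment")
  expect_length(d0, length(g$body$nodes))
  d1 <- strsplit(guideline_outline(g, 1), "\n")[[1]]
  expect_identical(length(d1) - length(d0), 2L)  # Assessment's two children
  dmax <- strsplit(guideline_outline(g, 99), "\n")[[1]]
  expect_length(dmax, 14L)
  nested <- doubly_nested_guideline()
  expect_length(strsplit(guideline_outline(nested, 99), "\n")[[1]], 6L)
})

test_that("DOT export maps kinds to shapes and counts match the level", {
  g <- demo_guideline()
  dot <- guideline_to_dot(g, "top")
  expect_match(dot, '"assessment" \\[label="Assessment", shape=octagon')
  expect_match(dot, 'shape=diamond, style=filled, fillcolor=yellow')
  expect_match(dot, '"tis" \\[label="TIS", shape=triangle')
  lines <- strsplit(dot, "\n")[[1]]
  expect_identical(sum(grepl("shape=", lines)), length(g$body$nodes))
  expect_identical(sum(grepl(" -> ", lines)), nrow(g$body$arcs))
  # nested level
  dot2 <- guideline_to_dot(g, "assessment")
  expect_match(dot2, 'shape=parallelogram, style=filled, fillcolor=green')
  # one-node guideline: one node statement, zero edges
  dot3 <- guideline_to_dot(one_node_guideline())
  lines3 <- strsplit(dot3, "\n")[[1]]
  expect_identical(sum(grepl("shape=", lines3)), 1L)
  expect_identical(sum(grepl(" -> ", lines3)), 0L)
  expect_error(guideline_to_dot(g, "no_such_level"), class = "cig_format_error")
})

test_that("node_detail is total over valid ids and renders decision trees", {
  g <- demo_guideline()
  for (id in c("assessment", "dermoscopy", "biopsy_report", "tis",
               "evaluation_of_n", "n2a")) {
    expect_silent(node_detail(g, id))
  }
  d <- node_detail(g, "evaluation_of_n")
  expect_identical(d$kind, "decision")
  expect_match(d$tree_rendering, "num_positive_nodes")
  expect_length(d$media, 1L)
  expect_identical(node_detail(g, "excision_slnb")$media, list())
  expect_null(node_detail(g, "excision_slnb")$tree_rendering)
  expect_error(node_detail(g, "nope"), class = "cig_format_error")
})
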