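test_that("check_tree accepts partitions and flags overlaps, gaps, unknowns", {
  params <- demo_params()
  for (t in demo_trees()) expect_identical(nrow(check_tree(t, params)), 0L)

  yn <- list(ulceration = params$ulceration)
  ok <- tree_test("ulceration", list(
    tree_branch(new_predicate_eq("yes"), tree_leaf("a")),
    tree_branch(new_predicate_eq("no"), tree_leaf("b"))))
  expect_identical(nrow(check_tree(ok, yn)), 0L)

  overlap <- tree_test("Breslow_thickness", list(
    tree_branch(new_predicate_interval(0, 2), tree_leaf("a")),
    tree_branch(new_predicate_interval(1, Inf), tree_leaf("b"))))
  expect_true("OVERLAPPING_BRANCHES" %in% check_tree(overlap, params)$code)
  # ... and [0, 2) alone leaves both tails uncovered
  expect_true("NON_EXHAUSTIVE_TREE" %in% check_tree(overlap, params)$code)

  gap <- tree_test("ulceration", list(
    tree_branch(new_predicate_eq("yes"), tree_leaf("a"))))
  expect_true("NON_EXHAUSTIVE_TREE" %in% check_tree(gap, yn)$code)

  unknown <- tree_test("nonexistent", list(
    tree_branch(new_predicate_eq("x"), tree_leaf("a"))))
  expect_identical(check_tree(unknown, params)$code, "UNKNOWN_PARAMETER")
})

test_that("random partition trees are clean and evaluation is total and unique", {
  params <- random_tree_params()
  withr::with_seed(4242, {
    for (rep in 1:40) {
      t <- random_partition_tree(params, depth = 2L)
      expect_identical(nrow(check_tree(t, params)), 0L)
      for (j in 1:25) {
        d <- random_data_point(params)
        res <- evaluate_tree(t, d)          # errors if no branch matches
        expect_true(res$leaf %in% tree_leaves(t))
        # exactly one branch matches at every visited test
        node <- t
        for (st in res$path) {
          hits <- vapply(node$branches, function(b) {
            cigsim:::match_predicate(b$when, d[[node$test]])
          }, logical(1))
          expect_identical(sum(hits), 1L)
          node <- node$branches[[st$branch]]$child
        }
      }
    }
  })
})

test_that("evaluation descends deterministically and reports missing data", {
  trees <- demo_trees()
  single <- tree_leaf("only")
  res <- evaluate_tree(single, list())
  expect_identical(res$leaf, "only")
  expect_length(res$path, 0L)

  d <- list(invasion_level = "invasive", Breslow_thickness = 0.5)
  r1 <- evaluate_tree(trees$locoregional, d)
  expect_identical(r1$leaf, "t1")
  expect_length(r1$path, 2L)
  expect_identical(evaluate_tree(trees$locoregional, d), r1)  # bit-identical

  expect_identical(evaluate_tree(trees$evaluation_of_n,
                                 list(num_positive_nodes = 3))$leaf, "n2a")
  err <- tryCatch(evaluate_tree(trees$evaluation_of_n, list()),
                  cig_missing_data = function(e) e)
  expect_s3_class(err, "cig_missing_data")
  expect_identical(err$parameter, "num_positive_nodes")
})

test_that("witness synthesis follows the midpoint/choice policy and round-trips", {
  params <- demo_params()
  trees <- demo_trees()
  w <- witness_for(trees$evaluation_of_n, "n2a", params, seed = 1)
  expect_identical(w$num_positive_nodes, 3)           # midpoint of [2, 4)
  w2 <- witness_for(trees$locoregional, "tis", params, seed = 1)
  expect_identical(w2$invasion_level, "in_situ")      # eq takes the value
  w3 <- witness_for(trees$locoregional, "t2plus", params, seed = 1)
  expect_identical(w3$Breslow_thickness, 2)           # lo + 1 on [1, inf)

  # adjunction: every leaf of every fixture tree evaluates back to itself
  for (t in trees) {
    for (leaf in tree_leaves(t)) {
      expect_identical(evaluate_tree(t, witness_for(t, leaf, params, 9))$leaf,
                       leaf)
    }
  }
  # ... and over random generated trees
  rparams <- random_tree_params()
  withr::with_seed(77, {
    for (rep in 1:20) {
      t <- random_partition_tree(rparams, depth = 2L)
      for (leaf in tree_leaves(t)) {
        expect_identical(evaluate_tree(t, witness_for(t, leaf, rparams, rep))$leaf,
                         leaf)
      }
    }
  })
  expect_error(witness_for(trees$locoregional, "not_a_leaf", params, 1),
               class = "cig_format_error")
})

test_that("explanations pair the correct path with the learner's leaf", {
  params <- demo_params()
  t <- demo_trees()$evaluation_of_n
  d <- list(num_positive_nodes = 3)
  e <- explain_decision(t, d, "n3a")
  expect_identical(e$correct_leaf, "n2a")
  expect_identical(e$learner_leaf, "n3a")
  expect_length(e$narrative, length(e$visited))
  expect_match(e$narrative[1], "num_positive_nodes = 3 satisfies \\[2, 4\\)")
  # a correct learner still gets a (trivial) explanation
  e2 <- explain_decision(t, d, "n2a")
  expect_identical(e2$correct_leaf, e2$learner_leaf)
  # explanation does not depend on learner_choice except via learner_leaf
  e3 <- explain_decision(t, d, "n0")
  expect_identical(e3$visited, e$visited)
  expect_identical(e3$correct_leaf, e$correct_leaf)
  expect_error(explain_decision(t, d, "zebra"), class = "cig_format_error")
})

test_that("tree rendering marks the visited path and the learner leaf", {
  expect_identical(render_tree(tree_leaf("only")), "only")
  t <- demo_trees()$locoregional
  res <- evaluate_tree(t, list(invasion_level = "invasive",
                               Breslow_thickness = 0.5))
  txt <- render_tree(t, marks = list(result = res, learner_leaf = "tis"))
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(sum(grepl("\\[X\\]", lines)), 1L)
  expect_identical(sum(grepl("\\[\\*\\]", lines)), length(res$path) + 1L)
  expect_match(lines[1], "^\\[\\*\\] \\? invasion_level")
  # unmarked rendering has no mark characters
  expect_false(grepl("\\[\\*\\]|\\[X\\]", render_tree(t)))
})
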