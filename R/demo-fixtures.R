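# Deterministic melanoma-derived demo fixtures.
#
# The guideline skeleton uses the standard labels of a melanoma workup
# (assessment, sentinel-node excision, TNM staging report, locoregional
# staging, evaluation of N). The decision trees are deliberately simplified
# teaching material: they are NOT the AJCC staging rules and must not be
# read as clinically valid.

#' Build the demo melanoma-derived guideline
#'
#' A small two-level guideline: a composite "Assessment" (dermatoscopic
#' examination followed by a biopsy report request), a "Locoregional
#' staging" decision (in-situ disease exits early via the "TIS" conclusion,
#' invasive disease is split on Breslow thickness), sentinel-node excision,
#' the "Report for staging TNM" data request, and an "Evaluation of N"
#' decision splitting on the number of positive nodes into N0/N1a/N2a/N3a.
#' The construction is deterministic and always passes
#' [validate_guideline()].
#'
#' @return object of class `cig_guideline`.
#' @export
build_demo_guideline <- function() {
  params <- list(
    parameter_spec("invasion_level", "categorical", c("in_situ", "invasive")),
    parameter_spec("Breslow_thickness", "numeric", unit = "mm"),
    parameter_spec("ulceration", "categorical", c("yes", "no")),
    parameter_spec("num_positive_nodes", "numeric", unit = "nodes")
  )

  assessment_body <- subgraph(
    nodes = list(
      action_node("dermoscopy", "work", "Dermatoscopic examination",
                  "Inspect the lesion with a dermatoscope."),
      action_node("biopsy_report", "data_request", "Lesion biopsy report",
                  "Histopathology of the excised lesion.",
                  requests = c("invasion_level", "Breslow_thickness", "ulceration"))
    ),
    arcs = list(c("dermoscopy", "biopsy_report")),
    start = "dermoscopy", ends = "biopsy_report")

  locoregional_tree <- tree_test("invasion_level", list(
    tree_branch(new_predicate_eq("in_situ"), tree_leaf("tis")),
    tree_branch(new_predicate_eq("invasive"),
                tree_test("Breslow_thickness", list(
                  tree_branch(new_predicate_interval(-Inf, 1, FALSE, FALSE),
                              tree_leaf("t1")),
                  tree_branch(new_predicate_interval(1, Inf, TRUE, FALSE),
                              tree_leaf("t2plus"))
                )))
  ))

  n_tree <- tree_test("num_positive_nodes", list(
    tree_branch(new_predicate_interval(-Inf, 1, FALSE, FALSE), tree_leaf("n0")),
    tree_branch(new_predicate_interval(1, 2, TRUE, FALSE), tree_leaf("n1a")),
    tree_branch(new_predicate_interval(2, 4, TRUE, FALSE), tree_leaf("n2a")),
    tree_branch(new_predicate_interval(4, Inf, TRUE, FALSE), tree_leaf("n3a"))
  ))

  body <- subgraph(
    nodes = list(
      action_node("assessment", "composite", "Assessment",
                  "Initial diagnostic workup of the lesion.",
                  body = assessment_body),
      action_node("locoregional_staging", "decision", "Locoregional staging",
                  "Classify the primary tumor from the biopsy report.",
                  tree = locoregional_tree),
      action_node("tis", "conclusion", "TIS",
                  "Melanoma in situ; no nodal workup required."),
      action_node("t1", "conclusion", "T1",
                  "Invasive melanoma, Breslow thickness below 1 mm."),
      action_node("t2plus", "conclusion", "T2-T4",
                  "Invasive melanoma, Breslow thickness 1 mm or more."),
      action_node("excision_slnb", "work", "Excision of sentinel lymph node",
                  "Sentinel lymph node biopsy."),
      action_node("tnm_report", "data_request", "Report for staging TNM",
                  "Nodal pathology report used for N staging.",
                  requests = "num_positive_nodes"),
      action_node("evaluation_of_n", "decision", "Evaluation of N",
                  "Nodal staging from the number of positive sentinel nodes.",
                  media = list(list(ref = "media/n-staging-diagram.png",
                                    caption = "Nodal staging workup sketch")),
                  tree = n_tree),
      action_node("n0", "conclusion", "N0", "No nodal involvement."),
      action_node("n1a", "conclusion", "N1a", "One positive node."),
      action_node("n2a", "conclusion", "N2a", "Two or three positive nodes."),
      action_node("n3a", "conclusion", "N3a", "Four or more positive nodes.")
    ),
    arcs = list(
      c("assessment", "locoregional_staging"),
      c("locoregional_staging", "tis"),
      c("locoregional_staging", "t1"),
      c("locoregional_staging", "t2plus"),
      c("t1", "excision_slnb"),
      c("t2plus", "excision_slnb"),
      c("excision_slnb", "tnm_report"),
      c("tnm_report", "evaluation_of_n"),
      c("evaluation_of_n", "n0"),
      c("evaluation_of_n", "n1a"),
      c("evaluation_of_n", "n2a"),
      c("evaluation_of_n", "n3a")
    ),
    start = "assessment",
    ends = c("tis", "n0", "n1a", "n2a", "n3a"))

  guideline(id = "melanoma-demo", name = "Melanoma workup (demo)",
            version = "1.0", parameters = params, body = body)
}

#' Build the demo case studies
#'
#' Returns a deterministic list of complete case studies for the demo
#' guideline: one hand-written case whose "Evaluation of N" outcome is
#' "N2a" (the worked verification scenario), plus one synthesized case per
#' enumerated control path.
#'
#' @return named list of case studies; the worked scenario is
#'   `$demo_case_n2a`.
#' @export
build_demo_cases <- function() {
  g <- build_demo_guideline()
  designated <- case_study(
    id = "demo-case-n2a",
    description = paste("58-year-old with an invasive 0.5 mm non-ulcerated",
                        "melanoma and three positive sentinel nodes."),
    guideline_id = g$id,
    bindings = list(
      biopsy_report = list(invasion_level = "invasive",
                           Breslow_thickness = 0.5,
                           ulceration = "no"),
      tnm_report = list(num_positive_nodes = 3)
    ))
  paths <- enumerate_paths(g)
  synthesized <- lapply(seq_along(paths), function(i) {
    synthesize_case(g, paths[[i]], seed = 100L + i,
                    id = sprintf("demo-case-path-%02d", i))
  })
  names(synthesized) <- vapply(synthesized, `[[`, character(1), "id")
  c(list(demo_case_n2a = designated), synthesized)
}
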