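# cigsim

Simulation and learner verification for computer-interpretable clinical
guidelines (CIGs).

Clinical practice guidelines (CPGs) are the evidence-based "how to act"
knowledge of medicine, but they are published as long flat documents, and
learners struggle to map them onto concrete patients. `cigsim` is for
medical educators and health-informatics researchers who want to turn a
guideline into an executable teaching object. It provides:

* a **guideline formalism and JSON file format**: a hierarchical typed
  action graph — work actions, data requests, decision nodes with explicit
  decision trees, conclusions, and composite nodes refined into subgraphs —
  with a structural validator and Graphviz/outline exports;
* **case studies as data**: virtual patients represented purely by
  parameter values bound to the guideline's data-request nodes, authored
  by hand, by a guided walk, or synthesized automatically for any control
  path;
* an **automated simulation engine** that shows, step by step, how the
  guideline would manage a case (the case data dictate the path; the user
  makes no choices);
* a **verification engine** that quizzes a learner at every step — which
  action comes next, which data are required, which decision outcome is
  correct — scores the answers by category (activities / required data /
  decisions), and explains wrong decisions by highlighting the visited
  decision-tree path against the learner's choice;
* **evaluation statistics** for two-group teaching comparisons:
  percent-correct tables, percentage-point improvements, and Fisher's
  exact test for 2×2 outcome tables.

At the core is one invariant: every decision tree must *partition* its
parameters' domains (mutually exclusive, jointly exhaustive branches —
categorical values partition `allowed_values`, numeric intervals `[lo, hi)`
partition the real line). Validated guidelines therefore simulate totally
and deterministically: for a case `c` with complete data, the engine's
induced path `π(c)` is always one of the finitely many control paths
`enumerate_paths(g)`, and conversely every enumerated path is induced by a
witness case built by inverting the decision trees
(`evaluate(witness(leaf)) = leaf`).

## Worked example

The package ships a melanoma-derived demo guideline (labels from a
standard melanoma workup; the decision trees are simplified teaching
fixtures, *not* clinically valid staging rules):

```r
library(cigsim)
g <- build_demo_guideline()
cat(guideline_outline(g, depth = 1))
#> Assessment
#>   Dermatoscopic examination
#>   Lesion biopsy report
#> Locoregional staging
#> T1
#> Excision of sentinel lymph node
#> Report for staging TNM
#> Evaluation of N
#> N0
#> ...
```

Run a verification session on the worked case (three positive sentinel
nodes, so the correct N stage is N2a) with a learner who answers
everything right except the N-staging decision, where they pick N3a:

```r
case <- build_demo_cases()$demo_case_n2a
qs <- make_questions(g, case, seed = 1)
answers <- lapply(qs, `[[`, "correct")
answers[[which(sapply(qs, `[[`, "node") == "evaluation_of_n")]] <- "n3a"
run_session(g, case, answers, seed = 1)
#> Verification of case 'demo-case-n2a' against guideline 'melanoma-demo'
#>
#>   activities    3/3 correct (100.0%)
#>   required_data 2/2 correct (100.0%)
#>   decisions     1/2 correct (50.0%)
#>
#> Discrepancies:
#> - [decision_outcome] Given the case data so far, what is the outcome of 'Evaluation of N'?
#>     answered: n3a | correct: n2a
#>     parameter num_positive_nodes = 3 satisfies [2, 4)
#> [*] ? num_positive_nodes
#>   - (-inf, 1):
#>     n0
#>   - [1, 2):
#>     n1a
#>   - [2, 4):
#>     [*] n2a
#>   - [4, inf):
#>     [X] n3a
```

The report reads: the learner scored 100% on activity ordering and data
requirements but got one of two decisions wrong; the explanation shows the
tree path the case data actually select (`[*]`, the case has 3 positive
nodes, which satisfies `[2, 4)` and leads to N2a) against the learner's
leaf (`[X]` N3a).

Feeding a published two-group percent-correct table back through the
statistics module gives the percentage-point training gains:

```r
r <- group_results_from_percent(list(
  traditional  = list(activities = 41, required_data = 77, n_staging = 12.5),
  cig_training = list(activities = 51, required_data = 81, n_staging = 22)))
improvement(r, "cig_training", "traditional", "activities")    # 10.0
improvement(r, "cig_training", "traditional", "required_data") #  4.0
improvement(r, "cig_training", "traditional", "n_staging")     #  9.5
```

A command-line interface wraps the same functions
(`inst/cli/cig validate|outline|export-dot|fixtures|gen-case|validate-case|acquire|simulate|paths|verify|stats`);
every interactive feature has a scripted twin.

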