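---
title: "A simulation and verification engine for computer-interpretable clinical guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simulation and verification engine for computer-interpretable clinical guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Clinical practice guidelines are long, flat documents; learning which
recommendation applies to which patient is a skill of its own. `cigsim`
encodes a guideline as a *computer-interpretable guideline* (CIG) — a
hierarchical typed action graph — and builds three educational facilities
on top of it: navigation of the structure, automated step-by-step
simulation on virtual cases, and learner verification with explanations.
This vignette is the package's account of the model, its conventions, and
the design choices behind them.

## The guideline formalism

A guideline is a graph whose nodes are actions and whose arcs are control
flow. Five node kinds exist:

* **work** — an atomic clinical act (e.g., a sentinel-node excision);
* **data request** — an atomic step acquiring named parameter values;
* **decision** — an atomic step selecting among outcomes via an explicit
  decision tree;
* **conclusion** — a node modelling one outcome of a decision (e.g., a
  staging class);
* **composite** — a node refined into a nested subgraph, giving the
  hierarchy used for top-down exploration.

The structural discipline is deliberately strict, because an educational
engine must never dead-end mid-lesson:

* graphs are acyclic; iteration is out of scope for this version (the
  formalism family we follow shows no loops in its published examples, and
  guessing loop semantics would be worse than rejecting them);
* only decision nodes branch, and their successors are exactly their
  conclusions; every other node has at most one outgoing arc;
* end nodes have no outgoing arcs, and several ends per subgraph are
  allowed — guidelines legitimately terminate at different stages (an
  in-situ finding exits the melanoma workup long before nodal staging);
* node ids are global across hierarchy levels, so traces, cases, and
  learner answers can reference nodes unambiguously.

`validate_guideline()` checks all of this and reports coded issues
(`DANGLING_ARC`, `CYCLE`, `MULTI_SUCCESSOR`, `ORPHAN_LEAF_CONCLUSION`,
`NON_EXHAUSTIVE_TREE`, `OVERLAPPING_BRANCHES`, `UNKNOWN_PARAMETER`,
`BAD_START`, `BAD_END`, plus a few auxiliary codes) rather than throwing,
so authoring errors surface all at once. Cycle detection and reachability
are delegated to `igraph`; everything semantic about the formalism is
implemented here.

Persistence is a canonical JSON dialect (CIG-JSON): keys in fixed order,
parameters and nodes sorted by name/id, arcs sorted by endpoints. The
point of canonicalization is reproducibility — saving the same guideline
twice is byte-identical, and structural equality reduces to comparing
serialized text. `flatten_guideline()` splices composite bodies into their
enclosing level (incoming arcs to the body start, body ends to the
composite's successor); the flat graph is the reference semantics against
which the hierarchical walk is tested.

## Decision trees

The decision criteria of published guidelines are prose; some encoding had
to be chosen. We use the minimal predicate language that covers
staging-style rules exactly:

* `eq` / `in` for categorical parameters;
* closed-open intervals `[lo, hi)` for numeric parameters, with
  infinities. The closed-open convention means adjacent thresholds (1.0
  mm, 2.0 mm, ...) tile the axis with no overlap and no gap.

`check_tree()` verifies, at every test node, that the branch predicates
are mutually exclusive and exhaustive over the parameter's domain —
a partition of `allowed_values` for categorical tests, of the whole real
line for numeric tests. Exhaustiveness is enforced at validation time, not
discovered at run time: evaluation of a clean tree is total and
deterministic by construction. Degenerate single-branch tests are
permitted (useful while authoring).

Two derived operations make trees more than classifiers. `witness_for()`
inverts a tree: it synthesizes parameter values forcing a chosen leaf,
using a fixed deterministic policy (`eq` takes the value, `in` takes a
seeded choice, finite intervals take their midpoint, half-infinite ones
`lo + 1` / `hi − 1`, the whole line 0). Midpoints keep witness values away
from thresholds, where a reader could mistake a boundary convention for a
clinical claim. `explain_decision()` re-evaluates the tree on the case
data and pairs the visited path (the "green" nodes of a highlighted
explanation, with a one-sentence narrative per test) with the learner's
chosen leaf (the "red" one). `render_tree()` draws the ASCII tree, marking
visited tests and the correct leaf `[*]` and the learner's leaf `[X]`;
when the learner is right the `[X]` takes precedence on the shared line.

## Case studies

A virtual patient is data, nothing more: a case binds parameter values to
the *data-request nodes* of a guideline. Keying by node rather than
globally by parameter is the minimal reading of "data tracking clinical
status changes": a parameter requested again later may carry a new value,
and the runtime environment takes the latest one. Extra bindings for
nodes off the induced path are allowed and ignored by simulation — a case
authored to cover several alternative paths remains usable for each.

Cases are authored three ways, all producing the same structure:

* `acquire_case()` walks the guideline asking a callback for each
  requested value (the scripted twin of an interactive acquisition
  session); type-invalid answers are re-prompted up to three times;
* `synthesize_case()` mechanizes authoring: given a target control path it
  computes tree witnesses for every decision on the path and attaches each
  witness value to the *last* data request before the consuming decision
  (so latest-wins delivers exactly the witness); unconstrained requested
  parameters get seeded domain samples;
* hand-written JSON (CASE-JSON), validated by `validate_case()`, which
  type-checks bindings and probes the case with a full simulation —
  a case is *complete* iff the probe reaches an end node.

## Simulation and verification

`simulate_case()` executes the guideline on a case with no user choices:
work actions are recorded and passed, data requests copy their bindings
into the environment, decisions evaluate their tree and jump to the chosen
conclusion, composites descend into their body (descend/ascend markers are
kept in the trace so a renderer can show per-level progress, but are
excluded from the induced atomic path). Incomplete cases *block* rather
than throw — the trace carries the reason and location, which is the right
failure mode for teaching material. `enumerate_paths()` is the brute-force
oracle: all root-to-end atomic paths of the flattened graph, depth-first,
arcs in canonical order. The central engine property, tested exhaustively
on the demo guideline, is the adjunction between the two: every enumerated
path is induced by a synthesized case, and every simulated trace's atomic
path is a member of the enumeration.

`make_questions()` turns a reference trace into a quiz: a `next_action`
multiple-choice question before each work/composite action (the correct
node plus up to three seeded distractors drawn from the same hierarchy
level — plausible confusables, reproducibly chosen; conclusions are not
offered as distractors since they are outcomes, not actions), a
`data_items` free-set question at each data request, and a
`decision_outcome` question over all conclusion successors at each
decision. Question kinds map onto the three reported score categories:
activities, required data, decisions. Grading is deliberately simple:
set equality (no partial credit) for data items, key equality for
selections; a wrong decision answer gets an explanation attached; a wrong
answer never derails the session, because the comparison is step-by-step
against the guideline's own path, which is fixed by the case. Questions
are quizzed at every hierarchy level traversed, not just the top one.

## Evaluation statistics

`percent_correct()` and `improvement()` implement the arithmetic of a
two-group teaching comparison (percentages to one decimal, half-up, the
convention of printed result tables; `group_results_from_percent()` lets
published percentage tables be fed back in exactly, using a common
denominator of 1000). `fisher_exact()` is the appropriate test for two
dichotomous nominal variables with small samples; it delegates to
`stats::fisher.test()` (whose two-sided p is the standard "sum of small p"
over margin-fixed tables) after rejecting degenerate tables, and the test
suite checks it exhaustively against an independent log-binomial
enumeration for every 2×2 table with total at most 40.

## The demo fixtures, and what they do not show

`build_demo_guideline()` constructs a melanoma-derived two-level
guideline: an Assessment composite (dermatoscopic examination, biopsy
report), a Locoregional staging decision (in-situ → TIS early exit;
invasive split at 1 mm Breslow thickness), sentinel-node excision, the TNM
staging report, and an Evaluation of N decision splitting on the number of
positive nodes into N0/N1a/N2a/N3a. The labels are the standard vocabulary
of a melanoma workup; the trees are **invented, simplified teaching
fixtures** — the real AJCC staging rules are richer (ulceration,
micro/macrometastases, in-transit disease) and are deliberately not
claimed here. `build_demo_cases()` returns one hand-written case (the
worked discrepancy scenario: three positive nodes, correct answer N2a,
learner answer N3a) plus one synthesized case per enumerated path, with
fixed seeds so the fixtures are identical across calls.

Consequently, passing tests show that the *engine* is correct on graphs
of this shape — hierarchy, early exits, shared continuations, multi-way
decisions — not that any clinical content is right, and not that the
engine scales to guidelines with hundreds of nodes (nothing in the design
prevents it, but it is unmeasured here). Human-study outcomes are of
course not reproducible by software at all; only the published
improvement arithmetic is recomputed.

## Numerical and scale choices

* Percent rounding: half away from zero at one decimal, with a 1e-9 guard
  against binary-representation ties.
* Witness policy and question generation draw randomness only through an
  explicit seed, scoped so the caller's RNG state is untouched.
* Problem sizes in the shipped tests: the 14-node demo guideline with 9
  control paths (exhaustive where the property allows it), 1000 random
  samples per fixture tree for the partition property, 40 random trees ×
  25 data points for generated-tree properties, and the full 132,470-table
  grid for the Fisher cross-check. These sizes keep the default suite
  around a minute while leaving every property exhaustive at its natural
  scale.

## Known limitations

* No iteration/loops, no parallel branches, no temporal constraints or
  action durations; conclusions carry at most one successor.
* No ontology binding for terms; media attachments are opaque references.
* Decision trees must be explicit; free-text criteria are not parsed.
* No partial credit, adaptive questioning, or learner modelling in the
  verification engine.
* Comorbidity (multiple interacting guidelines) is out of scope.
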