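# Evaluation statistics for comparing training groups: percent-correct
# tables per category, percentage-point improvements between groups, and
# Fisher's exact test for 2x2 outcome tables (appropriate for two
# dichotomous nominal variables with small samples).

#' Construct per-group per-category answer counts
#'
#' @param groups named list: group label -> named list: category ->
#'   `list(correct = n, total = n)`.
#' @return object of class `cig_group_results`.
#' @export
group_results <- function(groups) {
  for (gl in names(groups)) {
    for (cat in names(groups[[gl]])) {
      cell <- groups[[gl]][[cat]]
      if (!is.numeric(cell$correct) || !is.numeric(cell$total) ||
          cell$correct < 0 || cell$correct > cell$total) {
        cig_abort(sprintf("bad counts for %s/%s: need 0 <= correct <= total",
                          gl, cat), "cig_format_error")
      }
    }
  }
  structure(list(groups = groups), class = "cig_group_results")
}

#' Build group results from printed percentages
#'
#' Study reports often print only the percentage of correct answers per
#' group and category. This helper converts such a percentage table into
#' counts over a common denominator so the arithmetic operations
#' ([percent_correct()], [improvement()]) can be applied to published
#' numbers. With the default `total = 1000` every percentage printed to one
#' decimal is represented exactly.
#'
#' @param percents named list: group label -> named list: category ->
#'   percentage (0-100).
#' @param total denominator used for every cell.
#' @return object of class `cig_group_results`.
#' @export
group_results_from_percent <- function(percents, total = 1000L) {
  groups <- lapply(percents, function(cats) {
    lapply(cats, function(pct) {
      list(correct = round(pct * total / 100), total = total)
    })
  })
  group_results(groups)
}

#' Percent correct per group and category
#'
#' `100 * correct / total`, rounded half-up to one decimal. Cells with a
#' zero total are omitted with a warning.
#'
#' @param r a `cig_group_results`.
#' @return data frame with columns `group`, `category`, `n_correct`,
#'   `n_total`, `percent`.
#' @export
percent_correct <- function(r) {
  rows <- list()
  for (gl in names(r$groups)) {
    for (cat in names(r$groups[[gl]])) {
      cell <- r$groups[[gl]][[cat]]
      if (cell$total == 0) {
        warning(sprintf("omitting %s/%s: zero total", gl, cat))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = gl, category = cat, n_correct = cell$correct,
        n_total = cell$total,
        percent = round_half_up(100 * cell$correct / cell$total, 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(group = character(), category = character(),
               n_correct = numeric(), n_total = numeric(), percent = numeric())
  rownames(out) <- NULL
  out
}

#' Percentage-point improvement of one group over another
#'
#' The difference of the two groups' percent-correct values in one
#' category, to one decimal. Antisymmetric in its group arguments.
#'
#' @param r a `cig_group_results`.
#' @param treat,ctrl group labels (e.g. tool-supported vs. traditional
#'   teaching).
#' @param category category label present in both groups.
#' @return numeric scalar (percentage points).
#' @export
improvement <- function(r, treat, ctrl, category) {
  pc <- percent_correct(r)
  pt <- pc$percent[pc$group == treat & pc$category == category]
  pq <- pc$percent[pc$group == ctrl & pc$category == category]
  if (length(pt) != 1 || length(pq) != 1) {
    cig_abort(sprintf("category '%s' must be present in both groups", category),
              "cig_format_error")
  }
  round_half_up(pt - pq, 1)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under fixed margins, with the standard
#' "sum of small p" convention: the sum of hypergeometric probabilities of
#' every margin-consistent table whose probability does not exceed the
#' observed table's. Rows are groups, columns correct/incorrect counts.
#'
#' @param tab a 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @return the two-sided p-value in `[0, 1]`.
#' @section Errors: negative counts or a zero row/column margin (a
#'   degenerate table with no variation to test) raise an error.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    cig_abort("need a 2x2 table of non-negative integer counts",
              "cig_format_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    cig_abort("degenerate table: a margin is zero", "cig_format_error")
  }
  unname(stats::fisher.test(tab)$p.value)
}
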