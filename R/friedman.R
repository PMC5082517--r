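#' Ordinal outcome scores
#'
#' Maps three-way classification outcomes to the ordinal scale used for
#' biomarker comparison: correct = 2, uncertain = 1, misclassified = 0. Any
#' strictly monotone coding yields the same within-subject ranks, so the
#' choice does not affect the Friedman statistic.
#'
#' @param outcomes per-subject outcomes in `"ige"`, `"normal"`, `"uncertain"`.
#' @param labels matching true labels (`"ige"`/`"patient"` or `"control"`).
#' @return Integer vector of scores in `{0, 1, 2}`.
#' @export
outcome_scores <- function(outcomes, labels) {
  if (length(outcomes) != length(labels))
    stop("outcomes and labels differ in length")
  correct <- ifelse(is_ige_label(labels), "ige", "normal")
  ifelse(outcomes == correct, 2L,
         ifelse(outcomes == "uncertain", 1L, 0L))
}

#' Subjects x biomarkers outcome matrix for one cohort
#'
#' Assembles the ordinal outcome scores of several biomarkers for the
#' subjects of one cohort arm. The arms are never pooled: the comparison is
#' run separately for patients and controls.
#'
#' @param classifications named list of [loocv_classify()] results over the
#'   same subjects in the same order.
#' @param labels per-subject true labels.
#' @param cohort `"ige"` or `"control"`: which arm to keep.
#' @return Integer matrix (subjects x biomarkers) of class `outcome_matrix`.
#' @export
outcome_matrix <- function(classifications, labels,
                           cohort = c("ige", "control")) {
  cohort <- match.arg(cohort)
  keep <- if (cohort == "ige") is_ige_label(labels) else !is_ige_label(labels)
  if (!any(keep)) stop("outcome_matrix: no subjects in the requested cohort")
  cols <- lapply(classifications, function(cc) {
    stopifnot(inherits(cc, "cohort_classification"))
    outcome_scores(cc$folds$outcome, labels)[keep]
  })
  m <- do.call(cbind, cols)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("biomarker", seq_len(ncol(m)))
  structure(m, cohort = cohort, class = c("outcome_matrix", class(m)))
}

#' Friedman test across biomarkers
#'
#' Nonparametric repeated-measures comparison of the per-subject ordinal
#' outcomes of k biomarkers: within-subject mid-ranks with the standard tie
#' correction, chi-squared statistic with k - 1 degrees of freedom. Because
#' three-way outcomes are massively tied, the tie correction is essential; a
#' matrix in which every subject's outcomes are fully tied leaves the
#' statistic undefined and raises an error. An exact Monte-Carlo permutation
#' p-value (permuting outcomes within subjects) is available as an
#' alternative to the chi-squared reference.
#'
#' @param om a numeric matrix, subjects x biomarkers (see [outcome_matrix()]).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations for `method = "permutation"`.
#' @param seed seed for the permutation draw.
#' @return List with `chi2`, `df` and `p`.
#' @export
friedman_outcomes <- function(om, method = c("chisq", "permutation"),
                              n_perm = 2000, seed = 1L) {
  method <- match.arg(method)
  om <- unclass(as.matrix(om))
  if (nrow(om) < 2L || ncol(om) < 2L)
    stop("friedman_outcomes: need at least 2 subjects and 2 biomarkers")
  all_tied <- apply(om, 1L, function(r) all(r == r[1L]))
  if (all(all_tied))
    stop("friedman_outcomes: all rows fully tied, statistic undefined")
  ft <- stats::friedman.test(om)
  chi2 <- unname(ft$statistic)
  df <- unname(ft$parameter)
  if (method == "chisq")
    return(list(chi2 = chi2, df = df, p = unname(ft$p.value)))
  stat_of <- function(m) unname(stats::friedman.test(m)$statistic)
  p <- with_seed(seed, function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- t(apply(om, 1L, sample))
      if (stat_of(perm) >= chi2 - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(chi2 = chi2, df = df, p = p)
}

#' Pairwise Friedman comparison of two biomarkers
#'
#' The Friedman test restricted to two columns (df = 1). With no tied rows
#' this reduces to a sign-test-like statistic: chi-squared equals the number
#' of non-tied rows when one biomarker dominates.
#'
#' @param om outcome matrix.
#' @param col_a,col_b column names or indices.
#' @inheritParams friedman_outcomes
#' @return List with `chi2`, `df = 1` and `p`.
#' @export
pairwise_friedman <- function(om, col_a, col_b, method = c("chisq",
                                                           "permutation"),
                              n_perm = 2000, seed = 1L) {
  om <- unclass(as.matrix(om))
  friedman_outcomes(om[, c(col_a, col_b), drop = FALSE], method = method,
                    n_perm = n_perm, seed = seed)
}
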