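# Internal orientation: values are mapped so that HIGHER always means more
# epilepsy-like; thresholds are stored in that oriented space alongside the
# direction, and reported in original units by orient(, invert = TRUE).
orient <- function(values, direction) {
  if (direction == "higher_is_ige") values else -values
}

is_ige_label <- function(labels) {
  tolower(labels) %in% c("ige", "patient")
}

#' Dual thresholds from a training set
#'
#' Two cuts on one biomarker: `th1`, the most sensitive cut that keeps
#' training specificity at 100% (zero false positives), and `th2`, the most
#' specific cut that keeps training sensitivity at 100% (zero false
#' negatives). Each cut is the midpoint between the two adjacent order
#' statistics that realize its optimum; when a control and a patient value tie
#' exactly at a boundary, the 100% requirement is enforced strictly, so the
#' cut moves past the tied value.
#'
#' @param values per-subject biomarker values (finite).
#' @param labels `"ige"`/`"patient"` vs `"control"`.
#' @param direction `"higher_is_ige"` or `"lower_is_ige"`: which side of the
#'   scale is epilepsy-like.
#' @return An object of class `threshold_pair` with oriented cuts `th1`,
#'   `th2`, the achieved training `sens_at_th1` and `spec_at_th2`, and the
#'   direction.
#' @export
optimize_thresholds <- function(values, labels,
                                direction = c("higher_is_ige",
                                              "lower_is_ige")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stop("optimize_thresholds: non-finite values")
  ige <- is_ige_label(labels)
  if (!any(ige) || all(ige))
    stop("optimize_thresholds: need both classes in the training set")
  v <- orient(values, direction)
  vi <- v[ige]
  vc <- v[!ige]
  # th1: zero false positives (no control strictly above), maximal recall
  max_c <- max(vc)
  above <- vi[vi > max_c]
  th1 <- if (length(above)) (max_c + min(above)) / 2 else max_c
  sens1 <- mean(vi > th1)
  # th2: zero false negatives (no patient strictly below), maximal rejection
  min_i <- min(vi)
  below <- vc[vc < min_i]
  th2 <- if (length(below)) (max(below) + min_i) / 2 else min_i
  spec2 <- mean(vc < th2)
  structure(list(th1 = th1, th2 = th2, sens_at_th1 = sens1,
                 spec_at_th2 = spec2, direction = direction),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  flip <- if (x$direction == "higher_is_ige") 1 else -1
  cat(sprintf("Thresholds (%s): th1 = %.4g (train sens %.1f%% at 100%% spec), th2 = %.4g (train spec %.1f%% at 100%% sens)\n",
              x$direction, flip * x$th1, 100 * x$sens_at_th1, flip * x$th2,
              100 * x$spec_at_th2))
  invisible(x)
}

#' Three-way classification of one subject
#'
#' A subject is `"ige"` when the biomarker lies on the epilepsy side of both
#' thresholds, `"normal"` when on the control side of both, and
#' `"uncertain"` in between. With independently optimized parameter sets the
#' two thresholds refer to two biomarker evaluations; pass `value` of length
#' 2 (`value[1]` against `th1`, `value[2]` against `th2`), or a scalar to use
#' one value for both.
#'
#' @param value biomarker value(s), length 1 or 2, original units.
#' @param thresholds a [optimize_thresholds()] result.
#' @return `"ige"`, `"normal"` or `"uncertain"`.
#' @export
classify <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (any(!is.finite(value))) stop("classify: non-finite value")
  v <- orient(value, thresholds$direction)
  v1 <- v[1L]
  v2 <- v[length(v)]
  if (v1 > thresholds$th1 && v2 > thresholds$th2) "ige"
  else if (v1 < thresholds$th1 && v2 < thresholds$th2) "normal"
  else "uncertain"
}

# Per-(channel, K) training optimization for the table biomarker: returns the
# grid cell maximizing each objective plus its threshold pair. `tab` is the
# subjects x channels x K array restricted to the training rows.
optimize_grid <- function(tab, labels, direction) {
  chs <- dimnames(tab)[[2L]]
  nK <- dim(tab)[3L]
  best1 <- list(sens = -1)
  best2 <- list(spec = -1)
  for (ci in seq_along(chs)) {
    for (ki in seq_len(nK)) {
      tp <- optimize_thresholds(tab[, ci, ki], labels, direction)
      if (tp$sens_at_th1 > best1$sens)
        best1 <- list(sens = tp$sens_at_th1, ch = ci, k = ki, tp = tp)
      if (tp$spec_at_th2 > best2$spec)
        best2 <- list(spec = tp$spec_at_th2, ch = ci, k = ki, tp = tp)
    }
  }
  list(best1 = best1, best2 = best2)
}

#' Leave-one-out dual-threshold classification of a cohort
#'
#' Pools all subjects, leaves each out in turn, optimizes on the rest and
#' classifies the held-out subject. For a plain per-subject biomarker
#' (`values` a numeric vector) only the thresholds are optimized. For the
#' local-coupling biomarker (`values` a subjects x channels x K array from
#' [local_coupling_table()]) each fold additionally grid-searches `(channel,
#' K)` twice: once maximizing training sensitivity at 100% specificity (used
#' with `th1`) and once maximizing training specificity at 100% sensitivity
#' (used with `th2`); ties go to the first grid cell in (channel, K) order.
#'
#' @param values numeric vector or 3-d array of biomarker values.
#' @param labels per-subject `"ige"`/`"patient"` vs `"control"` labels.
#' @param direction which side of the scale is epilepsy-like.
#' @param subject_ids optional subject identifiers.
#' @return An object of class `cohort_classification`: a per-subject data
#'   frame of outcomes with fold metadata, plus the inputs.
#' @export
loocv_classify <- function(values, labels,
                           direction = c("higher_is_ige", "lower_is_ige"),
                           subject_ids = NULL) {
  direction <- match.arg(direction)
  tabular <- length(dim(values)) == 3L
  n <- if (tabular) dim(values)[1L] else length(values)
  if (length(labels) != n) stop("labels length must match values")
  ige <- is_ige_label(labels)
  if (sum(ige) < 2L || sum(!ige) < 2L)
    stop("loocv_classify: need at least 2 subjects per class")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (tabular) {
      opt <- optimize_grid(values[train, , , drop = FALSE], labels[train],
                           direction)
      tp <- structure(list(th1 = opt$best1$tp$th1, th2 = opt$best2$tp$th2,
                           sens_at_th1 = opt$best1$sens,
                           spec_at_th2 = opt$best2$spec,
                           direction = direction),
                      class = "threshold_pair")
      v1 <- values[i, opt$best1$ch, opt$best1$k]
      v2 <- values[i, opt$best2$ch, opt$best2$k]
      out <- classify(c(v1, v2), tp)
      rows[[i]] <- data.frame(
        subject = subject_ids[i], label = labels[i], outcome = out,
        value1 = v1, value2 = v2,
        th1 = orient(tp$th1, direction), th2 = orient(tp$th2, direction),
        channel1 = dimnames(values)[[2L]][opt$best1$ch],
        K1 = attr(values, "Kgrid")[opt$best1$k],
        channel2 = dimnames(values)[[2L]][opt$best2$ch],
        K2 = attr(values, "Kgrid")[opt$best2$k],
        stringsAsFactors = FALSE)
    } else {
      tp <- optimize_thresholds(values[train], labels[train], direction)
      out <- classify(values[i], tp)
      rows[[i]] <- data.frame(
        subject = subject_ids[i], label = labels[i], outcome = out,
        value1 = values[i], value2 = values[i],
        th1 = orient(tp$th1, direction), th2 = orient(tp$th2, direction),
        channel1 = NA_character_, K1 = NA_real_,
        channel2 = NA_character_, K2 = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(folds = do.call(rbind, rows), direction = direction,
                 tabular = tabular),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  f <- x$folds
  cat(sprintf("Leave-one-out classification of %d subjects (%s)\n",
              nrow(f), x$direction))
  print(table(truth = ifelse(is_ige_label(f$label), "ige", "control"),
              outcome = factor(f$outcome,
                               levels = c("ige", "uncertain", "normal"))))
  invisible(x)
}

#' @export
summary.cohort_classification <- function(object, ...) {
  p <- performance(object)
  print(object)
  cat(sprintf("sensitivity at 100%% training specificity: %.1f%%\n",
              100 * p$sensitivity))
  cat(sprintf("specificity at 100%% training sensitivity: %.1f%%\n",
              100 * p$specificity))
  invisible(p)
}

#' Classification performance of a three-outcome cohort
#'
#' Sensitivity is the fraction of true patients classified unequivocally
#' `"ige"`; specificity the fraction of controls classified unequivocally
#' `"normal"`; uncertain outcomes count against both. Accepts a
#' [loocv_classify()] result, or a 2 x 3 count matrix with rows `ige`,
#' `control` and columns `ige`, `uncertain`, `normal` (e.g. a published count
#' table).
#'
#' @param x a `cohort_classification` or a 2 x 3 numeric count matrix.
#' @return List with `sensitivity`, `specificity` (proportions) and the 2 x 3
#'   `counts` table.
#' @export
performance <- function(x) {
  if (inherits(x, "cohort_classification")) {
    f <- x$folds
    truth <- ifelse(is_ige_label(f$label), "ige", "control")
    counts <- table(factor(truth, levels = c("ige", "control")),
                    factor(f$outcome, levels = c("ige", "uncertain",
                                                 "normal")))
    counts <- unclass(as.matrix(counts))
  } else {
    counts <- as.matrix(x)
    if (!all(dim(counts) == c(2L, 3L)))
      stop("performance: need a 2 x 3 count matrix (ige/control x ige/uncertain/normal)")
    if (is.null(rownames(counts))) rownames(counts) <- c("ige", "control")
    if (is.null(colnames(counts)))
      colnames(counts) <- c("ige", "uncertain", "normal")
  }
  list(sensitivity = counts["ige", "ige"] / sum(counts["ige", ]),
       specificity = counts["control", "normal"] / sum(counts["control", ]),
       counts = counts)
}
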