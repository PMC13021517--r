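#' Descendant-aware correctness of a single prediction
#'
#' A prediction is correct if it equals the ground-truth label or is a
#' descendant (more specific subtype) of it in the ontology. Predicting a
#' coarser label — a parent or any other non-descendant — is incorrect.
#' This mirrors how mixed-granularity annotations are scored: a cell
#' annotated "T cell" is correctly called "CD4-positive, alpha-beta T
#' cell", but not the other way around.
#'
#' @param pred,truth 1-based class indices.
#' @param R reachability matrix: `R[truth, pred] == 1` iff `pred` is
#'   `truth` itself or one of its descendants.
#' @return logical.
#' @export
hierarchical_match <- function(pred, truth, R) {
  R[cbind(truth, pred)] == 1L
}

#' Per-class confusion counts under hierarchical matching
#'
#' Every prediction that is hierarchically correct (equal to the truth or a
#' descendant of it) is first remapped to the ground-truth class; standard
#' one-vs-rest true-positive / false-positive / false-negative counts are
#' then tallied. Remapping is what keeps the per-class bookkeeping
#' consistent with the per-cell correctness rule: a descendant prediction
#' counts as a true positive of the annotated class and not as a false
#' positive of the subtype.
#'
#' @param preds,truths equal-length integer vectors of 1-based class
#'   indices.
#' @param R reachability matrix, or `NULL` for flat (exact-match) scoring.
#' @param C number of classes; defaults to `ncol(R)` when available.
#' @return data.frame with columns `class`, `tp`, `fp`, `fn`, one row per
#'   class.
#' @export
confusion_summary <- function(preds, truths, R = NULL, C = NULL) {
  preds <- as.integer(preds); truths <- as.integer(truths)
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length")
  }
  if (is.null(C)) {
    if (is.null(R)) stop("supply C when R is NULL")
    C <- ncol(R)
  }
  if (length(preds) > 0L &&
      (max(preds, truths) > C || min(preds, truths) < 1L)) {
    stop("class index out of range [1, ", C, "]")
  }
  if (!is.null(R) && length(preds) > 0L) {
    ok <- hierarchical_match(preds, truths, R)
    preds[ok] <- truths[ok]
  }
  tp <- tabulate(truths[preds == truths], nbins = C)
  fp <- tabulate(preds[preds != truths], nbins = C)
  fn <- tabulate(truths[preds != truths], nbins = C)
  data.frame(class = seq_len(C), tp = tp, fp = fp, fn = fn)
}

.f1_per_class <- function(cs) {
  prec <- ifelse(cs$tp + cs$fp > 0, cs$tp / (cs$tp + cs$fp), 0)
  rec <- ifelse(cs$tp + cs$fn > 0, cs$tp / (cs$tp + cs$fn), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Macro F1 score
#'
#' Unweighted mean of per-class F1 scores over the included classes, so
#' every cell type contributes equally regardless of prevalence. The 0/0
#' degenerate case (no true positives, no false positives or negatives) is
#' defined as F1 = 0, preventing unpredicted absent-support classes from
#' inflating the average.
#'
#' @param cs confusion data.frame from [confusion_summary()].
#' @param include integer vector of class indices to average over
#'   (typically the classes present in the evaluation set's ground truth).
#' @return scalar in \[0, 1\].
#' @export
macro_f1 <- function(cs, include = cs$class) {
  include <- as.integer(include)
  if (length(include) == 0L) stop("include must name at least one class")
  f1 <- .f1_per_class(cs)
  mean(f1[match(include, cs$class)])
}

#' Full evaluation report
#'
#' @param preds,truths 1-based class indices.
#' @param R reachability matrix (`NULL` for flat matching).
#' @param include `"present"` (default) to average macro F1 over classes
#'   present in `truths`, `"all"` for every class, or an explicit integer
#'   vector.
#' @param C number of classes when `R` is `NULL`.
#' @return list with `confusion`, `per_class` (precision/recall/F1),
#'   `macro_f1` and `included_classes`.
#' @export
evaluate_predictions <- function(preds, truths, R = NULL,
                                 include = "present", C = NULL) {
  cs <- confusion_summary(preds, truths, R = R, C = C)
  inc <- if (identical(include, "present")) sort(unique(as.integer(truths)))
         else if (identical(include, "all")) cs$class
         else as.integer(include)
  prec <- ifelse(cs$tp + cs$fp > 0, cs$tp / (cs$tp + cs$fp), 0)
  rec <- ifelse(cs$tp + cs$fn > 0, cs$tp / (cs$tp + cs$fn), 0)
  per_class <- data.frame(class = cs$class, precision = prec, recall = rec,
                          f1 = .f1_per_class(cs))
  list(confusion = cs, per_class = per_class,
       macro_f1 = macro_f1(cs, include = inc), included_classes = inc)
}

#' Per-class paired comparison of two training arms
#'
#' Given per-run, per-class F1 matrices for models trained with CE and HCE
#' on matched seeds, performs a two-sided paired t-test per class on the
#' F1 differences and adjusts the p-values with the Holm-Bonferroni
#' step-down procedure. Classes whose difference vector has zero variance
#' (including all-zero differences) have an undefined t statistic; they are
#' flagged untestable and excluded from the adjustment family.
#'
#' @param f1_ce,f1_hce numeric matrices (runs x classes) with identical
#'   dimensions; paired rows correspond to matched seeds.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per class: `class`, `mean_delta`
#'   (HCE - CE), `t`, `p`, `p_adj`, `testable`, `significant`.
#' @export
compare_runs <- function(f1_ce, f1_hce, alpha = 0.05) {
  f1_ce <- as.matrix(f1_ce); f1_hce <- as.matrix(f1_hce)
  if (!all(dim(f1_ce) == dim(f1_hce))) {
    stop("run matrices must have identical dimensions")
  }
  if (nrow(f1_ce) < 2L) stop("paired comparison needs at least 2 runs")
  D <- f1_hce - f1_ce
  C <- ncol(D)
  mean_delta <- colMeans(D)
  sds <- apply(D, 2L, stats::sd)
  testable <- sds > 0
  tstat <- rep(NA_real_, C); p <- rep(NA_real_, C)
  for (j in which(testable)) {
    tt <- stats::t.test(f1_hce[, j], f1_ce[, j], paired = TRUE)
    tstat[j] <- unname(tt$statistic); p[j] <- tt$p.value
  }
  p_adj <- rep(NA_real_, C)
  p_adj[testable] <- holm_adjust(p[testable])
  cls <- if (!is.null(colnames(D))) colnames(D) else seq_len(C)
  data.frame(class = cls, mean_delta = mean_delta, t = tstat, p = p,
             p_adj = p_adj, testable = testable,
             significant = !is.na(p_adj) & p_adj <= alpha,
             row.names = NULL)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Orders the raw p-values, multiplies the k-th smallest by (m - k + 1),
#' enforces monotonicity with a running maximum, and caps at 1. Controls
#' the family-wise error rate without the full Bonferroni penalty.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}
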