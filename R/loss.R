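#' Inverse-frequency class weights
#'
#' Computes the balanced class weights `w_i = N / (C * n_i)` from training
#' labels, where `N` is the number of training samples, `C` the number of
#' classes and `n_i` the sample count of class `i`. Classes with no
#' training samples get weight 0 and are flagged: they cannot be learned
#' and must not contribute infinite weight.
#'
#' @param labels integer vector of 1-based class indices.
#' @param C number of classes (ontology size).
#' @return list with components `w` (length-C numeric), `n` (counts),
#'   `N` (total) and `absent` (indices of zero-count classes).
#' @examples
#' compute_class_weights(rep(1:4, c(40, 40, 10, 10)), C = 4)$w
#' @export
compute_class_weights <- function(labels, C) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("label vector is empty")
  if (any(labels < 1L | labels > C)) {
    stop("labels must be 1-based indices in [1, ", C, "]")
  }
  n <- tabulate(labels, nbins = C)
  N <- length(labels)
  w <- ifelse(n > 0L, N / (C * n), 0)
  list(w = w, n = n, N = N, absent = which(n == 0L))
}

#' Hierarchy-adjusted class scores
#'
#' Propagates predicted probability mass up the ontology: the adjusted
#' score of class `i` is its own probability plus the probabilities of all
#' its descendant subtypes, `s = R p`, computed as a single matrix-vector
#' product with the reachability matrix. The result satisfies
#' `p[i] <= s[i] <= 1` and is monotone along edges: a parent's score is
#' never below any child's.
#'
#' @param p probability vector of length C (non-negative, sums to 1), or a
#'   matrix with one probability vector per row.
#' @param R reachability matrix from [reachability()].
#' @return adjusted scores, same shape as `p`.
#' @export
adjust_scores <- function(p, R) {
  if (is.matrix(p)) {
    if (ncol(p) != ncol(R)) stop("dimension mismatch between p and R")
    return(p %*% t(R))
  }
  if (length(p) != ncol(R)) stop("dimension mismatch between p and R")
  as.numeric(R %*% p)
}

.check_prob <- function(p, tol = 1e-6) {
  if (any(p < -tol)) stop("probability vector has negative entries")
  if (abs(sum(p) - 1) > tol) stop("probability vector does not sum to 1")
  invisible(TRUE)
}

#' Weighted cross-entropy loss for one sample
#'
#' Standard flat cross-entropy treating every cell type as an independent
#' class: `-w_t * log(p_t + eps)`. The stabilising `eps` matches the one
#' used inside [hce_loss()] so the two losses coincide exactly on an
#' edge-free ontology.
#'
#' @param p probability vector over the C classes.
#' @param true_label 1-based index of the true class.
#' @param w class-weight vector (default: unweighted). A weight of 0 marks
#'   a class absent from training; such samples contribute 0 with a warning.
#' @param epsilon numerical stabiliser added inside the log (default 1e-6).
#' @return non-negative scalar loss.
#' @export
ce_loss <- function(p, true_label, w = NULL, epsilon = 1e-6) {
  .check_prob(p)
  wt <- if (is.null(w)) 1 else w[true_label]
  if (wt == 0) {
    warning("true class ", true_label,
            " was absent from training (weight 0); loss contributes 0")
    return(0)
  }
  -wt * log(p[true_label] + epsilon)
}

#' Hierarchical cross-entropy loss for one sample
#'
#' Replaces the raw probability of the true class with its
#' hierarchy-adjusted score `s_t = p_t + sum of descendant probabilities`
#' before taking the weighted negative log: `-w_t * log(s_t + eps)`.
#' Predicting any subtype of the annotated label therefore incurs no
#' penalty, aligning the training objective with descendant-aware
#' evaluation. Because `s_t >= p_t` always, the HCE loss never exceeds the
#' CE loss for the same input, and the two are identical when the ontology
#' has no edges (`R` is the identity).
#'
#' @inheritParams ce_loss
#' @param R reachability matrix aligned to the class order.
#' @return non-negative scalar loss.
#' @examples
#' dag <- ontology_dag(c("A", "B", "C"),
#'                     data.frame(child = c("C", "B"), parent = c("B", "A")))
#' R <- reachability(dag)
#' hce_loss(c(0.1, 0.3, 0.6), true_label = 2, R = R)  # -log(0.9 + 1e-6)
#' @export
hce_loss <- function(p, true_label, R, w = NULL, epsilon = 1e-6) {
  .check_prob(p)
  wt <- if (is.null(w)) 1 else w[true_label]
  if (wt == 0) {
    warning("true class ", true_label,
            " was absent from training (weight 0); loss contributes 0")
    return(0)
  }
  s <- adjust_scores(p, R)
  -wt * log(s[true_label] + epsilon)
}

#' Row-wise softmax
#'
#' Numerically stable softmax mapping raw classifier outputs (logits) to
#' probability vectors.
#'
#' @param Z numeric matrix (samples x classes) or vector.
#' @return matrix (or vector) of probabilities, rows summing to 1.
#' @export
softmax <- function(Z) {
  if (!is.matrix(Z)) {
    z <- Z - max(Z)
    e <- exp(z)
    return(e / sum(e))
  }
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Batched loss on logits
#'
#' Mean weighted loss over a mini-batch, computed from raw logits. The
#' reduction is the weighted mean: the sum of per-sample weighted losses
#' divided by the sum of the participating class weights, the usual
#' convention for weighted negative log-likelihoods.
#'
#' @param Z logits matrix (n x C).
#' @param labels integer vector of 1-based true-class indices, length n.
#' @param w class-weight vector (length C); `NULL` for unweighted.
#' @param R reachability matrix; `NULL` (or identity) gives flat CE.
#' @param epsilon stabiliser inside the log.
#' @return scalar loss.
#' @export
batch_loss <- function(Z, labels, w = NULL, R = NULL, epsilon = 1e-6) {
  P <- softmax(Z)
  S <- if (is.null(R)) P else P %*% t(R)
  st <- S[cbind(seq_len(nrow(S)), labels)]
  wt <- if (is.null(w)) rep(1, length(labels)) else w[labels]
  if (sum(wt) == 0) return(0)
  sum(-wt * log(st + epsilon)) / sum(wt)
}

#' Gradient of the batched loss with respect to logits
#'
#' Analytic gradient of [batch_loss()] through the softmax, used by the
#' training loop and verifiable against finite differences. For one sample
#' with true label t, `dL/dp = -w_t * R[t, ] / (s_t + eps)` and the softmax
#' Jacobian gives `dL/dz_k = p_k * (g_k - <g, p>)`.
#'
#' @inheritParams batch_loss
#' @return matrix of the same shape as `Z`.
#' @export
batch_loss_grad <- function(Z, labels, w = NULL, R = NULL, epsilon = 1e-6) {
  P <- softmax(Z)
  n <- nrow(P); C <- ncol(P)
  S <- if (is.null(R)) P else P %*% t(R)
  st <- S[cbind(seq_len(n), labels)]
  wt <- if (is.null(w)) rep(1, length(labels)) else w[labels]
  wsum <- sum(wt)
  if (wsum == 0) return(matrix(0, n, C))
  # G[i, ] = dL_i / dp: -w_t * R[t, ] / (s_t + eps)
  Rrows <- if (is.null(R)) diag(C)[labels, , drop = FALSE]
           else R[labels, , drop = FALSE]
  G <- -(wt / (st + epsilon)) * Rrows
  dZ <- P * (G - rowSums(G * P)) / wsum
  dimnames(dZ) <- dimnames(Z)
  dZ
}
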