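# Training objectives and threshold-free evaluation metrics.

#' Contrastive distillation loss (InfoNCE over matched rows)
#'
#' Each teacher row is anchored against all student rows:
#' `-1/N sum_i log( exp(T_i . S_i / tau) / sum_j exp(T_i . S_j / tau) )`,
#' log-sum-exp stabilized. Equals `log(N)` when all dot products are tied
#' and 0 when `N = 1`.
#'
#' @param x_tea,x_stu `N x d` teacher and student representation matrices
#'   with matched rows.
#' @param tau temperature (> 0).
#' @return scalar loss (>= 0).
#' @export
hkd_loss <- function(x_tea, x_stu, tau = 0.5) {
  x_tea <- as.matrix(x_tea); x_stu <- as.matrix(x_stu)
  if (nrow(x_tea) == 0) stopf("distillation loss undefined for zero rows")
  if (nrow(x_tea) != nrow(x_stu)) stopf("teacher/student row counts differ")
  if (tau <= 0) stopf("temperature must be positive")
  s <- tcrossprod(x_tea, x_stu) / tau
  mx <- apply(s, 1, max)
  mean(mx + log(rowSums(exp(s - mx))) - diag(s))
}

#' Mean binary cross-entropy
#'
#' `-1/N sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]`, with probabilities
#' clipped to `[eps, 1 - eps]`.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param eps clipping constant (default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels)) stopf("probs/labels length mismatch")
  if (length(probs) == 0) stopf("empty loss batch")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Combined training objective
#'
#' `L = L_BCE + lambda * L_HKD` with distillation weight `lambda` (default 1).
#'
#' @param l_bce,l_hkd component losses.
#' @param lambda distillation weight (>= 0).
#' @return scalar total loss.
#' @export
total_loss <- function(l_bce, l_hkd, lambda = 1) {
  if (lambda < 0) stopf("lambda must be nonnegative")
  l_bce + lambda * l_hkd
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with tie correction (midranks).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUROC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration (average precision): scores are swept from
#' high to low, tied scores are grouped, and precision is accumulated over
#' recall increments.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUPRC undefined with a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}
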