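# Loss functions: binary cross-entropy with logits (RPN objjectness and the
# keypoint heatmap), softmax cross-entropy (box-head classification), and
# smooth L1 (box regression).

# numerically stable BCE-with-logits; returns loss (mean) and dlogits
bce_with_logits <- function(z, t) {
  loss <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  dz <- (1 / (1 + exp(-z)) - t) / length(z)
  list(loss = loss, dz = dz)
}

# labels: integer vector in 0..C (0 = background); logits: (C+1) x n
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dz <- p
  dz[idx] <- dz[idx] - 1
  list(loss = loss, dz = dz / n)
}

smooth_l1 <- function(x, beta = 1) {
  a <- abs(x)
  ifelse(a < beta, 0.5 * x^2 / beta, a - 0.5 * beta)
}

smooth_l1_grad <- function(x, beta = 1) {
  pmin(pmax(x / beta, -1), 1)
}

#' Keypoint heatmap loss
#'
#' Mean per-cell binary cross-entropy between the sigmoid of the predicted
#' heatmap logits and the Gaussian target heatmap. Zero only in the
#' saturated-perfect limit.
#'
#' @param pred Predicted logits: a matrix, or an `mt_heatmap` whose `grid`
#'   holds logits.
#' @param target Target heatmap: a matrix of values in `[0, 1]`, or an
#'   `mt_heatmap` (e.g. from [render_target_heatmap()]).
#' @return Non-negative scalar loss.
#' @export
keypoint_loss <- function(pred, target) {
  zp <- if (inherits(pred, "mt_heatmap")) pred$grid else pred
  tg <- if (inherits(target, "mt_heatmap")) target$grid else target
  if (!all(dim(zp) == dim(tg))) stop("prediction and target heatmap shapes differ")
  bce_with_logits(zp, tg)$loss
}
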