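softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Prediction loss
#'
#' Classification: mean cross-entropy of softmaxed logits against 0-based
#' class indices. Regression: root-mean-square error over the batch, in
#' degrees Celsius.
#'
#' @param outputs Classification: n x C logit matrix (or length-C vector for
#'   n = 1). Regression: length-n numeric predictions.
#' @param targets Length-n class indices (0-based) or temperatures.
#' @param task `"classification"` or `"regression"`.
#' @return Scalar loss.
#' @export
prediction_loss <- function(outputs, targets, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") {
    if (!is.matrix(outputs)) outputs <- matrix(outputs, nrow = 1)
    n <- nrow(outputs); C <- ncol(outputs)
    stopifnot(length(targets) == n)
    targets <- as.integer(targets)
    if (any(targets < 0L | targets >= C))
      stop(sprintf("class index outside 0..%d", C - 1L))
    ce <- vapply(seq_len(n), function(i) {
      p <- softmax_vec(outputs[i, ])
      -log(p[targets[i] + 1L])
    }, numeric(1))
    mean(ce)
  } else {
    stopifnot(length(outputs) == length(targets), length(targets) >= 1L)
    sqrt(mean((as.numeric(outputs) - as.numeric(targets))^2))
  }
}

#' Overall training loss
#'
#' L = prediction loss + alpha * contrastive loss. With alpha = 0 the
#' contrastive term is ablated and training reduces to the plain
#' sequence-structure model.
#'
#' @param pred_loss Scalar prediction loss.
#' @param cont_loss Scalar contrastive loss.
#' @param alpha Nonnegative weight of the contrastive term.
#' @return Scalar total loss.
#' @export
total_loss <- function(pred_loss, cont_loss, alpha) {
  stopifnot(is.finite(pred_loss), is.finite(cont_loss), alpha >= 0)
  pred_loss + alpha * cont_loss
}
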