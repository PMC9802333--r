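# Comparison models: the purely learned graph-network baseline (edge MLP +
# node MLP), GN+ / GN+_uni (learnable per-node or shared scalars, dividing
# aggregated messages by 10^w), and the symmetry-regularized baseline.

#' Baseline forward pass: learned edge and node networks
#'
#' The node network maps `concat(node features, summed incoming messages)`
#' to a length-`d` acceleration; all parameters are trained jointly. Unlike
#' the physics operator, nothing ties the output to the mass feature.
#'
#' @param model A `pignpi` model with variant `"gn_baseline"` or
#'   `"gn_symreg"`.
#' @param sample A [graph_sample()].
#' @return `n x d` predicted acceleration matrix.
#' @export
baseline_forward <- function(model, sample) {
  stopifnot(model$variant %in% c("gn_baseline", "gn_symreg"))
  act <- .act_code(model$activation)
  M <- cpp_mlp_forward(model$edge$W, model$edge$b, sample$X, act)
  n <- nrow(sample$eta)
  S <- matrix(0, n, ncol(M))
  agg <- rowsum(M, group = sample$edges[, 1])
  S[as.integer(rownames(agg)), ] <- agg
  cpp_mlp_forward(model$node$W, model$node$b, cbind(sample$eta, S), act)
}

#' GN+ forward pass: aggregated messages divided by 10^w
#'
#' @param model A `pignpi` model with variant `"gn_plus"` (per-node scalar
#'   `w_i`) or `"gn_plus_uni"` (one shared scalar).
#' @param sample A [graph_sample()].
#' @return `n x d` predicted acceleration matrix.
#' @export
gnplus_forward <- function(model, sample) {
  stopifnot(model$variant %in% c("gn_plus", "gn_plus_uni"))
  M <- edge_messages(model, sample)
  n <- nrow(sample$eta)
  w <- if (model$variant == "gn_plus_uni") rep(model$w, n) else model$w
  if (length(w) != n)
    stop("gn_plus carries per-node scalars for ", length(w),
         " particles but the sample has ", n,
         "; see generalization_eval() for the mean-scalar fallback")
  S <- matrix(0, n, ncol(M))
  agg <- rowsum(M, group = sample$edges[, 1])
  S[as.integer(rownames(agg)), ] <- agg
  S / 10^w
}

#' Symmetry-regularization penalty on edge messages
#'
#' Mean over directed edges of the elementwise absolute sum of opposing
#' messages, `mean_e l1(M_e, -M_rev(e))`; exactly zero for antisymmetric
#' messages. Multiplied by the weight `alpha` it is the regularization term
#' of the symmetry-regularized baseline objective.
#'
#' @param messages `E x k` message matrix.
#' @param rev Reverse-edge index (row of the opposing edge, 1-based).
#' @return Scalar penalty (before weighting).
#' @export
symreg_penalty <- function(messages, rev) {
  messages <- as.matrix(messages)
  mean(rowSums(abs(messages + messages[rev, , drop = FALSE])))
}

#' Symmetry-regularized training objective on one sample
#'
#' Acceleration l1 term plus `alpha` times [symreg_penalty()]; with
#' `alpha = 0` this is exactly the baseline acceleration loss.
#'
#' @param model A `pignpi` model with variant `"gn_symreg"` or
#'   `"gn_baseline"`.
#' @param sample A [graph_sample()].
#' @param alpha Regularization weight (>= 0).
#' @return Scalar loss.
#' @export
symreg_loss <- function(model, sample, alpha = 0) {
  stopifnot(alpha >= 0)
  pred <- baseline_forward(model, sample)
  acc_term <- sum(abs(pred - sample$target)) / nrow(pred)
  M <- cpp_mlp_forward(model$edge$W, model$edge$b, sample$X,
                       .act_code(model$activation))
  acc_term + alpha * symreg_penalty(M, sample$rev)
}
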