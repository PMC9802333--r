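# Model fitting: the acceleration-only objective, mini-batched Adam
# optimization with validation-based model selection, prediction and the
# physics-consistency evaluation report.

#' Fit an interaction model to a particle trajectory
#'
#' Trains the edge network (and, for baselines, the node network and any
#' learnable scalars) by minimizing the mean absolute error of predicted
#' accelerations over mini-batches of whole time steps with Adam. Time
#' steps are split at random into training / validation / test sets
#' (default ratio 7 : 1.5 : 1.5); after every epoch the validation
#' acceleration error is recorded and the returned model is the one with
#' the lowest validation error (ties broken by earliest epoch).
#'
#' @param trajectory A [simulate_system()] / [read_extxyz()] trajectory.
#'   By default its kinematics are replaced by central finite differences
#'   of the positions (the observational premise: only positions are
#'   measured), dropping the two endpoint steps.
#' @param mode `"force"`: edge messages are pairwise forces, node operator
#'   is sum/mass. `"potential"`: scalar messages are pairwise potentials,
#'   node operator is the negative receiver-position derivative over mass.
#' @param variant `"pignpi"` (the physics operator) or a baseline:
#'   `"gn_baseline"` (learned node MLP), `"gn_symreg"` (baseline plus
#'   symmetry regularization with weight `alpha`), `"gn_plus"` /
#'   `"gn_plus_uni"` (messages divided by 10^w with per-node / shared
#'   learnable scalar; force mode only).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Time steps per mini-batch; defaults to 32 in force
#'   mode and 8 in potential mode.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param hidden_layers,hidden_units Edge-network size (default 4 x 300).
#' @param activation Activation name (default `"silu"`; ReLU is rejected
#'   in potential mode).
#' @param alpha Symmetry-regularization weight (`gn_symreg`; 0 reduces it
#'   to `gn_baseline` exactly).
#' @param split Length-3 split ratios over usable time steps.
#' @param kinematics `"fd"` (default) differentiates positions; `"recorded"`
#'   uses the integrator-recorded accelerations as-is.
#' @param seed Root seed; weight initialisation, the split and batch
#'   shuffling are all derived from it.
#' @param verbose Print per-epoch progress.
#' @return Object of class `pignpi` with the trained parameters, the step
#'   `split`, a per-epoch `history` data frame, `best_epoch` and the
#'   originating `system_spec`.
#' @seealso [evaluate()], [predict.pignpi()], [extract_interactions()]
#' @export
#' @examples
#' traj <- simulate_system(system_spec("spring"), n = 4, n_steps = 60,
#'                         dt = 0.01, seed = 1)
#' fit <- pignpi(traj, mode = "force", epochs = 2, hidden_layers = 1,
#'               hidden_units = 8, seed = 1)
#' fit
pignpi <- function(trajectory, mode = c("force", "potential"),
                   variant = c("pignpi", "gn_baseline", "gn_plus",
                               "gn_plus_uni", "gn_symreg"),
                   epochs = 200, batch_size = NULL, learning_rate = 0.001,
                   hidden_layers = 4, hidden_units = 300,
                   activation = "silu", alpha = 0,
                   split = c(7, 1.5, 1.5),
                   kinematics = c("fd", "recorded"),
                   seed = 1, verbose = FALSE) {
  stopifnot(inherits(trajectory, "trajectory"))
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  kinematics <- match.arg(kinematics)
  if (variant %in% c("gn_plus", "gn_plus_uni") && mode != "force")
    stop("GN+ is defined for pairwise-force learning only")
  if (seed >= 2^31 - 10) stop("seed too large")
  if (kinematics == "fd" && trajectory$provenance == "integrator")
    trajectory <- with_fd_kinematics(trajectory)
  batch_size <- batch_size %||% if (mode == "force") 32L else 8L

  ds <- .graph_dataset(trajectory)
  ns <- length(ds$row_ranges)
  sp <- split_timesteps(ns, ratios = split, seed = seed + 1L)

  model <- pignpi_model(mode, ds$layout, variant,
                        hidden_layers = hidden_layers,
                        hidden_units = hidden_units,
                        activation = activation, n_particles = ds$n,
                        seed = seed)
  model$spec <- trajectory$spec
  model$kinematics <- kinematics
  model$alpha <- alpha

  parts <- Filter(Negate(is.null),
                  list(edge = model$edge, node = model$node, w = model$w))
  theta <- .flatten_params(parts)
  adam <- .adam_init(length(theta))
  best <- list(theta = theta, mae = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_mae = numeric())

  set.seed(seed + 2L)
  n_batches <- max(1L, ceiling(length(sp$train) / batch_size))
  for (ep in seq_len(epochs)) {
    perm <- sample(sp$train)
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      sel <- perm[(((bi - 1L) * batch_size + 1L)):min(bi * batch_size, length(perm))]
      sel <- sel[!is.na(sel)]
      if (!length(sel)) next
      b <- .batch_of(ds, sel)
      parts <- .unflatten_params(theta, parts)
      res <- .variant_batch(parts, model, b, ds, alpha, want_grad = TRUE)
      ep_loss <- ep_loss + res$loss * length(sel)
      grad <- res$grad
      if (!all(is.finite(grad)) || !is.finite(res$loss))
        stop("training diverged (non-finite loss/gradient) at epoch ", ep)
      upd <- .adam_step(theta, grad, adam, learning_rate)
      theta <- upd$theta
      adam <- upd$state
    }
    parts <- .unflatten_params(theta, parts)
    vmae <- .eval_mae(parts, model, ds, sp$valid)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / length(sp$train),
                                         valid_mae = vmae))
    if (vmae < best$mae) best <- list(theta = theta, mae = vmae, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.5g  valid MAE_acc %.5g%s",
                      ep, ep_loss / length(sp$train), vmae,
                      if (best$epoch == ep) " *" else ""))
  }

  parts <- .unflatten_params(best$theta, parts)
  model$edge <- parts$edge
  model$node <- parts$node %||% NULL
  model$w <- parts$w %||% NULL
  model$history <- history
  model$best_epoch <- best$epoch
  model$split <- lapply(sp, function(i) ds$steps[i])
  model$config <- utils::modifyList(model$config, list(
    epochs = epochs, batch_size = batch_size, learning_rate = learning_rate,
    alpha = alpha, split = split, kinematics = kinematics, seed = seed))
  model$call <- match.call()
  model
}

# dispatch one mini-batch to the variant's fused loss/grad kernel and
# flatten the gradient in the same order as the parameter vector
.variant_batch <- function(parts, model, b, ds, alpha, want_grad) {
  act <- .act_code(model$activation)
  B <- nrow(b$target) / ds$n
  masses <- rep(ds$masses, B)
  if (model$variant == "pignpi") {
    scale <- 1 / masses
    if (model$mode == "force") {
      res <- cpp_force_batch(parts$edge$W, parts$edge$b, b$X, b$recv0, scale,
                             b$target, act, 0, integer(0), want_grad)
    } else {
      lay <- model$layout
      res <- cpp_potential_batch(parts$edge$W, parts$edge$b, b$X, b$recv0,
                                 scale, b$target, act, lay$pos_cols - 1L,
                                 if (is.null(lay$disp_cols)) integer(0)
                                 else lay$disp_cols - 1L, want_grad)
    }
    grad <- if (want_grad) c(unlist(res$gW), unlist(res$gb)) else NULL
  } else if (model$variant %in% c("gn_plus", "gn_plus_uni")) {
    w_node <- if (model$variant == "gn_plus_uni") rep(parts$w, length(masses))
              else rep(parts$w, B)
    scale <- 10^(-w_node)
    res <- cpp_force_batch(parts$edge$W, parts$edge$b, b$X, b$recv0, scale,
                           b$target, act, 0, integer(0), want_grad)
    grad <- NULL
    if (want_grad) {
      gw_node <- res$gscale * scale * (-log(10))
      gw <- if (model$variant == "gn_plus_uni") sum(gw_node)
            else rowsum(gw_node, rep(seq_len(ds$n), B))[, 1]
      grad <- c(unlist(res$gW), unlist(res$gb), gw)
    }
  } else {  # gn_baseline / gn_symreg
    res <- cpp_baseline_batch(parts$edge$W, parts$edge$b,
                              parts$node$W, parts$node$b,
                              b$X, b$recv0, b$eta_nodes, b$target, act,
                              if (model$variant == "gn_symreg") alpha else 0,
                              b$rev0, want_grad)
    grad <- if (want_grad)
      c(unlist(res$geW), unlist(res$geb), unlist(res$gnW), unlist(res$gnb))
    else NULL
  }
  list(loss = res$loss, grad = grad, accel = res$accel,
       M = res$M, G = res$G)
}

# validation / test acceleration MAE (no regularization term), chunked
.eval_mae <- function(parts, model, ds, step_idx, chunk = 200L) {
  if (!length(step_idx)) return(NA_real_)
  total <- 0
  rows <- 0
  for (start in seq(1L, length(step_idx), by = chunk)) {
    sel <- step_idx[start:min(start + chunk - 1L, length(step_idx))]
    b <- .batch_of(ds, sel)
    res <- .variant_batch(parts, model, b, ds, alpha = 0, want_grad = FALSE)
    total <- total + sum(abs(res$accel - b$target))
    rows <- rows + nrow(b$target)
  }
  total / rows
}

# stacked predictions over a dataset: accelerations, messages and (potential
# mode) message position-gradients, chunked to bound memory
.predict_ds <- function(model, ds, step_idx, chunk = 200L) {
  act <- .act_code(model$activation)
  parts <- Filter(Negate(is.null),
                  list(edge = model$edge, node = model$node, w = model$w))
  accel <- NULL; M <- NULL; G <- NULL
  for (start in seq(1L, length(step_idx), by = chunk)) {
    sel <- step_idx[start:min(start + chunk - 1L, length(step_idx))]
    b <- .batch_of(ds, sel)
    res <- .variant_batch(parts, model, b, ds, alpha = 0, want_grad = FALSE)
    accel <- rbind(accel, res$accel)
    if (model$variant == "pignpi" && model$mode == "potential") {
      M <- rbind(M, res$M)
      G <- rbind(G, res$G)
    } else {
      Mi <- cpp_mlp_forward(model$edge$W, model$edge$b, b$X, act)
      M <- rbind(M, Mi)
    }
  }
  list(accel = accel, M = M, G = G)
}

#' Predict from a fitted interaction model
#'
#' @param object A fitted `pignpi` model.
#' @param trajectory Trajectory to predict on (finite-difference kinematics
#'   are applied first if the model was trained that way).
#' @param steps Optional subset of usable time steps.
#' @param type `"acceleration"` (per particle), `"message"` (raw edge
#'   output), `"force"` (pairwise forces; potential mode derives them as
#'   the negative receiver-position derivative) or `"potential"` (scalar
#'   pairwise potentials, potential mode only).
#' @param ... Unused.
#' @return An array: `(steps, n, d)` for accelerations; `(steps, E, k)` for
#'   per-edge quantities of a fixed edge set, otherwise a list of per-step
#'   matrices.
#' @export
predict.pignpi <- function(object, trajectory, steps = NULL,
                           type = c("acceleration", "message", "force",
                                    "potential"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(trajectory, "trajectory"))
  if ((object$kinematics %||% "fd") == "fd" &&
      trajectory$provenance == "integrator")
    trajectory <- with_fd_kinematics(trajectory)
  ds <- .graph_dataset(trajectory)
  if (!.layout_equal(ds$layout, object$layout))
    stop("trajectory feature layout does not match the fitted model")
  step_idx <- steps %||% seq_along(ds$row_ranges)
  pr <- .predict_ds(object, ds, step_idx)
  ns <- length(step_idx)
  if (type == "acceleration")
    return(.stack_to_array(pr$accel, ns, ds$n))
  ecounts <- lengths(ds$row_ranges[step_idx])
  per_edge <- switch(type,
    message = pr$M,
    force = {
      if (object$mode == "force") pr$M
      else if (!is.null(pr$G)) -pr$G
      else stop("this model has no pairwise-force interpretation")
    },
    potential = {
      if (object$mode != "potential") stop("potential only in potential mode")
      pr$M
    })
  .split_edge_rows(per_edge, ecounts)
}

# reshape step-major stacked rows (blocks of n rows per step) to (steps, n, d)
.stack_to_array <- function(mat, ns, n) {
  mat <- as.matrix(mat)
  arr <- array(NA_real_, c(ns, n, ncol(mat)))
  for (k in seq_len(ncol(mat))) arr[, , k] <- t(matrix(mat[, k], n, ns))
  arr
}

.split_edge_rows <- function(mat, ecounts) {
  mat <- as.matrix(mat)
  if (length(unique(ecounts)) == 1L) {
    E <- ecounts[1]
    arr <- array(NA_real_, c(length(ecounts), E, ncol(mat)))
    for (k in seq_len(ncol(mat)))
      arr[, , k] <- t(matrix(mat[, k], E, length(ecounts)))
    if (ncol(mat) == 1L) arr[, , 1] else arr
  } else {
    offs <- cumsum(c(0L, ecounts[-length(ecounts)]))
    Map(function(o, e) mat[(o + 1):(o + e), , drop = FALSE], offs, ecounts)
  }
}

#' @export
print.pignpi <- function(x, ...) {
  cat(sprintf("<pignpi> %s-mode %s", x$mode, x$variant))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf(": trained %d epochs, best epoch %d (valid MAE_acc %.4g)",
                nrow(x$history), x$best_epoch,
                x$history$valid_mae[x$best_epoch]))
  } else cat(" (untrained)")
  cat("\n")
  if (!is.null(x$edge))
    cat(sprintf("  edge net: %d -> %s -> %d (%s), %d parameters\n",
                nrow(x$edge$W[[1]]),
                paste(rep(x$config$hidden_units, x$config$hidden_layers),
                      collapse = "-"),
                ncol(x$edge$W[[length(x$edge$W)]]), x$activation,
                length(.flatten_params(list(e = x$edge)))))
  invisible(x)
}

#' @export
summary.pignpi <- function(object, ...) {
  print(object)
  if (!is.null(object$split))
    cat(sprintf("  split: %d / %d / %d usable steps (train/valid/test)\n",
                length(object$split$train), length(object$split$valid),
                length(object$split$test)))
  if (!is.null(object$history) && nrow(object$history)) {
    cat("  last epochs:\n")
    print(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.pignpi <- function(object, ...) {
  Filter(Negate(is.null),
         list(edge = object$edge, node = object$node, w = object$w))
}

#' @export
plot.pignpi <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) stop("untrained model")
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", log = "y", xlab = "epoch",
       ylab = "acceleration MAE", col = "grey40", ...)
  lines(h$epoch, h$valid_mae, col = "firebrick")
  abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.pignpi <- function(object, trajectory, steps = NULL, ...) {
  if (missing(trajectory))
    stop("supply the trajectory to compute residuals on")
  pred <- predict(object, trajectory, steps = steps, type = "acceleration")
  if ((object$kinematics %||% "fd") == "fd" &&
      trajectory$provenance == "integrator")
    trajectory <- with_fd_kinematics(trajectory)
  idx <- steps %||% seq_len(dim(trajectory$accelerations)[1])
  pred - trajectory$accelerations[idx, , , drop = FALSE]
}
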