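# Physics-consistency evaluation of fitted (or oracle) models against the
# ground-truth pair law, plus the generalization and noise-robustness
# protocols.

# vectorised true pairwise force / potential from the stacked edge inputs;
# mass is the last feature of each node half, charge the one before (when
# present), so the truths come straight from the feature matrix
.true_edge_batch <- function(spec, X, layout) {
  d <- layout$d
  nd <- layout$node_dim
  disp <- if (layout$has_disp) X[, layout$disp_cols, drop = FALSE]
          else X[, nd + 1:d, drop = FALSE] - X[, 1:d, drop = FALSE]
  r <- sqrt(rowSums(disp^2))
  cs <- spec$constants
  qi <- if (layout$has_charge) X[, 2 * d + 1] else 0
  qj <- if (layout$has_charge) X[, nd + 2 * d + 1] else 0
  mi <- X[, nd]
  mj <- X[, 2 * nd]
  law <- spec$law
  if (law == "spring") {
    coef <- cs$k * (r - cs$L) / r
    P <- 0.5 * cs$k * (r - cs$L)^2
  } else if (law == "charge") {
    coef <- -cs$c * qi * qj / ((r + cs$delta)^2 * r)
    P <- cs$c * qi * qj / (r + cs$delta)
  } else if (law == "orbital") {
    coef <- mi * mj / ((r + cs$delta) * r)
    P <- mi * mj * log(r + cs$delta)
  } else if (law == "discnt") {
    coef <- ifelse(r < cs$theta, 0, (r - 1) / r)
    P <- ifelse(r < cs$theta, 0, 0.5 * (r - 1)^2)
  } else {  # lj
    sr6 <- (cs$sigma / r)^6
    out <- r > cs$r_cut
    coef <- ifelse(out, 0, -24 * cs$epsilon * (2 * sr6^2 - sr6) / r^2)
    P <- ifelse(out, 0, 4 * cs$epsilon * (sr6^2 - sr6))
  }
  list(force = disp * coef, potential = P, r = r)
}

#' Evaluate a model's physics consistency on a trajectory
#'
#' Computes the full metric report on a set of time steps (all usable steps
#' unless `steps` is given; pass `fit$split$test` to score a model's own
#' held-out steps): acceleration error, pairwise-force error, potential
#' increment error (relative to the trajectory's initial configuration),
#' action-reaction symmetry errors, and force magnitude / angle errors.
#'
#' @param object A fitted `pignpi` model (or [closed_form_model()]).
#' @param ... Passed to methods.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @param trajectory Trajectory with a `system_spec` providing the ground
#'   truth.
#' @param steps Usable-step indices to evaluate (default: all).
#' @param label Split label recorded in the report.
#' @return Object of class `pignpi_metrics`: a list of named metric values
#'   plus counts (`n_particles`, `n_edges`, `n_steps`) and notes.
#' @export
evaluate.pignpi <- function(object, trajectory, steps = NULL,
                            label = "test", ...) {
  stopifnot(inherits(trajectory, "trajectory"))
  if ((object$kinematics %||% "fd") == "fd" &&
      trajectory$provenance == "integrator")
    trajectory <- with_fd_kinematics(trajectory)
  ds <- .graph_dataset(trajectory)
  if (!.layout_equal(ds$layout, object$layout))
    stop("trajectory feature layout does not match the model")
  step_idx <- steps %||% seq_along(ds$row_ranges)
  notes <- character()

  if (inherits(object, "pignpi_closed")) {
    pr <- .closed_predict(object, ds, step_idx)
  } else {
    pr <- .predict_ds(object, ds, step_idx)
  }
  rows <- unlist(ds$row_ranges[step_idx], use.names = FALSE)
  truth <- .true_edge_batch(trajectory$spec, ds$X[rows, , drop = FALSE],
                            ds$layout)
  node_rows <- as.vector(outer(seq_len(ds$n), (step_idx - 1L) * ds$n, `+`))
  target <- ds$target[node_rows, , drop = FALSE]
  b_rev <- .batch_of(ds, step_idx)$rev0 + 1L

  mae_acc <- mae_part(pr$accel, target)

  # predicted pairwise forces (when the model admits them)
  Fhat <- if (object$mode == "force") pr$M
          else if (!is.null(pr$G)) -pr$G else NULL
  mae_ef <- if (!is.null(Fhat)) mae_inter(Fhat, truth$force) else NA_real_
  symm_f <- if (!is.null(Fhat)) mae_symm(Fhat, b_rev, "force") else NA_real_
  fe <- if (!is.null(Fhat)) field_errors(Fhat, truth$force) else NULL

  # potential quantities exist whenever messages are scalars
  mae_dep <- symm_p <- NA_real_
  if (object$mode == "potential") {
    Phat <- drop(pr$M)
    symm_p <- mae_symm(cbind(Phat), b_rev, "potential")
    ref <- .reference_potentials(object, trajectory, ds)
    key <- .edge_keys(ds, rows)
    hit <- match(key, ref$key)
    ok <- !is.na(hit)
    if (any(!ok)) notes <- c(notes, sprintf(
      "%d edges absent from the reference configuration dropped from the potential increment", sum(!ok)))
    mae_dep <- mae_inter(Phat[ok] - ref$phat[hit[ok]],
                         truth$potential[ok] - ref$ptrue[hit[ok]])
  }

  structure(list(
    mae_acc = mae_acc, mae_ef = mae_ef, mae_dep = mae_dep,
    mae_symm_f = symm_f, mae_symm_p = symm_p,
    mean_magnitude_error = if (!is.null(fe)) fe$mean_magnitude else NA_real_,
    mean_angle_error = if (!is.null(fe)) fe$mean_angle else NA_real_,
    mean_cosine = if (!is.null(fe)) fe$mean_cosine else NA_real_,
    label = label, n_particles = ds$n,
    n_edges = length(rows) / length(step_idx),
    n_steps = length(step_idx), notes = notes),
    class = "pignpi_metrics")
}

# per-edge predictions of a closed-form oracle model over the dataset
.closed_predict <- function(object, ds, step_idx) {
  rows <- unlist(ds$row_ranges[step_idx], use.names = FALSE)
  truth <- .true_edge_batch(object$spec, ds$X[rows, , drop = FALSE], ds$layout)
  B <- length(step_idx)
  recv0 <- .batch_of(ds, step_idx)$recv0
  masses <- rep(ds$masses, B)
  accel <- node_force_operator(truth$force, recv0 + 1L, masses)
  if (object$mode == "force")
    list(accel = accel, M = truth$force, G = NULL)
  else
    list(accel = accel, M = cbind(truth$potential), G = -truth$force)
}

# pair keys (receiver, sender) for matching edges across configurations
.edge_keys <- function(ds, rows) {
  send_local <- integer(length(ds$recv_local))
  for (rr in ds$row_ranges) {
    # reconstruct sender ids from the reverse index: sender of e is the
    # receiver of rev(e)
    send_local[rr] <- ds$recv_local[ds$rev0[rr] + 1L]
  }
  (ds$recv_local[rows]) * ds$n + send_local[rows]
}

# model + true pairwise potentials on the trajectory's initial configuration
.reference_potentials <- function(object, trajectory, ds) {
  rows0 <- ds$row_ranges[[1]]
  X0 <- ds$X[rows0, , drop = FALSE]
  truth0 <- .true_edge_batch(trajectory$spec, X0, ds$layout)
  phat0 <- if (inherits(object, "pignpi_closed")) truth0$potential
           else drop(cpp_mlp_forward(object$edge$W, object$edge$b, X0,
                                     .act_code(object$activation)))
  list(key = .edge_keys(ds, rows0), phat = phat0, ptrue = truth0$potential)
}

#' @export
print.pignpi_metrics <- function(x, ...) {
  cat(sprintf("<pignpi_metrics> %s split: %d steps x %d particles (%g edges/step)\n",
              x$label, x$n_steps, x$n_particles, x$n_edges))
  vals <- c(MAE_acc = x$mae_acc, MAE_ef = x$mae_ef, MAE_dep = x$mae_dep,
            MAE_symm_F = x$mae_symm_f, MAE_symm_P = x$mae_symm_p,
            mean_magnitude = x$mean_magnitude_error,
            mean_angle_rad = x$mean_angle_error,
            mean_cosine = x$mean_cosine)
  for (nm in names(vals))
    if (is.finite(vals[[nm]])) cat(sprintf("  %-15s %.6g\n", nm, vals[[nm]]))
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Evaluate a trained model on a larger particle system
#'
#' Applies a model trained on one system size to a freshly simulated system
#' with a different particle count, without retraining. The physics-operator
#' model transfers unchanged (its parameters are edge-level); the per-node
#' scalars of GN+ do not exist for unseen particles, so new nodes receive
#' the mean trained scalar and the report is flagged.
#'
#' @param object A fitted `pignpi` model.
#' @param trajectory Trajectory of the larger system.
#' @param steps Usable-step subset (default: all).
#' @return A `pignpi_metrics` report labelled `"generalization"`.
#' @export
generalization_eval <- function(object, trajectory, steps = NULL) {
  n_new <- dim(trajectory$positions)[2]
  notes <- character()
  if (identical(object$variant, "gn_plus") && length(object$w) != n_new) {
    object$w <- rep(mean(object$w), n_new)
    notes <- "gn_plus: unseen nodes assigned the mean trained scalar"
  }
  rep <- evaluate(object, trajectory, steps = steps, label = "generalization")
  rep$notes <- c(rep$notes, notes)
  rep
}

#' Noise-robustness sweep
#'
#' For each relative noise level, corrupts the trajectory positions,
#' recomputes kinematics by finite differences, trains each variant and
#' evaluates it on its own test split. Level 0 is the clean
#' finite-difference run.
#'
#' @param trajectory A clean `trajectory`.
#' @param levels Non-negative relative noise levels (default
#'   `c(0.001, 0.01, 0.05)`).
#' @param variants Model variants to train per level.
#' @param seed Root seed (noise, splits and training all derive from it).
#' @param ... Passed to [pignpi()] (e.g. `epochs`, `hidden_units`).
#' @return Data frame with one row per (level, variant), sorted by level,
#'   containing the main metrics.
#' @export
noise_sweep <- function(trajectory, levels = c(0.001, 0.01, 0.05),
                        variants = c("pignpi", "gn_baseline"), seed = 1, ...) {
  stopifnot(all(levels >= 0))
  levels <- sort(levels)
  out <- NULL
  for (li in seq_along(levels)) {
    noisy <- add_position_noise(trajectory, levels[li], seed = seed + 100L * li)
    for (v in variants) {
      fit <- pignpi(noisy, variant = v, seed = seed, ...)
      rep <- evaluate(fit, noisy, steps = fit$split$test)
      out <- rbind(out, data.frame(level = levels[li], variant = v,
                                   mae_acc = rep$mae_acc, mae_ef = rep$mae_ef,
                                   mae_symm_f = rep$mae_symm_f))
    }
  }
  out
}
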