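# Data splitting, the training objective, and the physics-consistency
# metric family: per-particle and per-edge mean absolute errors, symmetry
# errors, and force-field magnitude/angle errors.

#' Sum of absolute differences
#'
#' `l1(x, y) = sum_i |x_i - y_i|` for vectors, the absolute difference for
#' scalars; matrices are compared elementwise and summed.
#'
#' @param x,y Numeric objects of matching shape.
#' @return Scalar.
#' @export
l1 <- function(x, y) {
  if (length(x) != length(y)) stop("shape mismatch in l1")
  sum(abs(x - y))
}

#' Random split of time steps into train / validation / test
#'
#' Uniformly random disjoint index sets with sizes proportional to
#' `ratios` (default 7 : 1.5 : 1.5); the rounding remainder goes to the
#' training set. Deterministic per seed.
#'
#' @param n_steps Number of usable time steps.
#' @param ratios Positive length-3 weights.
#' @param seed Integer seed.
#' @return List of integer vectors `train`, `valid`, `test`.
#' @export
#' @examples
#' lengths(split_timesteps(10000, seed = 1))  # 7000 / 1500 / 1500
split_timesteps <- function(n_steps, ratios = c(7, 1.5, 1.5), seed = 1) {
  if (length(ratios) != 3 || any(ratios <= 0)) stop("ratios must be 3 positive numbers")
  set.seed(seed)
  p <- ratios / sum(ratios)
  n_valid <- floor(n_steps * p[2])
  n_test <- floor(n_steps * p[3])
  n_train <- n_steps - n_valid - n_test
  perm <- sample.int(n_steps)
  list(train = sort(perm[seq_len(n_train)]),
       valid = sort(perm[n_train + seq_len(n_valid)]),
       test = sort(perm[n_train + n_valid + seq_len(n_test)]))
}

#' Acceleration training objective
#'
#' Mean over time steps and particles of the l1 difference between
#' predicted and target accelerations.
#'
#' @param predicted,target Matrices with one row per particle-step and one
#'   column per spatial dimension.
#' @return Scalar loss.
#' @export
training_loss <- function(predicted, target) {
  if (!all(dim(predicted) == dim(target))) stop("shape mismatch")
  sum(abs(predicted - target)) / nrow(as.matrix(predicted))
}

#' Per-particle mean absolute error
#'
#' Average of `l1(pred_i^t, true_i^t)` over particles and time steps; with
#' accelerations this is the acceleration error reported as the supervised
#' metric.
#'
#' @param predicted,target Row-per-particle-step matrices.
#' @return Scalar.
#' @export
mae_part <- function(predicted, target) training_loss(predicted, target)

#' Per-edge mean absolute error
#'
#' Average of `l1` over directed edges and time steps; applied to forces it
#' is the pairwise-force error, applied to potential increments the
#' pairwise-potential incremental error.
#'
#' @param predicted,target Row-per-edge-step matrices (or vectors).
#' @return Scalar.
#' @export
mae_inter <- function(predicted, target) {
  predicted <- as.matrix(predicted)
  target <- as.matrix(target)
  training_loss(predicted, target)
}

#' Action-reaction symmetry error
#'
#' Mean over directed edges of `l1(F_ij, -F_ji)` (forces) or
#' `l1(P_ij, P_ji)` (potentials); zero iff Newton's third law (or potential
#' symmetry) holds exactly.
#'
#' @param predicted Row-per-edge matrix (or vector of potentials).
#' @param rev Reverse-edge row index.
#' @param kind `"force"` or `"potential"`.
#' @return Scalar.
#' @export
mae_symm <- function(predicted, rev, kind = c("force", "potential")) {
  kind <- match.arg(kind)
  predicted <- as.matrix(predicted)
  if (anyNA(rev)) stop("missing reverse edge")
  other <- predicted[rev, , drop = FALSE]
  if (kind == "force") mean(rowSums(abs(predicted + other)))
  else mean(rowSums(abs(predicted - other)))
}

#' Magnitude and angle errors of predicted forces
#'
#' Per edge, `| ||Fhat|| - ||F|| |` and the angle (radians) between
#' predicted and true force. Edges with a zero vector on either side are
#' excluded from the angle mean and counted.
#'
#' @param predicted,target `E x d` force matrices.
#' @return List with vectors `magnitude`, `angle` (length `E`; `NA` on
#'   excluded edges), their means, mean cosine similarity and the excluded
#'   count.
#' @export
field_errors <- function(predicted, target) {
  np <- sqrt(rowSums(predicted^2))
  nt <- sqrt(rowSums(target^2))
  magnitude <- abs(np - nt)
  ok <- np > 0 & nt > 0
  cosv <- rep(NA_real_, length(np))
  cosv[ok] <- pmin(1, pmax(-1, rowSums(predicted * target)[ok] / (np[ok] * nt[ok])))
  angle <- acos(cosv)
  list(magnitude = magnitude, angle = angle,
       mean_magnitude = mean(magnitude),
       mean_angle = mean(angle[ok]),
       mean_cosine = mean(cosv[ok]),
       n_excluded = sum(!ok))
}
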