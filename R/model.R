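# The model core: edge network plus the deterministic node physics operator.
# In force mode the node update is (sum of incoming messages) / mass; in
# potential mode it is the negative derivative of the summed scalar messages
# with respect to the receiver position, divided by mass. Neither operator
# has trainable parameters.

#' Construct an (untrained) interaction model
#'
#' Builds the edge network and fixes the node operator by `mode`. Used
#' directly for testing operators and as the starting point of [pignpi()];
#' most users call [pignpi()] instead.
#'
#' @param mode `"force"` (edge output dimension `d`) or `"potential"`
#'   (scalar edge output, differentiable activation required).
#' @param layout A [feature_layout()].
#' @param variant `"pignpi"` or one of the baselines `"gn_baseline"`,
#'   `"gn_plus"`, `"gn_plus_uni"`, `"gn_symreg"`.
#' @param hidden_layers,hidden_units Edge-network size (defaults 4 x 300).
#' @param activation `"silu"` (default), `"tanh"`, `"relu"`, `"leaky_relu"`.
#'   ReLU-family activations are rejected in potential mode: the operator
#'   differentiates the edge network, and a piecewise-constant derivative
#'   cannot represent a smooth force.
#' @param n_particles Training-system particle count (needed by the
#'   per-node scalars of `"gn_plus"`).
#' @param seed Seed for weight initialisation.
#' @return Object of class `pignpi` (untrained: empty history).
#' @export
pignpi_model <- function(mode = c("force", "potential"), layout,
                         variant = c("pignpi", "gn_baseline", "gn_plus",
                                     "gn_plus_uni", "gn_symreg"),
                         hidden_layers = 4, hidden_units = 300,
                         activation = "silu", n_particles = NULL, seed = 1) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  stopifnot(inherits(layout, "pignpi_layout"))
  if (mode == "potential" && variant == "pignpi" && !.act_smooth(activation))
    stop("potential mode needs a continuously differentiable activation; ",
         "'", activation, "' is piecewise linear")
  out_dim <- if (mode == "force") layout$d else 1L
  set.seed(seed)
  edge <- .init_mlp(layout$in_dim, out_dim, hidden_layers, hidden_units)
  node <- NULL
  w <- NULL
  if (variant %in% c("gn_baseline", "gn_symreg")) {
    node <- .init_mlp(layout$node_dim + out_dim, layout$d,
                      hidden_layers, hidden_units)
  } else if (variant == "gn_plus") {
    if (is.null(n_particles))
      stop("gn_plus needs n_particles for its per-node scalars")
    w <- numeric(n_particles)
  } else if (variant == "gn_plus_uni") {
    w <- 0
  }
  structure(list(mode = mode, variant = variant, layout = layout,
                 edge = edge, node = node, w = w,
                 activation = activation,
                 config = list(hidden_layers = hidden_layers,
                               hidden_units = hidden_units, seed = seed),
                 history = NULL, best_epoch = NULL, spec = NULL),
            class = "pignpi")
}

#' Wrap a ground-truth pair law as a perfect-oracle model
#'
#' The "edge network" of the returned model is the closed-form law itself:
#' in force mode messages are the true pairwise forces, in potential mode
#' the true pairwise potentials with their analytic position gradients.
#' Useful as an oracle in tests and for validating the node operators
#' independently of learning.
#'
#' @param spec A [system_spec()].
#' @param mode `"force"` or `"potential"`.
#' @return Object of class `c("pignpi_closed", "pignpi")`.
#' @export
closed_form_model <- function(spec, mode = c("force", "potential")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, variant = "closed_form",
                 layout = .layout_for(spec), spec = spec,
                 activation = "silu", edge = NULL, node = NULL, w = NULL),
            class = c("pignpi_closed", "pignpi"))
}

# per-edge truths from the governing law, vectorised over a sample
.true_edge_quantities <- function(spec, sample) {
  edges <- sample$edges
  n <- nrow(sample$eta)
  d <- sample$layout$d
  E <- nrow(edges)
  F <- matrix(0, E, d)
  P <- numeric(E)
  pos <- sample$eta[, 1:d, drop = FALSE]
  q <- if (sample$layout$has_charge) sample$eta[, 2 * d + 1] else rep(0, n)
  m <- sample$masses
  for (e in seq_len(E)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (!is.null(sample$disp)) {
      dd <- sample$disp[e, ]
      lp <- lj_pair(spec, dd)
      F[e, ] <- lp$force
      P[e] <- lp$potential
    } else {
      F[e, ] <- pairwise_force(spec, pos[i, ], pos[j, ], q[i], q[j], m[i], m[j])
      P[e] <- pairwise_potential(spec, pos[i, ], pos[j, ], q[i], q[j], m[i], m[j])
    }
  }
  list(force = F, potential = P)
}

#' Edge messages of a model on a graph sample
#'
#' One message per directed edge: a length-`d` force in force mode, a scalar
#' potential in potential mode.
#'
#' @param model A `pignpi` model.
#' @param sample A [graph_sample()].
#' @return `E x d` (force mode) or `E x 1` (potential mode) matrix.
#' @export
edge_messages <- function(model, sample) {
  stopifnot(inherits(model, "pignpi"), inherits(sample, "graph_sample"))
  if (inherits(model, "pignpi_closed")) {
    tq <- .true_edge_quantities(model$spec, sample)
    return(if (model$mode == "force") tq$force else cbind(tq$potential))
  }
  if (ncol(sample$X) != model$layout$in_dim)
    stop("sample feature layout does not match the model")
  cpp_mlp_forward(model$edge$W, model$edge$b, sample$X,
                  .act_code(model$activation))
}

# dM/dr_i per edge (E x d), through the receiver-position slots and, when a
# displacement feature is present, through d(disp)/dr_i = -I.
.message_position_gradient <- function(model, sample) {
  if (inherits(model, "pignpi_closed")) {
    # analytic: F_ij = -dP_ij/dr_i, so the gradient is minus the true force
    return(-.true_edge_quantities(model$spec, sample)$force)
  }
  lay <- model$layout
  res <- cpp_edge_tangent(model$edge$W, model$edge$b, sample$X,
                          .act_code(model$activation),
                          lay$pos_cols - 1L,
                          if (is.null(lay$disp_cols)) integer(0) else lay$disp_cols - 1L)
  res$G
}

#' Force-mode node operator: summed messages over mass
#'
#' The parameter-free node update of Newton's second law: the acceleration
#' of node i is the sum of its incoming messages divided by its mass.
#'
#' @param messages `E x d` message matrix.
#' @param receivers Integer receiver index per edge (1-based).
#' @param masses Particle masses (strictly positive).
#' @return `n x d` acceleration matrix.
#' @export
node_force_operator <- function(messages, receivers, masses) {
  if (any(masses <= 0)) stop("masses must be strictly positive")
  n <- length(masses)
  S <- matrix(0, n, ncol(messages))
  agg <- rowsum(messages, group = receivers)
  S[as.integer(rownames(agg)), ] <- agg
  S / masses
}

#' Potential-mode node operator: negative receiver-position derivative
#'
#' The acceleration of node i is the negative derivative of the sum of its
#' incoming scalar messages with respect to its position, divided by its
#' mass. The derivative flows through every input slot that is a function
#' of the receiver position (its position entries and, in periodic layouts,
#' the displacement feature) and is computed exactly by forward-mode
#' tangents through the edge network.
#'
#' @param model A potential-mode `pignpi` model.
#' @param sample A [graph_sample()].
#' @return `n x d` acceleration matrix.
#' @export
node_potential_operator <- function(model, sample) {
  stopifnot(model$mode == "potential")
  if (any(sample$masses <= 0)) stop("masses must be strictly positive")
  G <- .message_position_gradient(model, sample)
  -node_force_operator(G, sample$edges[, 1], sample$masses)
}

#' Extract pairwise interactions from a model
#'
#' Force mode: the messages are the inferred pairwise forces. Potential
#' mode: the messages are the inferred pairwise potentials and their
#' negative receiver-position derivatives are the forces. Re-aggregating
#' the extracted forces through [node_force_operator()] reproduces the
#' model's predicted accelerations exactly.
#'
#' @param model A `pignpi` model.
#' @param sample A [graph_sample()].
#' @return List with `force` (`E x d`; `NULL` for a scalar-message
#'   baseline, which has no force interpretation) and `potential`
#'   (length-`E` vector, potential mode only).
#' @export
extract_interactions <- function(model, sample) {
  stopifnot(inherits(model, "pignpi"))
  if (model$mode == "force") {
    M <- edge_messages(model, sample)
    list(force = M, potential = NULL)
  } else {
    M <- edge_messages(model, sample)
    F <- if (model$variant %in% c("pignpi", "closed_form"))
      -.message_position_gradient(model, sample) else NULL
    list(force = F, potential = drop(M))
  }
}

# central finite differences of edge messages over receiver-position slots;
# the independent oracle for the exact tangent mechanism
.fd_message_grad <- function(model, sample, h = 1e-5) {
  lay <- model$layout
  act <- .act_code(model$activation)
  d <- lay$d
  G <- matrix(0, nrow(sample$X), d)
  for (k in seq_len(d)) {
    Xp <- sample$X; Xm <- sample$X
    Xp[, lay$pos_cols[k]] <- Xp[, lay$pos_cols[k]] + h
    Xm[, lay$pos_cols[k]] <- Xm[, lay$pos_cols[k]] - h
    if (!is.null(lay$disp_cols)) {
      Xp[, lay$disp_cols[k]] <- Xp[, lay$disp_cols[k]] - h
      Xm[, lay$disp_cols[k]] <- Xm[, lay$disp_cols[k]] + h
    }
    Mp <- cpp_mlp_forward(model$edge$W, model$edge$b, Xp, act)
    Mm <- cpp_mlp_forward(model$edge$W, model$edge$b, Xm, act)
    G[, k] <- (Mp - Mm) / (2 * h)
  }
  G
}
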