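# Conversion of trajectory time steps into directed-graph samples: full
# connectivity for small systems, cutoff-radius connectivity with periodic
# minimum-image displacements for Lennard-Jones, and the concatenated edge
# input features the edge network consumes.

#' Feature layout of a graph sample
#'
#' Declares how node features and edge inputs are assembled. Node features
#' are `[position, velocity, charge, mass]` (charge omitted for
#' Lennard-Jones systems, where it is not a particle property). The edge
#' input is the receiver's features followed by the sender's and, for
#' periodic systems, the minimum-image displacement from receiver to sender.
#' The receiver-position (and displacement) column indices are recorded for
#' the potential-mode derivative.
#'
#' @param d Spatial dimension.
#' @param has_charge Include the charge slot in node features.
#' @param has_disp Append the per-edge displacement feature.
#' @return Object of class `pignpi_layout` with fields `d`, `node_dim`,
#'   `in_dim`, `pos_cols`, `disp_cols` (1-based; `NULL` when absent).
#' @export
feature_layout <- function(d, has_charge = TRUE, has_disp = FALSE) {
  d <- as.integer(d)
  node_dim <- 2L * d + 1L + as.integer(has_charge)
  in_dim <- 2L * node_dim + if (has_disp) d else 0L
  structure(list(d = d, node_dim = node_dim, in_dim = in_dim,
                 has_charge = has_charge, has_disp = has_disp,
                 pos_cols = 1:d,
                 disp_cols = if (has_disp) (2L * node_dim + 1L):(2L * node_dim + d) else NULL),
            class = "pignpi_layout")
}

.layout_for <- function(spec) {
  feature_layout(spec$d, has_charge = spec$law != "lj",
                 has_disp = spec$law == "lj")
}

.layout_equal <- function(a, b) {
  identical(unclass(a)[c("d", "node_dim", "in_dim", "has_charge", "has_disp")],
            unclass(b)[c("d", "node_dim", "in_dim", "has_charge", "has_disp")])
}

#' All ordered pairs of a fully connected particle graph
#'
#' @param n Particle count (>= 2).
#' @return Integer matrix with `n (n - 1)` rows and columns
#'   `receiver`, `sender`; edge (i, j) carries the message from j to i.
#' @export
#' @examples
#' build_full_graph(3)
build_full_graph <- function(n) {
  if (n < 2) stop("need at least two particles")
  idx <- expand.grid(sender = seq_len(n), receiver = seq_len(n))
  idx <- idx[idx$sender != idx$receiver, c("receiver", "sender")]
  e <- as.matrix(idx[order(idx$receiver, idx$sender), ])
  rownames(e) <- NULL
  e
}

# index of the reverse edge (j, i) for every edge (i, j)
.reverse_index <- function(edges) {
  n <- max(edges)
  key <- (edges[, 1] - 1L) * n + edges[, 2]
  rev_key <- (edges[, 2] - 1L) * n + edges[, 1]
  match(rev_key, key)
}

#' Cutoff-radius graph under periodic boundaries
#'
#' Includes the ordered pair (i, j) iff the minimum-image distance is at
#' most `r_cut`; the stored displacement is the minimum-image vector from
#' receiver i to sender j.
#'
#' @param positions `n x d` position matrix.
#' @param box_length Periodic box edge length.
#' @param r_cut Cutoff radius (<= `box_length / 2`).
#' @return List with `edges` (two-column matrix, receiver/sender) and
#'   `disp` (`E x d` matrix of displacements).
#' @export
build_cutoff_graph <- function(positions, box_length, r_cut) {
  if (r_cut > box_length / 2)
    stop("r_cut must not exceed half the box length")
  n <- nrow(positions)
  d <- ncol(positions)
  D <- lapply(seq_len(d), function(k) {
    dk <- outer(positions[, k], positions[, k], function(a, b) b - a)
    dk - box_length * floor(dk / box_length + 0.5)
  })
  R2 <- Reduce(`+`, lapply(D, function(dk) dk^2))
  diag(R2) <- Inf
  hit <- which(R2 <= r_cut^2, arr.ind = TRUE)  # row = receiver, col = sender
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  disp <- vapply(seq_len(d), function(k) D[[k]][hit], numeric(nrow(hit)))
  list(edges = unname(cbind(receiver = hit[, 1], sender = hit[, 2])),
       disp = matrix(disp, ncol = d))
}

# node feature matrix (n x node_dim) for one time step
.node_features <- function(traj, t, layout) {
  n <- dim(traj$positions)[2]
  pos <- matrix(traj$positions[t, , ], n)
  vel <- matrix(traj$velocities[t, , ], n)
  if (layout$has_charge) cbind(pos, vel, traj$charges, traj$masses)
  else cbind(pos, vel, traj$masses)
}

#' Build the directed-graph sample for one trajectory time step
#'
#' @param traj A `trajectory`.
#' @param t Time-step index.
#' @param layout Optional [feature_layout()]; defaults to the layout implied
#'   by the trajectory's system spec.
#' @return Object of class `graph_sample` with node features `eta`
#'   (`n x node_dim`), `edges`, per-edge input matrix `X`, optional `disp`,
#'   reverse-edge index `rev`, target accelerations and masses.
#' @export
graph_sample <- function(traj, t, layout = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  layout <- layout %||% .layout_for(traj$spec)
  n <- dim(traj$positions)[2]
  eta <- .node_features(traj, t, layout)
  if (layout$has_disp) {
    cg <- build_cutoff_graph(matrix(traj$positions[t, , ], n),
                             traj$spec$constants$box_length,
                             traj$spec$constants$r_cut)
    edges <- cg$edges
    disp <- cg$disp
  } else {
    edges <- build_full_graph(n)
    disp <- NULL
  }
  X <- cbind(eta[edges[, 1], , drop = FALSE], eta[edges[, 2], , drop = FALSE])
  if (!is.null(disp)) X <- cbind(X, disp)
  structure(list(eta = eta, edges = edges, X = X, disp = disp,
                 rev = .reverse_index(edges),
                 target = matrix(traj$accelerations[t, , ], n),
                 masses = traj$masses, layout = layout, t = t),
            class = "graph_sample")
}

#' Edge input feature vector of one directed edge
#'
#' Receiver features first, sender features second, then (periodic layouts
#' only) the displacement feature.
#'
#' @param sample A [graph_sample()].
#' @param e Edge row index.
#' @return Numeric feature vector of length `layout$in_dim`.
#' @export
edge_input <- function(sample, e) {
  stopifnot(inherits(sample, "graph_sample"), e >= 1, e <= nrow(sample$X))
  sample$X[e, ]
}

# Stacked dataset over many steps for batched training/evaluation.
# Node rows of step k occupy ((k-1) V + 1):(k V); edge rows are recorded in
# row_ranges. recv0/send0 are 0-based receiver indices local to the step.
.graph_dataset <- function(traj, steps = NULL, layout = NULL) {
  layout <- layout %||% .layout_for(traj$spec)
  T <- dim(traj$positions)[1]
  steps <- steps %||% seq_len(T)
  n <- dim(traj$positions)[2]
  d <- layout$d
  if (!layout$has_disp) {
    edges <- build_full_graph(n)
    rev_local <- .reverse_index(edges)
    E <- nrow(edges)
    nf <- do.call(rbind, lapply(steps, .node_features, traj = traj, layout = layout))
    ns <- length(steps)
    recv_rows <- rep((seq_len(ns) - 1L) * n, each = E) + rep(edges[, 1], ns)
    send_rows <- rep((seq_len(ns) - 1L) * n, each = E) + rep(edges[, 2], ns)
    X <- cbind(nf[recv_rows, , drop = FALSE], nf[send_rows, , drop = FALSE])
    recv_local <- rep(edges[, 1] - 1L, ns)
    rev_local_all <- rep(rev_local - 1L, ns) + rep((seq_len(ns) - 1L) * E, each = E)
    row_ranges <- lapply(seq_len(ns), function(k) ((k - 1L) * E + 1L):(k * E))
    disp <- NULL
  } else {
    samples <- lapply(steps, graph_sample, traj = traj, layout = layout)
    nf <- do.call(rbind, lapply(samples, `[[`, "eta"))
    X <- do.call(rbind, lapply(samples, `[[`, "X"))
    ecounts <- vapply(samples, function(s) nrow(s$X), integer(1))
    offs <- cumsum(c(0L, ecounts[-length(ecounts)]))
    recv_local <- unlist(lapply(samples, function(s) s$edges[, 1] - 1L))
    rev_local_all <- unlist(Map(function(s, o) s$rev - 1L + o, samples, offs))
    row_ranges <- Map(function(o, e) if (e > 0) (o + 1L):(o + e) else integer(0),
                      offs, ecounts)
    disp <- do.call(rbind, lapply(samples, `[[`, "disp"))
  }
  target <- do.call(rbind, lapply(steps, function(t)
    matrix(traj$accelerations[t, , ], n)))
  list(X = X, nf = nf, recv_local = recv_local, rev0 = rev_local_all,
       row_ranges = row_ranges, target = target,
       masses = traj$masses, n = n, d = d, steps = steps,
       layout = layout, disp = disp)
}

# Assemble one mini-batch (a set of whole time steps) from a dataset.
# sel indexes into ds$steps. Returns 0-based receiver/rev indices global to
# the batch, plus stacked node-level targets and per-node scale.
.batch_of <- function(ds, sel) {
  rows <- unlist(ds$row_ranges[sel], use.names = FALSE)
  lens <- lengths(ds$row_ranges[sel])
  B <- length(sel)
  n <- ds$n
  recv0 <- ds$recv_local[rows] + rep.int((seq_len(B) - 1L) * n, lens)
  # reverse index must be re-based within the batch
  offs_ds <- vapply(ds$row_ranges[sel], function(r) r[1] - 1L, integer(1))
  offs_batch <- cumsum(c(0L, lens[-B]))
  rev0 <- ds$rev0[rows] - rep.int(offs_ds, lens) + rep.int(offs_batch, lens)
  node_rows <- as.vector(outer(seq_len(n), (sel - 1L) * n, `+`))
  list(X = ds$X[rows, , drop = FALSE], recv0 = recv0, rev0 = rev0,
       target = ds$target[node_rows, , drop = FALSE],
       eta_nodes = ds$nf[node_rows, , drop = FALSE],
       rows = rows, node_rows = node_rows)
}
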