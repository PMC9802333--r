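# Ground-truth pair laws, initial-condition sampling, velocity-Verlet
# integration (optionally periodic / thermostatted), finite-difference
# kinematics and position-noise injection.

# Boltzmann constant in kcal/(mol K); with Angstrom and Dalton this fixes the
# internal time unit at ~48.888 fs.
.kB <- 0.0019872041

#' Specify a particle system and its governing pair law
#'
#' @param law One of `"spring"`, `"charge"`, `"orbital"`, `"discnt"`
#'   (discontinuous spring) or `"lj"` (Lennard-Jones).
#' @param d Spatial dimension, 2 or 3. Defaults to 2 for the benchmark laws
#'   and 3 for Lennard-Jones.
#' @param ... Law constants overriding the defaults: `k` (spring stiffness, 2),
#'   `L` (rest length, 1), `c` (charge constant, 1), `delta` (distance
#'   regulariser, 0.01), `theta` (discontinuity threshold, 2), `epsilon`
#'   (LJ well depth, kcal/mol, 0.238), `sigma` (LJ radius, Angstrom, 3.4),
#'   `r_cut` (interaction cutoff, 3 sigma), `box_length` (Angstrom, 27.27),
#'   `temperature` (K, 100), `mass` (Dalton, 39.9).
#'
#' @return An object of class `system_spec`.
#' @export
#' @examples
#' system_spec("spring", k = 2, L = 1)
system_spec <- function(law = c("spring", "charge", "orbital", "discnt", "lj"),
                        d = NULL, ...) {
  law <- match.arg(law)
  d <- d %||% if (law == "lj") 3L else 2L
  if (!d %in% c(2L, 3L)) stop("spatial dimension must be 2 or 3")
  defaults <- switch(law,
    spring  = list(k = 2, L = 1),
    charge  = list(c = 1, delta = 0.01),
    orbital = list(delta = 0.01),
    discnt  = list(theta = 2),
    lj      = list(epsilon = 0.238, sigma = 3.4, r_cut = 3 * 3.4,
                   box_length = 27.27, temperature = 100, mass = 39.9)
  )
  const <- utils::modifyList(defaults, list(...))
  bad <- names(const)[vapply(const, function(x) !is.numeric(x) || x <= 0, TRUE)]
  if (length(bad)) stop("constants must be positive numbers: ", paste(bad, collapse = ", "))
  if (law == "lj" && !is.null(const$box_length) &&
      const$r_cut > const$box_length / 2)
    stop("r_cut must not exceed half the box length under periodic boundaries")
  structure(list(law = law, d = as.integer(d), constants = const),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("<system_spec> law:", x$law, " d:", x$d, "\n  constants:",
      paste(names(x$constants), unlist(x$constants), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

.unit_vec <- function(disp, r) {
  if (r > 0) disp / r else disp * 0
}

#' Ground-truth pairwise force between two particles
#'
#' Returns the force exerted on particle i by particle j along the unit
#' vector pointing from i to j. For the charge and orbital laws every
#' distance in a denominator is replaced by `r + delta` so that the force is
#' exactly the negative position gradient of [pairwise_potential()]. The
#' discontinuous law is zero strictly below its threshold.
#'
#' @param spec A [system_spec()].
#' @param r_i,r_j Positions (length-`d` numeric vectors).
#' @param q_i,q_j Charges.
#' @param m_i,m_j Masses.
#' @return Length-`d` force vector on particle i.
#' @export
#' @examples
#' sp <- system_spec("spring")
#' pairwise_force(sp, c(0, 0), c(2, 0))  # k (r - L) n_ij = (2, 0)
pairwise_force <- function(spec, r_i, r_j, q_i = 0, q_j = 0, m_i = 1, m_j = 1) {
  stopifnot(inherits(spec, "system_spec"))
  disp <- r_j - r_i
  r <- sqrt(sum(disp^2))
  cs <- spec$constants
  if (r == 0 && spec$law %in% c("spring", "discnt", "lj"))
    stop("zero separation is not allowed for the ", spec$law, " law")
  n <- .unit_vec(disp, r)
  switch(spec$law,
    spring  = cs$k * (r - cs$L) * n,
    charge  = -cs$c * q_i * q_j * n / (r + cs$delta)^2,
    orbital = m_i * m_j * n / (r + cs$delta),
    discnt  = if (r < cs$theta) n * 0 else (r - 1) * n,
    lj      = lj_pair(spec, disp)$force
  )
}

#' Ground-truth pairwise potential energy between two particles
#'
#' Scalar potential of the ordered pair (i, j); symmetric in its arguments.
#' Distance regularisation matches [pairwise_force()], so the force equals
#' the negative gradient of this potential exactly.
#'
#' @inheritParams pairwise_force
#' @return Scalar potential energy.
#' @export
pairwise_potential <- function(spec, r_i, r_j, q_i = 0, q_j = 0, m_i = 1, m_j = 1) {
  stopifnot(inherits(spec, "system_spec"))
  disp <- r_j - r_i
  r <- sqrt(sum(disp^2))
  cs <- spec$constants
  if (r == 0 && spec$law %in% c("spring", "discnt", "lj"))
    stop("zero separation is not allowed for the ", spec$law, " law")
  switch(spec$law,
    spring  = 0.5 * cs$k * (r - cs$L)^2,
    charge  = cs$c * q_i * q_j / (r + cs$delta),
    orbital = m_i * m_j * log(r + cs$delta),
    discnt  = if (r < cs$theta) 0 else 0.5 * (r - 1)^2,
    lj      = lj_pair(spec, disp)$potential
  )
}

#' Lennard-Jones pair potential and force
#'
#' Evaluates `V(r) = 4 epsilon ((sigma/r)^12 - (sigma/r)^6)` and the force on
#' the receiver particle for a given (possibly minimum-image) displacement
#' from i to j. Both are exactly zero beyond the cutoff radius.
#'
#' @param spec A [system_spec()] with law `"lj"`.
#' @param disp Displacement vector from particle i to particle j.
#' @return List with elements `potential` (scalar) and `force` (vector on i).
#' @export
lj_pair <- function(spec, disp) {
  stopifnot(inherits(spec, "system_spec"), spec$law == "lj")
  cs <- spec$constants
  r <- sqrt(sum(disp^2))
  if (r == 0) stop("zero-length displacement")
  if (r > cs$r_cut)
    return(list(potential = 0, force = disp * 0))
  sr6 <- (cs$sigma / r)^6
  v <- 4 * cs$epsilon * (sr6^2 - sr6)
  # F_i = -(24 eps / r) (2 (sigma/r)^12 - (sigma/r)^6) n_ij
  fmag <- -(24 * cs$epsilon / r) * (2 * sr6^2 - sr6)
  list(potential = v, force = fmag * disp / r)
}

#' Minimum-image displacement under periodic boundaries
#'
#' Componentwise displacement from i to j wrapped into
#' `[-box_length/2, box_length/2)`.
#'
#' @param r_i,r_j Positions.
#' @param box_length Edge length of the cubic periodic box (> 0).
#' @return Length-`d` displacement vector.
#' @export
minimum_image <- function(r_i, r_j, box_length) {
  stopifnot(box_length > 0)
  disp <- r_j - r_i
  disp - box_length * floor(disp / box_length + 0.5)
}

# Vectorised net forces for all particles: returns n x d matrix.
# pos is n x d; for periodic systems displacements use the minimum image.
.net_forces <- function(spec, pos, q, m) {
  n <- nrow(pos)
  d <- ncol(pos)
  cs <- spec$constants
  box <- if (spec$law == "lj") cs$box_length else NULL
  D <- lapply(seq_len(d), function(k) {
    dk <- outer(pos[, k], pos[, k], function(a, b) b - a)
    if (!is.null(box)) dk <- dk - box * floor(dk / box + 0.5)
    dk
  })
  R2 <- Reduce(`+`, lapply(D, function(dk) dk^2))
  diag(R2) <- Inf
  R <- sqrt(R2)
  coef <- switch(spec$law,  # F_ij = coef[i,j] * (r_j - r_i)
    spring  = cs$k * (R - cs$L) / R,
    charge  = -cs$c * outer(q, q) / ((R + cs$delta)^2 * R),
    orbital = outer(m, m) / ((R + cs$delta) * R),
    discnt  = ifelse(R < cs$theta, 0, (R - 1) / R),
    lj      = {
      sr6 <- (cs$sigma / R)^6
      ifelse(R > cs$r_cut, 0, -(24 * cs$epsilon) * (2 * sr6^2 - sr6) / R2)
    }
  )
  diag(coef) <- 0
  F <- vapply(seq_len(d), function(k) rowSums(coef * D[[k]]), numeric(n))
  matrix(F, n, d)
}

# Total pair potential energy sum_{i<j} P_ij (used by energy-drift checks).
.total_potential <- function(spec, pos, q, m) {
  n <- nrow(pos)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + pairwise_potential(spec, pos[i, ], pos[j, ],
                                    q[i], q[j], m[i], m[j])
  tot
}

#' Sample an initial particle state
#'
#' For the benchmark laws, positions and velocities are standard normal per
#' component, `ln(m) ~ U(-1, 1)` and charges are `U(-1, 1)`. For the
#' Lennard-Jones law, particles are placed uniformly in the periodic box with
#' a minimum-separation rejection step and velocities are Maxwell-Boltzmann
#' at the spec temperature; charges are zero and the mass is the spec mass.
#'
#' @param n Particle count (>= 2).
#' @param spec A [system_spec()].
#' @param seed Integer seed; the draw is reproducible.
#' @return Object of class `particle_state` with fields `positions`,
#'   `velocities` (n x d), `charges`, `masses` (length n).
#' @export
sample_initial_state <- function(n, spec, seed = 1) {
  stopifnot(inherits(spec, "system_spec"))
  if (n < 2) stop("need at least two particles")
  set.seed(seed)
  d <- spec$d
  cs <- spec$constants
  if (spec$law == "lj") {
    box <- cs$box_length
    min_sep <- 0.85 * cs$sigma
    pos <- matrix(NA_real_, n, d)
    placed <- 0
    tries <- 0
    while (placed < n) {
      cand <- runif(d, 0, box)
      ok <- TRUE
      if (placed > 0) {
        dd <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
        dd <- dd - box * floor(dd / box + 0.5)
        ok <- min(sqrt(rowSums(dd^2))) >= min_sep
      }
      if (ok) { placed <- placed + 1; pos[placed, ] <- cand }
      tries <- tries + 1
      if (tries > 1e6) stop("could not place particles without overlap; box too dense")
    }
    m <- rep(cs$mass, n)
    vel <- matrix(rnorm(n * d, sd = sqrt(.kB * cs$temperature / cs$mass)), n, d)
    q <- rep(0, n)
  } else {
    pos <- matrix(rnorm(n * d), n, d)
    vel <- matrix(rnorm(n * d), n, d)
    q <- runif(n, -1, 1)
    m <- exp(runif(n, -1, 1))
  }
  structure(list(positions = pos, velocities = vel, charges = q, masses = m,
                 t = 0L, spec = spec),
            class = "particle_state")
}

#' Integrate a particle system with velocity Verlet
#'
#' Advances the state under the net pairwise force of the governing law
#' (Newton's second law, no external force) and records positions,
#' velocities and accelerations at every step. Periodic systems are wrapped
#' into the box. An optional Langevin thermostat (seeded) can act, e.g.
#' during Lennard-Jones equilibration.
#'
#' @param state A [sample_initial_state()] result.
#' @param spec A [system_spec()].
#' @param n_steps Number of recorded steps.
#' @param dt Step size (> 0).
#' @param thermostat `"none"` or `"langevin"`.
#' @param friction Langevin friction constant (1 / time unit).
#' @param seed Seed for the thermostat noise.
#' @return Object of class `trajectory`: arrays `positions`, `velocities`,
#'   `accelerations` of dim `(n_steps, n, d)`, static `charges`/`masses`,
#'   `dt`, `spec`, `provenance` and the periodic `box` (or `NULL`).
#' @export
integrate_system <- function(state, spec, n_steps, dt,
                             thermostat = c("none", "langevin"),
                             friction = 1, seed = 1) {
  stopifnot(inherits(state, "particle_state"), dt > 0, n_steps >= 1)
  thermostat <- match.arg(thermostat)
  n <- nrow(state$positions)
  d <- spec$d
  box <- if (spec$law == "lj") spec$constants$box_length else NULL
  pos <- state$positions
  vel <- state$velocities
  q <- state$charges
  m <- state$masses
  if (thermostat == "langevin") {
    set.seed(seed)
    c1 <- exp(-friction * dt)
    c2 <- sqrt((1 - c1^2) * .kB * spec$constants$temperature / m)
  }
  P <- array(NA_real_, c(n_steps, n, d))
  V <- array(NA_real_, c(n_steps, n, d))
  A <- array(NA_real_, c(n_steps, n, d))
  acc <- .net_forces(spec, pos, q, m) / m
  for (s in seq_len(n_steps)) {
    P[s, , ] <- pos; V[s, , ] <- vel; A[s, , ] <- acc
    pos <- pos + vel * dt + 0.5 * acc * dt^2
    if (!is.null(box)) pos <- pos - box * floor(pos / box)
    acc_new <- .net_forces(spec, pos, q, m) / m
    vel <- vel + 0.5 * (acc + acc_new) * dt
    if (thermostat == "langevin")
      vel <- c1 * vel + matrix(rnorm(n * d), n, d) * c2
    acc <- acc_new
    if (!all(is.finite(pos)))
      stop("integration blew up at step ", s,
           ": non-finite positions (reduce dt or check constants)")
  }
  structure(list(positions = P, velocities = V, accelerations = A,
                 charges = q, masses = m, dt = dt, spec = spec,
                 provenance = "integrator", box = box),
            class = "trajectory")
}

#' Simulate a trajectory from scratch
#'
#' Samples an initial state and integrates it. For the Lennard-Jones law an
#' equilibration prefix is run first under a Langevin thermostat and
#' discarded; production steps are plain (energy-conserving) velocity Verlet.
#'
#' @inheritParams integrate_system
#' @param n Particle count.
#' @param equilibration Number of discarded thermostatted steps (LJ only).
#' @export
#' @examples
#' traj <- simulate_system(system_spec("spring"), n = 4, n_steps = 50,
#'                         dt = 0.01, seed = 1)
simulate_system <- function(spec, n = 8, n_steps = 10000, dt = 0.01, seed = 1,
                            equilibration = if (spec$law == "lj") 200 else 0,
                            friction = 1) {
  state <- sample_initial_state(n, spec, seed = seed)
  if (equilibration > 0) {
    eq <- integrate_system(state, spec, equilibration, dt,
                           thermostat = "langevin", friction = friction,
                           seed = seed + 1L)
    last <- dim(eq$positions)[1]
    state$positions <- matrix(eq$positions[last, , ], n, spec$d)
    state$velocities <- matrix(eq$velocities[last, , ], n, spec$d)
  }
  integrate_system(state, spec, n_steps, dt)
}

#' @export
print.trajectory <- function(x, ...) {
  dm <- dim(x$positions)
  cat(sprintf("<trajectory> %s law, %d steps x %d particles x %dD, dt = %g (%s)\n",
              x$spec$law, dm[1], dm[2], dm[3], x$dt, x$provenance))
  invisible(x)
}

#' Central-difference velocities and accelerations from positions
#'
#' `v_t = (r_{t+1} - r_{t-1}) / (2 dt)` and
#' `a_t = (r_{t+1} - 2 r_t + r_{t-1}) / dt^2` at interior steps; the two
#' endpoint steps carry no estimate and are dropped downstream.
#'
#' @param positions Array of dim `(T, n, d)` with `T >= 3`.
#' @param dt Step size.
#' @return List with arrays `velocities` and `accelerations` of dim
#'   `(T - 2, n, d)` and the `interior` step indices they correspond to.
#' @export
finite_difference_kinematics <- function(positions, dt) {
  T <- dim(positions)[1]
  if (is.na(T) || T < 3) stop("need at least 3 time steps")
  fwd <- positions[3:T, , , drop = FALSE]
  bwd <- positions[1:(T - 2), , , drop = FALSE]
  mid <- positions[2:(T - 1), , , drop = FALSE]
  list(velocities = (fwd - bwd) / (2 * dt),
       accelerations = (fwd - 2 * mid + bwd) / dt^2,
       interior = 2:(T - 1))
}

#' Replace a trajectory's kinematics by finite differences
#'
#' Mirrors the observational premise that only positions are measured:
#' velocities and accelerations are recomputed by central differences and
#' the two endpoint steps are dropped.
#'
#' @param traj A `trajectory`.
#' @return A `trajectory` with `T - 2` steps and provenance
#'   `"finite-difference"` (input provenance is kept if already
#'   finite-differenced).
#' @export
with_fd_kinematics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  kin <- finite_difference_kinematics(traj$positions, traj$dt)
  traj$positions <- traj$positions[kin$interior, , , drop = FALSE]
  traj$velocities <- kin$velocities
  traj$accelerations <- kin$accelerations
  if (!traj$provenance %in% "noisy") traj$provenance <- "finite-difference"
  traj
}

#' Add measurement noise to trajectory positions
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `noise_scale` times the per-dimension standard deviation of all positions,
#' then recomputes velocities and accelerations by central differences
#' (dropping the endpoint steps).
#'
#' @param traj A `trajectory`.
#' @param noise_scale Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return A noisy `trajectory` with provenance `"noisy"` (or the clean
#'   finite-difference trajectory when `noise_scale` is 0).
#' @export
add_position_noise <- function(traj, noise_scale, seed = 1) {
  stopifnot(inherits(traj, "trajectory"), noise_scale >= 0)
  if (noise_scale > 0) {
    set.seed(seed)
    dm <- dim(traj$positions)
    sds <- apply(traj$positions, 3, sd)
    noise <- array(rnorm(prod(dm)), dm)
    for (k in seq_len(dm[3])) noise[, , k] <- noise[, , k] * noise_scale * sds[k]
    traj$positions <- traj$positions + noise
    traj$provenance <- "noisy"
  }
  with_fd_kinematics(traj)
}
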