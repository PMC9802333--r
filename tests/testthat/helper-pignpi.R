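# Fixtures are generated in code: short spring trajectories, hand-built
# two-body states and small models reused across test files.

make_spring_traj <- function(n = 4, steps = 60, seed = 1, dt = 0.01) {
  simulate_system(system_spec("spring"), n = n, n_steps = steps,
                  dt = dt, seed = seed)
}

# particle state with explicit fields (bypasses random sampling)
make_state <- function(positions, velocities = positions * 0,
                       charges = rep(0, nrow(positions)),
                       masses = rep(1, nrow(positions)), spec) {
  structure(list(positions = positions, velocities = velocities,
                 charges = charges, masses = masses, t = 0L, spec = spec),
            class = "particle_state")
}

small_model <- function(mode = "force", variant = "pignpi", layout = NULL,
                        seed = 1, n_particles = 4, hidden_layers = 2,
                        hidden_units = 8, ...) {
  layout <- layout %||% feature_layout(2)
  pignpi_model(mode, layout, variant, hidden_layers = hidden_layers,
               hidden_units = hidden_units, n_particles = n_particles,
               seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# total energy (kinetic + pair potential) of one trajectory step
total_energy <- function(traj, s) {
  n <- dim(traj$positions)[2]
  pos <- matrix(traj$positions[s, , ], n)
  vel <- matrix(traj$velocities[s, , ], n)
  kin <- 0.5 * sum(traj$masses * rowSums(vel^2))
  kin + pignpi:::.total_potential(traj$spec, pos, traj$charges, traj$masses)
}
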