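# Ground-truth pair laws, sampling, integration and kinematics.

test_that("pairwise forces match the closed-form laws", {
  sp <- system_spec("spring", k = 2, L = 1)
  expect_equal(pairwise_force(sp, c(0, 0), c(1, 0)), c(0, 0))
  expect_equal(pairwise_force(sp, c(0, 0), c(2, 0)), c(2, 0))

  ch <- system_spec("charge", c = 1, delta = 0.01)
  expect_equal(pairwise_force(ch, c(0, 0), c(1, 0), q_i = 1, q_j = 1),
               c(-1 / 1.01^2, 0))

  orb <- system_spec("orbital", delta = 0.01)
  expect_equal(pairwise_potential(orb, c(0, 0), c(1, 0), m_i = 1, m_j = 1),
               log(1.01))

  dc <- system_spec("discnt", theta = 2)
  expect_equal(pairwise_force(dc, c(0, 0), c(1.5, 0)), c(0, 0))
  expect_equal(pairwise_potential(dc, c(0, 0), c(1.9, 0)), 0)
  # the nonzero branch applies at exactly r = theta
  expect_equal(pairwise_force(dc, c(0, 0), c(2, 0)), c(1, 0))
  expect_equal(pairwise_force(dc, c(0, 0), c(2.5, 0)), c(1.5, 0))
})

test_that("forces are antisymmetric and potentials symmetric for all laws", {
  set.seed(11)
  specs <- list(system_spec("spring"), system_spec("charge"),
                system_spec("orbital"), system_spec("discnt"))
  for (spec in specs) {
    for (rep in 1:20) {
      ri <- rnorm(2); rj <- rnorm(2)
      qi <- runif(1, -1, 1); qj <- runif(1, -1, 1)
      mi <- exp(runif(1, -1, 1)); mj <- exp(runif(1, -1, 1))
      fij <- pairwise_force(spec, ri, rj, qi, qj, mi, mj)
      fji <- pairwise_force(spec, rj, ri, qj, qi, mj, mi)
      expect_equal(fij, -fji)
      expect_equal(pairwise_potential(spec, ri, rj, qi, qj, mi, mj),
                   pairwise_potential(spec, rj, ri, qj, qi, mj, mi))
    }
  }
})

test_that("force equals minus the finite-difference potential gradient", {
  set.seed(12)
  h <- 1e-6
  specs <- list(system_spec("spring"), system_spec("charge"),
                system_spec("orbital"), system_spec("discnt"),
                system_spec("lj"))
  for (spec in specs) {
    d <- spec$d
    for (rep in 1:10) {
      ri <- rnorm(d)
      rj <- ri + rnorm(d)
      r <- sqrt(sum((rj - ri)^2))
      if (spec$law == "discnt" && abs(r - spec$constants$theta) < 10 * h) next
      if (spec$law == "lj") {
        # keep inside the active well, away from the cutoff edge
        rj <- ri + (rj - ri) / r * runif(1, 0.95, 2.9) * spec$constants$sigma
      }
      qi <- 0.7; qj <- -0.4; mi <- 1.3; mj <- 0.8
      f <- pairwise_force(spec, ri, rj, qi, qj, mi, mj)
      g <- vapply(seq_len(d), function(k) {
        e <- numeric(d); e[k] <- h
        (pairwise_potential(spec, ri + e, rj, qi, qj, mi, mj) -
         pairwise_potential(spec, ri - e, rj, qi, qj, mi, mj)) / (2 * h)
      }, numeric(1))
      expect_equal(f, -g, tolerance = 1e-4)
    }
  }
})

test_that("Lennard-Jones pair has the analytic zero, minimum and cutoff", {
  lj <- system_spec("lj")
  s <- lj$constants$sigma
  eps <- lj$constants$epsilon
  expect_equal(lj_pair(lj, c(s, 0, 0))$potential, 0)
  rmin <- 2^(1 / 6) * s
  at_min <- lj_pair(lj, c(rmin, 0, 0))
  expect_equal(at_min$force, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(at_min$potential, -eps)
  beyond <- lj_pair(lj, c(3 * s + 1e-9, 0, 0))
  expect_identical(beyond$potential, 0)
  expect_identical(beyond$force, c(0, 0, 0))
  # finite-difference force oracle across the active range
  set.seed(13)
  for (r in runif(12, 0.91 * s, 2.99 * s)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    h <- 1e-6 * s
    dv <- (lj_pair(lj, (r + h) * u)$potential -
           lj_pair(lj, (r - h) * u)$potential) / (2 * h)
    expect_equal(lj_pair(lj, r * u)$force, -dv * (-u), tolerance = 1e-5)
  }
})

test_that("minimum image wraps into the half-open box and beats brute force", {
  expect_equal(minimum_image(0.5, 9.5, 10), -1)
  expect_equal(minimum_image(c(1, 2), c(1, 2), 10), c(0, 0))
  # half-box edge maps to -box/2, keeping the interval half-open
  expect_equal(minimum_image(0, 5, 10), -5)
  set.seed(14)
  for (rep in 1:30) {
    d <- sample(2:3, 1)
    box <- runif(1, 2, 20)
    ri <- runif(d, 0, box); rj <- runif(d, 0, box)
    mi <- minimum_image(ri, rj, box)
    shifts <- as.matrix(expand.grid(rep(list(-1:1), d))) * box
    cand <- sweep(shifts, 2, rj - ri, `+`)
    expect_equal(sqrt(sum(mi^2)), min(sqrt(rowSums(cand^2))), tolerance = 1e-12)
    expect_lte(sqrt(sum(mi^2)), sqrt(d) / 2 * box)
  }
})

test_that("initial-state sampling honours the documented distributions", {
  sp <- system_spec("spring")
  st <- sample_initial_state(8, sp, seed = 3)
  expect_identical(st, sample_initial_state(8, sp, seed = 3))
  big <- sample_initial_state(50000, sp, seed = 4)
  expect_gte(min(big$masses), exp(-1))
  expect_lte(max(big$masses), exp(1))
  expect_gte(min(big$charges), -1)
  expect_lte(max(big$charges), 1)
  # law-of-large-numbers tolerance on the position mean
  n_draws <- length(big$positions)
  expect_lt(max(abs(colMeans(big$positions))), 3 / sqrt(nrow(big$positions)))
  # log-masses uniform on [-1, 1]
  ks <- stats::ks.test(log(big$masses), "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_initial_state(1, sp), "two particles")
})

test_that("LJ initial states sit in the box with Maxwell-Boltzmann speeds", {
  lj <- system_spec("lj")
  st <- sample_initial_state(64, lj, seed = 5)
  expect_true(all(st$positions >= 0 & st$positions <= lj$constants$box_length))
  # no overlapping placements
  dmin <- min(dist(st$positions))
  expect_gte(dmin, 0.5 * lj$constants$sigma)
  expect_equal(st$masses, rep(39.9, 64))
})

test_that("two-body spring oscillates at the analytic frequency", {
  sp <- system_spec("spring", k = 2, L = 1)
  s0 <- 1.5
  st <- make_state(rbind(c(0, 0), c(s0, 0)), spec = sp)
  omega <- sqrt(2 * sp$constants$k / 1)  # equal unit masses
  period <- 2 * pi / omega
  dt <- 0.001
  steps <- ceiling(period / dt) + 1
  traj <- integrate_system(st, sp, steps, dt)
  sep <- sqrt(rowSums((traj$positions[, 2, ] - traj$positions[, 1, ])^2))
  tt <- (seq_len(steps) - 1) * dt
  closed <- sp$constants$L + (s0 - sp$constants$L) * cos(omega * tt)
  expect_lt(max(abs(sep - closed)) / max(abs(closed)), 1e-3)
})

test_that("conservative integration conserves momentum and bounds energy drift", {
  traj <- simulate_system(system_spec("spring"), n = 8, n_steps = 10000,
                          dt = 0.01, seed = 6)
  p <- apply(traj$velocities * rep(traj$masses, each = 10000), c(1, 3), sum)
  step_change <- abs(diff(p))
  expect_lt(max(step_change), 1e-10)
  e0 <- total_energy(traj, 1)
  drift <- vapply(seq(1, 10000, by = 500), function(s)
    abs(total_energy(traj, s) - e0), numeric(1))
  expect_lt(max(drift), 0.01 * abs(e0))
})

test_that("finite-difference kinematics are exact on polynomials", {
  dt <- 0.1
  tgrid <- (0:20) * dt
  # uniform motion: velocity exact, acceleration zero
  pos <- array(0, c(21, 1, 2))
  pos[, 1, 1] <- 3 * tgrid
  pos[, 1, 2] <- -2 * tgrid
  kin <- finite_difference_kinematics(pos, dt)
  expect_equal(kin$velocities[, 1, 1], rep(3, 19))
  expect_equal(kin$accelerations[, 1, ], matrix(0, 19, 2))
  # quadratic: acceleration exactly 2
  pos[, 1, 1] <- tgrid^2
  kin <- finite_difference_kinematics(pos, dt)
  expect_equal(kin$accelerations[, 1, 1], rep(2, 19))
  # smooth oscillation: second-order accuracy
  dt <- 1e-3
  tgrid <- (0:200) * dt
  pos <- array(sin(tgrid), c(201, 1, 1))
  kin <- finite_difference_kinematics(pos, dt)
  expect_lt(max(abs(kin$accelerations[, 1, 1] + sin(tgrid[2:200]))), 1e-5)
  expect_error(finite_difference_kinematics(array(0, c(2, 1, 1)), dt), "3 time steps")
})

test_that("position noise is seeded, scaled and recomputes kinematics", {
  traj <- make_spring_traj(n = 12, steps = 900, seed = 7)
  clean <- add_position_noise(traj, 0, seed = 1)
  fd <- with_fd_kinematics(traj)
  expect_equal(clean$positions, fd$positions)
  expect_equal(clean$accelerations, fd$accelerations)
  n1 <- add_position_noise(traj, 0.01, seed = 9)
  n2 <- add_position_noise(traj, 0.01, seed = 9)
  expect_identical(n1, n2)
  expect_identical(n1$provenance, "noisy")
  # empirical noise std within 5% of the requested level
  sds <- apply(traj$positions, 3, sd)
  delta <- n1$positions - fd$positions
  for (k in 1:2) {
    expect_equal(sd(delta[, , k]), 0.01 * sds[k], tolerance = 0.05)
  }
})
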