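# Splitting, objectives, metric family and training mechanics.

test_that("splits have the prescribed sizes with the remainder in training", {
  sp <- split_timesteps(10000, seed = 1)
  expect_equal(lengths(sp), c(train = 7000, valid = 1500, test = 1500))
  expect_identical(split_timesteps(10000, seed = 1), sp)
  expect_false(identical(split_timesteps(10000, seed = 2), sp))
  for (n in 1:100) {
    s <- split_timesteps(n, seed = n)
    expect_equal(sum(lengths(s)), n)
    expect_length(intersect(s$train, s$valid), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$valid, s$test), 0)
    expect_equal(length(s$valid), floor(n * 0.15))
    expect_equal(length(s$test), floor(n * 0.15))
    expect_equal(length(s$train), n - 2 * floor(n * 0.15))
  }
})

test_that("l1 and the training loss follow their definitions", {
  expect_equal(l1(c(1, 2), c(1, 2)), 0)
  expect_equal(l1(c(1, 2), c(0, 0)), 3)
  expect_error(l1(1:3, 1:2), "shape")
  set.seed(2)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(l1(x, y), sum(abs(x - y)))

  expect_equal(training_loss(rbind(c(0.1, -0.2)), rbind(c(0, 0))), 0.3)
  P <- matrix(rnorm(12), 4); Tg <- matrix(rnorm(12), 4)
  brute <- mean(vapply(1:4, function(i) l1(P[i, ], Tg[i, ]), numeric(1)))
  expect_equal(training_loss(P, Tg), brute)
  expect_equal(training_loss(P, P), 0)
})

test_that("per-particle and per-edge errors average l1 over their units", {
  set.seed(3)
  A <- matrix(rnorm(20), 10)
  expect_equal(mae_part(A, A), 0)
  expect_equal(mae_inter(A, A), 0)
  B <- matrix(rnorm(20), 10)
  brute <- mean(vapply(1:10, function(i) l1(A[i, ], B[i, ]), numeric(1)))
  expect_equal(mae_part(A, B), brute)
  expect_equal(mae_inter(A, B), brute)
  # potential increments are offset invariant (telescoping)
  p <- rnorm(10); p0 <- rnorm(1); q <- rnorm(10); q0 <- rnorm(1)
  expect_equal(mae_inter((p + 5) - (p0 + 5), q - q0),
               mae_inter(p - p0, q - q0))
})

test_that("symmetry errors vanish exactly on symmetric interactions", {
  edges <- build_full_graph(4)
  rev <- match(paste(edges[, 2], edges[, 1]), paste(edges[, 1], edges[, 2]))
  set.seed(4)
  M <- matrix(rnorm(nrow(edges) * 2), nrow(edges))
  F_anti <- M - M[rev, ]
  expect_equal(mae_symm(F_anti, rev, "force"), 0)
  P_symm <- rowSums(M)[rev] + rowSums(M)  # symmetric scalar per pair
  expect_equal(mae_symm(cbind(P_symm), rev, "potential"), 0)
  # hand-set two-particle case
  F2 <- rbind(c(1, 0), c(-0.5, 0.25))
  expect_equal(mae_symm(F2, c(2, 1), "force"), 0.75)
  expect_error(mae_symm(F2, c(2, NA), "force"), "reverse")
})

test_that("field errors capture magnitude, angle and degenerate edges", {
  F <- rbind(c(1, 0), c(0, 2))
  fe <- field_errors(F, F)
  expect_equal(fe$mean_magnitude, 0)
  expect_equal(fe$mean_angle, 0)
  expect_equal(fe$mean_cosine, 1)
  fe2 <- field_errors(2 * F, F)
  expect_equal(fe2$magnitude, sqrt(rowSums(F^2)))
  expect_equal(fe2$mean_angle, 0)
  perp <- field_errors(rbind(c(0, 1)), rbind(c(1, 0)))
  expect_equal(perp$mean_angle, pi / 2)
  withzero <- field_errors(rbind(c(0, 0), c(1, 0)), rbind(c(1, 0), c(1, 0)))
  expect_equal(withzero$n_excluded, 1)
  expect_equal(withzero$mean_angle, 0)
})

test_that("a small spring dataset can be overfitted", {
  traj <- make_spring_traj(n = 8, steps = 22, seed = 5)
  fit <- pignpi(traj, mode = "force", epochs = 800, hidden_layers = 2,
                hidden_units = 64, batch_size = 4, split = c(8, 1, 1),
                seed = 5)
  # capacity check: the training error collapses relative to where the
  # first epoch starts (the absolute floor is set by the fixed Adam step)
  expect_lt(min(fit$history$train_loss), 0.05 * fit$history$train_loss[1])
  scale <- mean(abs(with_fd_kinematics(traj)$accelerations))
  expect_lt(min(fit$history$train_loss), 0.05 * scale)
})

test_that("training is deterministic given the seed", {
  traj <- make_spring_traj(n = 4, steps = 40, seed = 6)
  f1 <- pignpi(traj, epochs = 2, hidden_layers = 1, hidden_units = 8, seed = 3)
  f2 <- pignpi(traj, epochs = 2, hidden_layers = 1, hidden_units = 8, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$edge, f2$edge)
  expect_identical(f1$split, f2$split)
})

test_that("alpha = 0 symmetry regularization is bit-identical to the baseline", {
  traj <- make_spring_traj(n = 4, steps = 40, seed = 7)
  fb <- pignpi(traj, variant = "gn_baseline", epochs = 3, hidden_layers = 1,
               hidden_units = 8, seed = 4)
  fs <- pignpi(traj, variant = "gn_symreg", alpha = 0, epochs = 3,
               hidden_layers = 1, hidden_units = 8, seed = 4)
  expect_identical(fb$history, fs$history)
  expect_identical(fb$edge, fs$edge)
  expect_identical(fb$node, fs$node)
})

test_that("evaluation reports test metrics and a perfect oracle scores zero", {
  traj <- make_spring_traj(n = 4, steps = 60, seed = 8)
  cf <- closed_form_model(system_spec("spring"), "force")
  cf$kinematics <- "recorded"
  rep <- evaluate(cf, traj, label = "oracle")
  expect_s3_class(rep, "pignpi_metrics")
  expect_equal(rep$mae_ef, 0, tolerance = 1e-12)
  expect_equal(rep$mae_acc, 0, tolerance = 1e-10)
  expect_equal(rep$mae_symm_f, 0, tolerance = 1e-12)
  expect_equal(rep$mean_cosine, 1, tolerance = 1e-12)
  cfp <- closed_form_model(system_spec("spring"), "potential")
  cfp$kinematics <- "recorded"
  repp <- evaluate(cfp, traj, label = "oracle")
  expect_equal(repp$mae_dep, 0, tolerance = 1e-12)
  expect_equal(repp$mae_symm_p, 0, tolerance = 1e-12)
})

test_that("generalization evaluation transfers to more particles", {
  traj <- make_spring_traj(n = 4, steps = 50, seed = 9)
  fit <- pignpi(traj, epochs = 2, hidden_layers = 1, hidden_units = 8, seed = 5)
  big <- make_spring_traj(n = 6, steps = 30, seed = 10)
  rep <- generalization_eval(fit, big)
  expect_equal(rep$n_particles, 6)
  expect_equal(rep$n_edges, 30)
  expect_identical(rep$label, "generalization")
  # GN+ falls back to the mean trained scalar, flagged in the notes
  fg <- pignpi(traj, variant = "gn_plus", epochs = 2, hidden_layers = 1,
               hidden_units = 8, seed = 5)
  rg <- generalization_eval(fg, big)
  expect_match(paste(rg$notes, collapse = " "), "mean trained scalar")
})

test_that("the noise sweep is ordered, seeded and collapses at level zero", {
  traj <- make_spring_traj(n = 4, steps = 50, seed = 11)
  tab <- noise_sweep(traj, levels = c(0.01, 0), epochs = 2, seed = 6,
                     hidden_layers = 1, hidden_units = 8)
  expect_equal(tab$level, c(0, 0, 0.01, 0.01))
  tab2 <- noise_sweep(traj, levels = c(0, 0.01), epochs = 2, seed = 6,
                      hidden_layers = 1, hidden_units = 8)
  expect_equal(tab, tab2)
  # the level-0 row equals a clean finite-difference run
  fit <- pignpi(with_fd_kinematics(traj), epochs = 2, hidden_layers = 1,
                hidden_units = 8, seed = 6)
  rep <- evaluate(fit, with_fd_kinematics(traj), steps = fit$split$test)
  expect_equal(tab$mae_ef[tab$variant == "pignpi" & tab$level == 0],
               rep$mae_ef)
})
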