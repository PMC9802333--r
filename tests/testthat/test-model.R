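# The model core: edge messages, deterministic node operators, interaction
# extraction and the exact-derivative mechanism.

test_that("edge messages are per-edge applications of the network", {
  traj <- make_spring_traj(n = 4, steps = 12, seed = 1)
  ft <- with_fd_kinematics(traj)
  gs <- graph_sample(ft, 3)

  m <- small_model("force", seed = 2)
  # zero-weight, zero-bias network: all messages vanish
  m0 <- m
  m0$edge$W <- lapply(m0$edge$W, function(w) w * 0)
  m0$edge$b <- lapply(m0$edge$b, function(b) b * 0)
  expect_equal(edge_messages(m0, gs), matrix(0, nrow(gs$X), 2))

  # single linear layer reproduces the hand-computed affine map
  lay <- feature_layout(2)
  ml <- pignpi_model("force", lay, hidden_layers = 0, hidden_units = 1, seed = 3)
  M <- edge_messages(ml, gs)
  expect_equal(M, gs$X %*% ml$edge$W[[1]] +
                 matrix(ml$edge$b[[1]], nrow(gs$X), 2, byrow = TRUE))

  # permuting edges permutes messages identically
  perm <- sample(nrow(gs$X))
  gsp <- gs
  gsp$X <- gs$X[perm, , drop = FALSE]
  expect_equal(edge_messages(m, gsp), edge_messages(m, gs)[perm, ])
})

test_that("the force-mode node operator is the exact mass-scaled sum", {
  msgs <- rbind(c(1, 0), c(0, 1))
  acc <- node_force_operator(msgs, receivers = c(1, 1), masses = c(2, 5))
  expect_equal(acc, rbind(c(0.5, 0.5), c(0, 0)))
  # brute-force aggregation oracle on random data
  set.seed(31)
  for (rep in 1:10) {
    n <- 6; E <- 25
    msgs <- matrix(rnorm(E * 2), E)
    recv <- sample(n, E, replace = TRUE)
    m <- exp(runif(n, -1, 1))
    brute <- matrix(0, n, 2)
    for (e in seq_len(E)) brute[recv[e], ] <- brute[recv[e], ] + msgs[e, ]
    brute <- brute / m
    expect_equal(node_force_operator(msgs, recv, m), brute, tolerance = 1e-14)
  }
  expect_error(node_force_operator(msgs, c(1, 2), c(1, 0)), "strictly positive")
})

test_that("the potential-mode operator differentiates the message sum exactly", {
  traj <- make_spring_traj(n = 5, steps = 12, seed = 4)
  ft <- with_fd_kinematics(traj)
  gs <- graph_sample(ft, 5)

  # constant network: derivative of a constant is zero
  m0 <- small_model("potential")
  m0$edge$W <- lapply(m0$edge$W, function(w) w * 0)
  expect_equal(node_potential_operator(m0, gs), matrix(0, 5, 2))

  # closed-form spring potential: operator equals analytic net force / mass
  cf <- closed_form_model(system_spec("spring"), "potential")
  acc <- node_potential_operator(cf, gs)
  truth <- t(vapply(1:5, function(i) {
    f <- numeric(2)
    for (j in setdiff(1:5, i))
      f <- f + pairwise_force(cf$spec, gs$eta[i, 1:2], gs$eta[j, 1:2])
    f / gs$masses[i]
  }, numeric(2)))
  expect_equal(acc, truth, tolerance = 1e-6)

  # random small networks: exact tangents match central finite differences
  for (s in 1:3) {
    m <- small_model("potential", seed = s + 10)
    G <- pignpi:::.message_position_gradient(m, gs)
    Gfd <- pignpi:::.fd_message_grad(m, gs, h = 1e-5)
    expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-4)
  }
})

test_that("extracted interactions re-aggregate to the model's accelerations", {
  traj <- make_spring_traj(n = 4, steps = 12, seed = 5)
  ft <- with_fd_kinematics(traj)
  gs <- graph_sample(ft, 2)

  mf <- small_model("force", seed = 6)
  exf <- extract_interactions(mf, gs)
  expect_equal(exf$force, edge_messages(mf, gs))
  accf <- node_force_operator(exf$force, gs$edges[, 1], gs$masses)
  dsf <- pignpi:::.graph_dataset(ft)
  b <- pignpi:::.batch_of(dsf, 2L)
  res <- pignpi:::.variant_batch(list(edge = mf$edge), mf, b, dsf, 0, FALSE)
  expect_equal(accf, res$accel, tolerance = 1e-10, ignore_attr = TRUE)

  mp <- small_model("potential", seed = 7)
  exp_ <- extract_interactions(mp, gs)
  accp <- node_force_operator(exp_$force, gs$edges[, 1], gs$masses)
  expect_equal(accp, node_potential_operator(mp, gs), tolerance = 1e-10)

  # gauge invariance: a constant added to every potential message leaves
  # forces and accelerations unchanged
  mshift <- mp
  mshift$edge$b[[length(mshift$edge$b)]] <-
    mshift$edge$b[[length(mshift$edge$b)]] + 17.3
  expect_equal(edge_messages(mshift, gs), edge_messages(mp, gs) + 17.3)
  expect_equal(extract_interactions(mshift, gs)$force, exp_$force)
  expect_equal(node_potential_operator(mshift, gs),
               node_potential_operator(mp, gs))

  # closed-form spring potential: extracted forces equal k (r - L) n
  cf <- closed_form_model(system_spec("spring"), "potential")
  excf <- extract_interactions(cf, gs)
  law <- t(vapply(seq_len(nrow(gs$edges)), function(e)
    pairwise_force(cf$spec, gs$eta[gs$edges[e, 1], 1:2],
                   gs$eta[gs$edges[e, 2], 1:2]), numeric(2)))
  expect_equal(excf$force, law, tolerance = 1e-6)
})

test_that("force mode is linear in the messages", {
  traj <- make_spring_traj(n = 4, steps = 10, seed = 8)
  ft <- with_fd_kinematics(traj)
  gs <- graph_sample(ft, 3)
  m <- small_model("force", seed = 9)
  M <- edge_messages(m, gs)
  a1 <- node_force_operator(M, gs$edges[, 1], gs$masses)
  a2 <- node_force_operator(2 * M, gs$edges[, 1], gs$masses)
  expect_equal(a2, 2 * a1)
})

test_that("potential mode rejects activations without smooth derivatives", {
  lay <- feature_layout(2)
  expect_error(pignpi_model("potential", lay, activation = "relu"),
               "differentiable")
  expect_silent(pignpi_model("force", lay, activation = "relu",
                             hidden_layers = 1, hidden_units = 4))
})

test_that("the whole model has no trainable node parameters", {
  m <- small_model("force")
  expect_null(m$node)
  expect_null(m$w)
  np <- length(pignpi:::.flatten_params(list(edge = m$edge)))
  expect_equal(np, sum(lengths(m$edge$W)) + sum(lengths(m$edge$b)))
})
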