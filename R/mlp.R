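# Edge/node multilayer perceptrons: seeded fan-in initialisation, parameter
# flattening for the optimizer, and the Adam update. The numerical heavy
# lifting (forward, tangents, backward) lives in src/edgenet.cpp.

.act_codes <- c(silu = 0L, tanh = 1L, relu = 2L, leaky_relu = 3L)

.act_code <- function(name) {
  code <- .act_codes[match.arg(name, names(.act_codes))]
  unname(code)
}

# smooth activations admit the second derivative the potential-mode
# backward pass needs
.act_smooth <- function(name) name %in% c("silu", "tanh")

# Fan-in-scaled uniform initialisation, U(-1/sqrt(in), 1/sqrt(in)) for both
# weights and biases. Caller controls the RNG state.
.init_mlp <- function(in_dim, out_dim, hidden_layers = 4, hidden_units = 300) {
  dims <- c(in_dim, rep(hidden_units, hidden_layers), out_dim)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    bound <- 1 / sqrt(dims[l])
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -bound, bound),
                     dims[l], dims[l + 1L])
    b[[l]] <- runif(dims[l + 1L], -bound, bound)
  }
  list(W = W, b = b)
}

# Flatten a named list of nets (each list(W=, b=)) plus optional extra
# numeric vectors into one parameter vector, with a skeleton to invert.
.flatten_params <- function(parts) {
  unlist(lapply(parts, function(p) {
    if (is.list(p)) c(unlist(p$W), unlist(p$b)) else p
  }), use.names = FALSE)
}

.unflatten_params <- function(theta, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    p <- skeleton[[nm]]
    if (is.list(p)) {
      for (l in seq_along(p$W)) {
        k <- length(p$W[[l]])
        out[[nm]]$W[[l]][] <- theta[pos + seq_len(k)]
        pos <- pos + k
      }
      for (l in seq_along(p$b)) {
        k <- length(p$b[[l]])
        out[[nm]]$b[[l]][] <- theta[pos + seq_len(k)]
        pos <- pos + k
      }
    } else {
      k <- length(p)
      out[[nm]][] <- theta[pos + seq_len(k)]
      pos <- pos + k
    }
  }
  out
}

# One Adam step; state holds first/second moments and the step counter.
.adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)
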