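# Minimal feed-forward machinery used by the model: tanh MLPs with
# hand-written backpropagation, and Adam over nested lists of arrays.
# Smooth activations keep the single-cell refit objective amenable to
# quasi-Newton optimization.

mlp_init <- function(d_in, d_out, depth = 2L, width = 256L) {
  depth <- as.integer(depth)
  dims <- if (depth == 0L) c(d_in, d_out) else c(d_in, rep(width, depth), d_out)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * dims[l + 1L], sd = sqrt(1 / fan_in)), fan_in, dims[l + 1L]),
      b = rep(0, dims[l + 1L])
    )
  }
  layers
}

# Forward pass. Hidden layers use tanh; the output layer is affine unless
# activate_last = TRUE (used for the decoder trunk, whose output feeds the
# distribution heads). Returns the output and, when cache = TRUE, the
# per-layer inputs needed by mlp_backward.
mlp_forward <- function(net, X, cache = FALSE, activate_last = FALSE) {
  L <- length(net)
  inputs <- if (cache) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    if (cache) inputs[[l]] <- H
    A <- H %*% net[[l]]$W
    A <- sweep(A, 2L, net[[l]]$b, `+`)
    H <- if (l < L || activate_last) tanh(A) else A
  }
  if (cache) list(out = H, inputs = inputs) else H
}

# Backward pass given d(loss)/d(output). Returns gradients in the same
# structure as the parameters plus the gradient with respect to the input.
mlp_backward <- function(net, fwd, dOut, activate_last = FALSE) {
  L <- length(net)
  grads <- vector("list", L)
  dA <- if (activate_last) dOut * (1 - fwd$out^2) else dOut
  for (l in rev(seq_len(L))) {
    H_in <- fwd$inputs[[l]]
    grads[[l]] <- list(W = crossprod(H_in, dA), b = colSums(dA))
    dH <- dA %*% t(net[[l]]$W)
    if (l > 1L) {
      # derivative of tanh at the *output* of layer l-1: 1 - h^2
      dA <- dH * (1 - H_in^2)  # inputs[[l]] is the activated output of l-1
    } else {
      dA <- dH
    }
  }
  list(grads = grads, dX = dA)
}

is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree) {
  if (is_param_leaf(tree)) return(f(tree))
  lapply(tree, tree_map, f = f)
}

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
  out
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_apply <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m_new <- beta1 * m + (1 - beta1) * g
  v_new <- beta2 * v + (1 - beta2) * g^2
  m_hat <- m_new / (1 - beta1^t)
  v_hat <- v_new / (1 - beta2^t)
  list(p = p - lr * m_hat / (sqrt(v_hat) + eps), m = m_new, v = v_new)
}

# One Adam step over a whole parameter tree. `lr` is a scalar or a named
# list keyed by top-level parameter names (directly-optimized embeddings
# typically take a larger rate than network weights).
adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  step_rec <- function(p, g, m, v, rate) {
    if (is_param_leaf(p)) {
      return(adam_apply(p, g, m, v, rate, opt$t))
    }
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- if (is.list(rate)) {
        nm <- names(p)[i]
        if (!is.null(nm) && !is.null(rate[[nm]])) rate[[nm]] else rate[["default"]]
      } else {
        rate
      }
      res <- step_rec(p[[i]], g[[i]], m[[i]], v[[i]], r)
      out_p[[i]] <- res$p; out_m[[i]] <- res$m; out_v[[i]] <- res$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  res <- step_rec(params, grads, opt$m, opt$v, lr)
  list(params = res$p, opt = list(m = res$m, v = res$v, t = opt$t))
}

row_softmax <- function(O) {
  mx <- apply(O, 1L, max)
  E <- exp(O - mx)
  E / rowSums(E)
}
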