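# Minimal dense / 1D-convolution neural-network engine with hand-written
# backpropagation and Adam. All parameters are nested lists of numeric
# arrays; gradients mirror the parameter structure exactly.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# derivative mask from the *post*-activation (relu(z) > 0 <=> z > 0)
relu_mask <- function(h) (h > 0) * 1

apply_act <- function(z, act) {
  switch(act,
    relu = relu(z),
    identity = z,
    tanh = tanh(z),
    stop("unknown activation: ", act)
  )
}

act_backward <- function(dh, h, act) {
  switch(act,
    relu = dh * relu_mask(h),
    identity = dh,
    tanh = dh * (1 - h^2),
    stop("unknown activation: ", act)
  )
}

# He-scaled Gaussian init; draws from the current RNG stream
nn_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

## ---- multilayer perceptron -------------------------------------------------

# sizes = c(n_in, h1, ..., n_out)
mlp_init <- function(sizes, zero_last = FALSE) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- nn_mat(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  if (zero_last) W[[L]][] <- 0
  list(W = W, b = b)
}

# X: n x n_in. Hidden layers use `act`, final layer `out_act`.
# Returns list(out, H) where H[[1]] = X and H[[l+1]] is layer l's output.
mlp_forward <- function(par, X, act = "relu", out_act = "identity") {
  L <- length(par$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- H[[l]] %*% par$W[[l]]
    Z <- Z + rep(par$b[[l]], each = nrow(Z))
    H[[l + 1L]] <- apply_act(Z, if (l < L) act else out_act)
  }
  list(out = H[[L + 1L]], H = H)
}

# dOut: gradient wrt the network output. Returns gradients and dX.
mlp_backward <- function(par, fw, dOut, act = "relu", out_act = "identity") {
  L <- length(par$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- act_backward(dH, fw$H[[l + 1L]], if (l < L) act else out_act)
    gW[[l]] <- crossprod(fw$H[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dH <- dZ %*% t(par$W[[l]])
  }
  list(grads = list(W = gW, b = gb), dX = dH)
}

## ---- 1D convolution over embedded token sequences --------------------------

# X: L x C input; returns (L-k+1) x (k*C) patch matrix whose column blocks
# are the k within-window offsets (matching the conv weight layout).
conv_patches <- function(X, k) {
  Lout <- nrow(X) - k + 1L
  do.call(cbind, lapply(0:(k - 1L), function(j) X[(1L + j):(Lout + j), , drop = FALSE]))
}

# scatter-add patch gradients back onto the input
conv_patches_backward <- function(dP, k, L, C) {
  Lout <- L - k + 1L
  dX <- matrix(0, L, C)
  for (j in 0:(k - 1L)) {
    cols <- (j * C + 1L):((j + 1L) * C)
    rows <- (1L + j):(Lout + j)
    dX[rows, ] <- dX[rows, ] + dP[, cols, drop = FALSE]
  }
  dX
}

## ---- Adam ------------------------------------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else {
    z <- p
    z[] <- 0
    z
  }
}

adam_init <- function(par) list(m = zeros_like(par), v = zeros_like(par), t = 0L)

adam_leaf <- function(p, g, m, v, lr, t, beta1, beta2, eps) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_recurse <- function(p, g, m, v, lr, t, beta1, beta2, eps) {
  if (is.list(p)) {
    out <- lapply(seq_along(p), function(i) {
      adam_recurse(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, beta1, beta2, eps)
    })
    list(
      p = stats::setNames(lapply(out, `[[`, "p"), names(p)),
      m = stats::setNames(lapply(out, `[[`, "m"), names(p)),
      v = stats::setNames(lapply(out, `[[`, "v"), names(p))
    )
  } else {
    adam_leaf(p, g, m, v, lr, t, beta1, beta2, eps)
  }
}

# One Adam step over a nested parameter list; returns updated par + state.
adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  out <- adam_recurse(par, grads, state$m, state$v, lr, state$t, beta1, beta2, eps)
  list(par = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

## ---- RNG scoping -----------------------------------------------------------

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
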