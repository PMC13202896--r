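# Minimal neural-network core: forward and analytic backward passes for the
# building blocks of the fusion network (affine maps, multi-head
# self-attention with residual connections, position-wise feed-forward
# blocks, learned-query attention pooling, the gating MLP) plus a flat-vector
# Adam optimizer. Backward passes are verified against numerical gradients
# in the test suite.

lin <- function(X, W, b) X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)

nn_mat <- function(nin, nout, sd) matrix(stats::rnorm(nin * nout, sd = sd), nin, nout)

attn_layer_init <- function(d, ffn_mult = 2L) {
  f <- d * ffn_mult
  s <- 1 / sqrt(d)
  # residual-branch outputs (Wo, W2) start small so each block is
  # near-identity at initialization; this keeps deep stacks stable without
  # normalization layers and keeps refined vectors close to their inputs
  # early in training
  list(Wq = nn_mat(d, d, s), bq = numeric(d),
       Wk = nn_mat(d, d, s), bk = numeric(d),
       Wv = nn_mat(d, d, s), bv = numeric(d),
       Wo = nn_mat(d, d, 0.1 * s), bo = numeric(d),
       W1 = nn_mat(d, f, s), b1 = numeric(f),
       W2 = nn_mat(f, d, 0.1 / sqrt(f)), b2 = numeric(d))
}

# One pre-activation Transformer block: multi-head self-attention with a
# residual connection, then a ReLU feed-forward block with a residual.
attn_layer_forward <- function(X, p, n_heads) {
  n <- nrow(X); d <- ncol(X)
  dh <- d %/% n_heads
  Q <- lin(X, p$Wq, p$bq); K <- lin(X, p$Wk, p$bk); V <- lin(X, p$Wv, p$bv)
  O <- matrix(0, n, d)
  A_list <- vector("list", n_heads)
  for (m in seq_len(n_heads)) {
    idx <- ((m - 1L) * dh + 1L):(m * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(S)
    A_list[[m]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  attn_out <- lin(O, p$Wo, p$bo)
  X1 <- X + attn_out
  Hpre <- lin(X1, p$W1, p$b1)
  Hact <- relu(Hpre)
  X2 <- X1 + lin(Hact, p$W2, p$b2)
  list(out = X2, attn = A_list,
       cache = list(X = X, Q = Q, K = K, V = V, A = A_list, O = O,
                    X1 = X1, Hpre = Hpre, Hact = Hact))
}

attn_layer_backward <- function(dX2, cache, p, n_heads) {
  d <- ncol(dX2)
  dh <- d %/% n_heads
  # FFN residual branch
  dW2 <- t(cache$Hact) %*% dX2
  db2 <- colSums(dX2)
  dHpre <- (dX2 %*% t(p$W2)) * (cache$Hpre > 0)
  dW1 <- t(cache$X1) %*% dHpre
  db1 <- colSums(dHpre)
  dX1 <- dX2 + dHpre %*% t(p$W1)
  # attention residual branch
  dWo <- t(cache$O) %*% dX1
  dbo <- colSums(dX1)
  dO <- dX1 %*% t(p$Wo)
  n <- nrow(dX2)
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (m in seq_len(n_heads)) {
    idx <- ((m - 1L) * dh + 1L):(m * dh)
    A <- cache$A[[m]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  X <- cache$X
  dX <- dX1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = t(X) %*% dQ, bq = colSums(dQ),
                Wk = t(X) %*% dK, bk = colSums(dK),
                Wv = t(X) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo,
                W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  list(dX = dX, grads = grads)
}

# Learned-query attention pooling: alpha = softmax(H q), z = H' alpha.
pool_forward <- function(H, q) {
  logits <- as.vector(H %*% q)
  alpha <- softmax(logits)
  z <- as.vector(crossprod(H, alpha))
  list(alpha = alpha, z = z, cache = list(H = H, alpha = alpha))
}

pool_backward <- function(dz, cache, q) {
  H <- cache$H; alpha <- cache$alpha
  dH <- alpha %o% dz
  dalpha <- as.vector(H %*% dz)
  dlog <- alpha * (dalpha - sum(dalpha * alpha))
  dq <- as.vector(crossprod(H, dlog))
  dH <- dH + dlog %o% q
  list(dH = dH, dq = dq)
}

gate_init <- function(G, d, hidden) {
  list(W1 = nn_mat(G * d, hidden, 1 / sqrt(G * d)), b1 = numeric(hidden),
       W2 = nn_mat(hidden, G, 1 / sqrt(hidden)), b2 = numeric(G))
}

# Gating MLP consumes the refined group vectors jointly (row-major flatten
# of the G x d matrix) and emits one score per group.
gate_forward <- function(Zt, p) {
  v <- as.vector(t(Zt))
  hpre <- as.vector(v %*% p$W1) + p$b1
  h <- relu(hpre)
  s <- as.vector(h %*% p$W2) + p$b2
  list(s = s, cache = list(v = v, hpre = hpre, h = h))
}

gate_backward <- function(ds, cache, p, G, d) {
  dW2 <- cache$h %o% ds
  db2 <- ds
  dhpre <- as.vector(p$W2 %*% ds) * (cache$hpre > 0)
  dW1 <- cache$v %o% dhpre
  db1 <- dhpre
  dv <- as.vector(p$W1 %*% dhpre)
  list(dZt = matrix(dv, G, d, byrow = TRUE),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Flatten a nested parameter list to one numeric vector and back. The
# skeleton fixes the traversal order, so gradients accumulated flat stay
# aligned with their parameters.
nn_flatten <- function(params) unlist(params, use.names = FALSE)

nn_unflatten <- function(flat, skeleton) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(v) <- dim(s)
    v
  }
  rec(skeleton)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
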