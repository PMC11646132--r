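# Internal neural-network primitives.
#
# Feature maps are numeric arrays of dim (channels, positions, batch); conv
# weights are (C_out, C_in * k) matrices with the input channel running
# fastest along the column index (see src/kernels.cpp).  All forward helpers
# return plain arrays; backward helpers return gradients of the same shapes.

conv1d <- function(X, W, b, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  .conv1d_fwd(X, W, b, as.integer(k), as.integer(pad), as.integer(stride))
}

conv1d_grad <- function(X, W, dY, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  bk <- .conv1d_bwd(X, W, dY, as.integer(k), as.integer(pad),
                    as.integer(stride))
  bk$db <- as.vector(bk$db)
  bk
}

maxpool1d <- function(X, k, pad = 1L, stride = 1L) {
  .maxpool1d_fwd(X, as.integer(k), as.integer(pad), as.integer(stride))
}

maxpool1d_grad <- function(dY, argmax, dims) {
  .maxpool1d_bwd(dY, argmax, dims[1L], dims[2L], dims[3L])
}

relu <- function(X) {
  if (is.array(X) && length(dim(X)) == 3L) .relu_cpp(X) else X * (X > 0)
}
relu_grad <- function(dY, Y) {
  if (is.array(dY) && length(dim(dY)) == 3L) .relu_grad_cpp(dY, Y)
  else dY * (Y > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over the positions axis of a (C, L, N) cube, per channel & sample
softmax_positions <- function(A) {
  d <- dim(A)
  M <- matrix(aperm(A, c(2L, 1L, 3L)), nrow = d[2L])   # L x (C*N)
  M <- exp(sweep(M, 2L, apply(M, 2L, max)))
  M <- sweep(M, 2L, colSums(M), "/")
  aperm(array(M, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
}

# backward of softmax_positions: dA = S * (dS - sum_L(dS * S))
softmax_positions_grad <- function(dS, S) {
  d <- dim(S)
  # sums over positions, per (channel, sample)
  sums <- colSums(array(aperm(dS * S, c(2L, 1L, 3L)),
                        c(d[2L], d[1L] * d[3L])))       # length C*N
  sums <- array(rep(sums, each = d[2L]), c(d[2L], d[1L], d[3L]))
  S * (dS - aperm(sums, c(2L, 1L, 3L)))
}

# softmax over the channel axis (alternative spatial-attention reading)
softmax_channels <- function(A) {
  d <- dim(A)
  M <- matrix(A, nrow = d[1L])                          # C x (L*N)
  M <- exp(sweep(M, 2L, apply(M, 2L, max)))
  M <- sweep(M, 2L, colSums(M), "/")
  array(M, d)
}

softmax_channels_grad <- function(dS, S) {
  d <- dim(S)
  sums <- colSums(matrix(dS * S, nrow = d[1L]))         # length L*N
  S * (dS - array(rep(sums, each = d[1L]), d))
}

# broadcast a (C, N) matrix over the positions axis of a (C, L, N) cube
broadcast_cl <- function(M, L) {
  d <- dim(M)
  aperm(array(rep(M, times = L), c(d[1L], d[2L], L)), c(1L, 3L, 2L))
}

# sum a (C, L, N) cube over positions -> (C, N) matrix
sum_positions <- function(A) {
  colSums(aperm(A, c(2L, 1L, 3L)), dims = 1L)
}

mean_positions <- function(A) sum_positions(A) / dim(A)[2L]

concat_channels <- function(maps) {
  d <- dim(maps[[1L]])
  Cs <- vapply(maps, function(m) dim(m)[1L], integer(1))
  out <- array(0, c(sum(Cs), d[2L], d[3L]))
  at <- 0L
  for (m in maps) {
    cm <- dim(m)[1L]
    out[(at + 1L):(at + cm), , ] <- m
    at <- at + cm
  }
  out
}

split_channels <- function(A, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- A[(at + 1L):(at + sizes[i]), , , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# ---- parameter initialisation ------------------------------------------

# He-normal fan-in initialisation for a conv weight (C_out, C_in * k)
init_conv <- function(C_out, C_in, k, gain = sqrt(2)) {
  fan_in <- C_in * k
  W <- matrix(rnorm(C_out * C_in * k, sd = gain / sqrt(fan_in)),
              nrow = C_out)
  list(W = W, b = numeric(C_out))
}

init_dense <- function(n_out, n_in) {
  W <- matrix(rnorm(n_out * n_in, sd = sqrt(1 / n_in)), nrow = n_out)
  list(W = W, b = numeric(n_out))
}

# embedding table: vocab x embed_dim; row 1 (padding code 0) fixed at zero
init_embedding <- function(vocab, embed_dim) {
  E <- matrix(rnorm(vocab * embed_dim, sd = 0.1), nrow = vocab)
  E[1L, ] <- 0
  E
}

# gather rows of the embedding table: codes is an L x N integer matrix
embed_forward <- function(codes, table) {
  d <- dim(codes)
  E <- t(table[as.vector(codes) + 1L, , drop = FALSE])  # embed_dim x (L*N)
  array(E, c(ncol(table), d[1L], d[2L]))
}

# scatter-add the gradient into the table; padding row stays zero
embed_backward <- function(dE, codes, vocab) {
  d <- dim(dE)
  G <- matrix(dE, nrow = d[1L])                          # embed_dim x (L*N)
  f <- as.vector(codes)
  dT <- matrix(0, nrow = vocab, ncol = d[1L])
  for (v in seq_len(vocab - 1L)) {
    sel <- which(f == v)
    if (length(sel))
      dT[v + 1L, ] <- rowSums(G[, sel, drop = FALSE])
  }
  dT
}

# ---- Adam optimiser -----------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
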