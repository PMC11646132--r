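# Explicit-loop reference implementations used as independent oracles, plus
# small shared fixtures.  The oracles deliberately share no code with the
# package internals.

# cross-correlation conv: X (Cin, L, N), W (Cout, Cin*k) with channel
# fastest along columns, zero padding, given stride
oracle_conv1d <- function(X, W, b, k, pad, stride = 1L) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; N <- d[3]; Cout <- nrow(W)
  Lout <- (L + 2 * pad - k) %/% stride + 1
  Y <- array(0, c(Cout, Lout, N))
  for (n in seq_len(N))
    for (j in seq_len(Lout))
      for (o in seq_len(Cout)) {
        acc <- b[o]
        for (t in seq_len(k)) {
          p <- (j - 1) * stride - pad + t       # 1-based input position
          if (p >= 1 && p <= L)
            for (c in seq_len(Cin))
              acc <- acc + W[o, c + Cin * (t - 1)] * X[c, p, n]
        }
        Y[o, j, n] <- acc
      }
  Y
}

oracle_maxpool1d <- function(X, k, pad, stride) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  Lout <- (L + 2 * pad - k) %/% stride + 1
  Y <- array(0, c(C, Lout, N))
  for (n in seq_len(N))
    for (j in seq_len(Lout))
      for (c in seq_len(C)) {
        best <- -Inf
        for (t in seq_len(k)) {
          p <- (j - 1) * stride - pad + t
          if (p >= 1 && p <= L && X[c, p, n] > best) best <- X[c, p, n]
        }
        Y[c, j, n] <- best
      }
  Y
}

# global channel attention: mean over positions, 1-channel conv across the
# channel axis (kernel kad, symmetric zero pad), sigmoid, broadcast multiply
oracle_global_fusion <- function(MK, w, b, kad) {
  d <- dim(MK); C <- d[1]; L <- d[2]; N <- d[3]
  half <- (kad - 1) %/% 2
  GF <- array(0, dim(MK)); GW <- matrix(0, C, N)
  for (n in seq_len(N)) {
    a <- sapply(seq_len(C), function(c) mean(MK[c, , n]))
    for (c in seq_len(C)) {
      acc <- b
      for (t in seq_len(kad)) {
        p <- c - half + (t - 1)
        if (p >= 1 && p <= C) acc <- acc + w[t] * a[p]
      }
      GW[c, n] <- 1 / (1 + exp(-acc))
      GF[c, , n] <- MK[c, , n] * GW[c, n]
    }
  }
  list(weight = GW, fea = GF)
}

# local spatial attention: squeeze conv (C -> C/r), excitation conv
# (C/r -> C), softmax over positions per channel, elementwise multiply
oracle_local_fusion <- function(MK, sqW, sqb, exW, exb, kad) {
  s <- oracle_conv1d(MK, sqW, sqb, kad, (kad - 1) %/% 2)
  e <- oracle_conv1d(s, exW, exb, kad, (kad - 1) %/% 2)
  d <- dim(e)
  lw <- array(0, d)
  for (n in seq_len(d[3]))
    for (c in seq_len(d[1])) {
      z <- exp(e[c, , n] - max(e[c, , n]))
      lw[c, , n] <- z / sum(z)
    }
  list(weight = lw, fea = MK * lw)
}

# pairwise-comparison AUC (probability a positive outranks a negative,
# ties counted one half)
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force mean silhouette with Euclidean distance
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ---- shared fixtures ----------------------------------------------------

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(L_max = 12L, embed_dim = 3L, out_channel = 8L,
         reduction_ratio = 4L, n_dr_blocks = 2L, batch_size = 4L,
         seed = 42L),
    list(...))
  do.call(m6a_config, args)
}

# a generic parameter point: zero biases leave padding-region
# pre-activations exactly at the ReLU kink, so nudge everything
randomize_params <- function(model, sd = 0.05, seed = 99L) {
  set.seed(seed)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    model$params[[nm]] <- p + rnorm(length(p), sd = sd)
    dim(model$params[[nm]]) <- dim(p)
  }
  model$params$embed[1L, ] <- 0
  model
}

tiny_records <- function(n_pos = 3L, n_neg = 3L, seed = 11L,
                         len = c(6L, 12L)) {
  generate_dataset(synthetic_spec(n_pos, n_neg, length_range = len,
                                  seed = seed))
}

ns <- asNamespace("m6afuse")
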