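#' @title Downsampling residual feature embedding (DRFE)
#'
#' @description
#' Compresses the fused feature map along the positions axis: an equal-length
#' two-convolution stem (kernel 5, symmetric padding 2) followed by a stack
#' of downsampling residual (DR) blocks.  Each DR block halves the positions
#' axis with a strided kernel-3 max-pool and adds the pooled map back onto an
#' equal-length double convolution of itself.  A margin-based contrastive
#' loss on the flattened embeddings pulls same-class samples together and
#' pushes different-class samples beyond the margin.
#'
#' @name drfe
NULL

#' Equal-length convolutional stem
#'
#' Two kernel-5 convolutions with symmetric padding 2 (each followed by
#' ReLU); channels and positions are unchanged.
#'
#' @param o_mkff feature map at stage `O_MKFF`.
#' @param config an [m6a_config()].
#' @param params model parameter list.
#' @return feature map at stage `stem`.
#' @export
stem_forward <- function(o_mkff, config, params) {
  fw <- stem_forward_cache(o_mkff, params)
  feature_map(fw$S2, "stem")
}

stem_forward_cache <- function(X, p) {
  S1 <- relu(conv1d(X, p$stem1.W, p$stem1.b, 5L, 2L))
  S2 <- relu(conv1d(S1, p$stem2.W, p$stem2.b, 5L, 2L))
  list(S1 = S1, S2 = S2)
}

stem_backward <- function(dS2, X, fw, p, g, prefix = "stem") {
  d2 <- relu_grad(dS2, fw$S2)
  bk2 <- conv1d_grad(fw$S1, p$stem2.W, d2, 5L, 2L)
  g[[paste0(prefix, "2.W")]] <- bk2$dW
  g[[paste0(prefix, "2.b")]] <- bk2$db
  d1 <- relu_grad(bk2$dX, fw$S1)
  bk1 <- conv1d_grad(X, p$stem1.W, d1, 5L, 2L)
  g[[paste0(prefix, "1.W")]] <- bk1$dW
  g[[paste0(prefix, "1.b")]] <- bk1$db
  list(dX = bk1$dX, g = g)
}

#' One downsampling residual block
#'
#' Max-pool (kernel 3, pad 1, stride `dr_pool_stride`) followed by two
#' equal-length kernel-5 convolutions (ReLU after each) whose output is
#' added back onto the pooled map.  The positions axis shrinks from `L` to
#' `floor((L + 2 - 3)/stride) + 1`.
#'
#' @param x input feature map.
#' @param block 1-based block index selecting the parameter set.
#' @inheritParams stem_forward
#' @return downsampled feature map.
#' @export
dr_block <- function(x, config, params, block = 1L) {
  fw <- dr_block_forward(x, config, params, block)
  feature_map(fw$out, "X_DRFE")
}

dr_block_forward <- function(X, cfg, p, i) {
  if (dim(X)[2L] < cfg$pool_kernel)
    stop("positions axis (", dim(X)[2L], ") shorter than the pool kernel; ",
         "reduce n_dr_blocks")
  mp <- maxpool1d(X, cfg$pool_kernel, pad = 1L, stride = cfg$dr_pool_stride)
  a <- p[[paste0("dr", i, "a.W")]]
  ab <- p[[paste0("dr", i, "a.b")]]
  b <- p[[paste0("dr", i, "b.W")]]
  bb <- p[[paste0("dr", i, "b.b")]]
  C1 <- relu(conv1d(mp$Y, a, ab, 5L, 2L))
  C2 <- relu(conv1d(C1, b, bb, 5L, 2L))
  list(Xdown = mp$Y, argmax = mp$argmax, C1 = C1, C2 = C2,
       out = C2 + mp$Y, in_dim = dim(X))
}

dr_block_backward <- function(dOut, fw, cfg, p, g, i) {
  dXdown <- dOut                                   # residual branch
  d2 <- relu_grad(dOut, fw$C2)
  bkb <- conv1d_grad(fw$C1, p[[paste0("dr", i, "b.W")]], d2, 5L, 2L)
  g[[paste0("dr", i, "b.W")]] <- bkb$dW
  g[[paste0("dr", i, "b.b")]] <- bkb$db
  d1 <- relu_grad(bkb$dX, fw$C1)
  bka <- conv1d_grad(fw$Xdown, p[[paste0("dr", i, "a.W")]], d1, 5L, 2L)
  g[[paste0("dr", i, "a.W")]] <- bka$dW
  g[[paste0("dr", i, "a.b")]] <- bka$db
  dXdown <- dXdown + bka$dX
  dX <- maxpool1d_grad(dXdown, fw$argmax, fw$in_dim)
  list(dX = dX, g = g)
}

#' Run the full DRFE module
#'
#' Stem followed by `config$n_dr_blocks` sequential DR blocks
#' (`n_dr_blocks = 0` returns the stem output, the no-DRFE ablation keeps
#' the module out entirely).
#'
#' @inheritParams stem_forward
#' @return feature map at stage `X_DRFE`.
#' @export
drfe_forward <- function(o_mkff, config, params) {
  fw <- drfe_forward_cache(o_mkff, config, params)
  feature_map(fw$X, "X_DRFE")
}

drfe_forward_cache <- function(X, cfg, p) {
  stem <- stem_forward_cache(X, p)
  cur <- stem$S2
  blocks <- vector("list", cfg$n_dr_blocks)
  for (i in seq_len(cfg$n_dr_blocks)) {
    blocks[[i]] <- dr_block_forward(cur, cfg, p, i)
    cur <- blocks[[i]]$out
  }
  list(stem = stem, blocks = blocks, X = cur)
}

drfe_backward <- function(dX, X_in, fw, cfg, p) {
  g <- list()
  cur <- dX
  for (i in rev(seq_len(cfg$n_dr_blocks))) {
    bk <- dr_block_backward(cur, fw$blocks[[i]], cfg, p, g, i)
    g <- bk$g
    cur <- bk$dX
  }
  bk <- stem_backward(cur, X_in, fw$stem, p, g)
  list(dX = bk$dX, g = bk$g)
}

#' Margin-based contrastive loss for one pair
#'
#' \deqn{L = \tfrac12\left[(1-K)D^2 + K \max(0, M - D)^2\right]}
#' with `K = 0` for a same-class pair, `K = 1` otherwise, and `D` the
#' Euclidean distance between the flattened embeddings.
#'
#' @param f_i,f_j numeric vectors (flattened embeddings) of equal length.
#' @param same_class TRUE if the two samples share a class.
#' @param M margin (> 0).
#' @return non-negative scalar.
#' @export
contrastive_loss <- function(f_i, f_j, same_class, M) {
  if (length(f_i) != length(f_j))
    stop("embeddings differ in dimension")
  if (M <= 0) stop("margin must be positive")
  D <- sqrt(sum((f_i - f_j)^2))
  if (isTRUE(same_class)) 0.5 * D^2 else 0.5 * max(0, M - D)^2
}

#' Batch contrastive loss over seeded random disjoint pairs
#'
#' Samples are shuffled with `pair_seed`, consecutive samples are paired
#' (an odd leftover is dropped), and the pair losses are averaged.  With
#' `pair_mode = "all"` every unordered pair contributes instead.
#'
#' @param features matrix with one flattened embedding per column.
#' @param labels binary vector, one per column.
#' @param M margin.
#' @param pair_seed integer seed making the pairing deterministic.
#' @param pair_mode `"shuffle"` (default) or `"all"`.
#' @return scalar mean contrastive loss.
#' @export
batch_contrastive <- function(features, labels, M, pair_seed,
                              pair_mode = "shuffle") {
  cl <- batch_contrastive_grad(features, labels, M, pair_seed, pair_mode)
  cl$loss
}

# returns loss and gradient w.r.t. the feature matrix (same shape)
batch_contrastive_grad <- function(F, labels, M, pair_seed,
                                   pair_mode = "shuffle") {
  n <- ncol(F)
  dF <- matrix(0, nrow(F), n)
  if (n < 2L) {
    warning("contrastive loss needs at least two samples; returning 0")
    return(list(loss = 0, dF = dF))
  }
  pairs <- if (identical(pair_mode, "all")) {
    t(utils::combn(n, 2L))
  } else {
    ord <- with_preserved_seed(pair_seed, sample.int(n))
    m <- n %/% 2L
    cbind(ord[seq(1L, 2L * m, by = 2L)], ord[seq(2L, 2L * m, by = 2L)])
  }
  np <- nrow(pairs)
  loss <- 0
  eps <- 1e-12
  for (t in seq_len(np)) {
    i <- pairs[t, 1L]; j <- pairs[t, 2L]
    diff <- F[, i] - F[, j]
    D <- sqrt(sum(diff^2))
    if (labels[i] == labels[j]) {
      loss <- loss + 0.5 * D^2
      dF[, i] <- dF[, i] + diff / np
      dF[, j] <- dF[, j] - diff / np
    } else if (D < M) {
      loss <- loss + 0.5 * (M - D)^2
      scale <- -(M - D) / max(D, eps) / np
      dF[, i] <- dF[, i] + scale * diff
      dF[, j] <- dF[, j] - scale * diff
    }
  }
  list(loss = loss / np, dF = dF)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
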