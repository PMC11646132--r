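#' @title Multi-kernel feature fusion (MKFF)
#'
#' @description
#' The encoded batch is embedded, projected to `out_channel` channels by a
#' point-wise convolution, passed through four parallel feature paths with
#' different receptive fields (kernel sizes 1, 3 and 5, plus a max-pooled
#' point-wise path), concatenated and re-mixed point-wise, and finally fused
#' by a global-local dynamic attention (GLDF): a sigmoid-gated per-channel
#' weight derived by efficient channel attention with adaptive kernel size,
#' and a softmax-normalised per-position weight from a squeeze-excitation
#' bottleneck.  A residual connection adds the projected embedding back onto
#' the fused features.
#'
#' All operations preserve the positions axis (`L_max`).
#'
#' @name mkff
NULL

feature_map <- function(values, stage) {
  attr(values, "stage") <- stage
  values
}

#' Stage tag of a feature map
#' @param x a feature map array.
#' @return the stage name, e.g. `"O_embed"` or `"MK_Fea"`.
#' @export
fm_stage <- function(x) attr(x, "stage")

path_channels <- function(cfg) cfg$out_channel %/% 4L

#' Embed and project an encoded batch
#'
#' Gathers the learned embedding vector of each integer code (the padding
#' code 0 maps to a fixed all-zero vector) and applies a point-wise
#' convolution taking `embed_dim` to `out_channel` channels.
#'
#' @param batch an `m6a_batch` from [batch_encode()].
#' @param config an [m6a_config()].
#' @param params model parameter list (see [build_model()]).
#' @return feature map of dim `(out_channel, L_max, n)`, stage `O_embed`.
#' @export
embed_project <- function(batch, config, params) {
  codes_t <- t(batch$codes)
  if (any(codes_t < 0L | codes_t > config$vocab - 1L))
    stop("encoded batch contains codes outside 0..", config$vocab - 1L)
  E <- embed_forward(codes_t, params$embed)
  O <- conv1d(E, params$epw.W, params$epw.b, 1L, 0L)
  feature_map(O, "O_embed")
}

#' Extract multi-kernel features
#'
#' Four parallel paths over `O_embed`, each producing `out_channel/4`
#' channels at unchanged length: a point-wise convolution (k1), kernel-3 and
#' kernel-5 convolutions behind point-wise bottlenecks (k2, k3), and a
#' point-wise convolution after a length-preserving kernel-3 max-pool (k4).
#' Each convolution is followed by ReLU.
#'
#' @inheritParams embed_project
#' @param o_embed feature map at stage `O_embed`.
#' @return named list of the feature maps selected by `config$kernel_combo`.
#' @export
multi_kernel_extract <- function(o_embed, config, params) {
  cache <- mk_paths_forward(o_embed, config, params)
  cache$maps
}

mk_paths_forward <- function(O, cfg, p) {
  maps <- list()
  cache <- list()
  ks <- cfg$kernel_sizes
  if ("k1" %in% cfg$kernel_combo) {
    maps$k1 <- feature_map(relu(conv1d(O, p$k1.W, p$k1.b, ks[1L])), "k1")
  }
  if ("k2" %in% cfg$kernel_combo) {
    cache$k2a <- relu(conv1d(O, p$k2a.W, p$k2a.b, 1L, 0L))
    maps$k2 <- feature_map(relu(conv1d(cache$k2a, p$k2b.W, p$k2b.b, ks[2L])),
                           "k2")
  }
  if ("k3" %in% cfg$kernel_combo) {
    cache$k3a <- relu(conv1d(O, p$k3a.W, p$k3a.b, 1L, 0L))
    maps$k3 <- feature_map(relu(conv1d(cache$k3a, p$k3b.W, p$k3b.b, ks[3L])),
                           "k3")
  }
  if ("k4" %in% cfg$kernel_combo) {
    mp <- maxpool1d(O, cfg$pool_kernel, pad = 1L, stride = 1L)
    cache$k4p <- mp$Y
    cache$k4_argmax <- mp$argmax
    maps$k4 <- feature_map(relu(conv1d(mp$Y, p$k4.W, p$k4.b, 1L, 0L)), "k4")
  }
  list(maps = maps, cache = cache)
}

#' Concatenate and point-wise fuse the kernel paths
#'
#' @inheritParams embed_project
#' @param k_maps named list of kernel-path feature maps (order k1..k4).
#' @return feature map `MK_Fea` with `out_channel` channels.
#' @export
concat_fuse <- function(k_maps, config, params) {
  lens <- unique(vapply(k_maps, function(m) dim(m)[2L], integer(1)))
  if (length(lens) != 1L)
    stop("kernel-path feature maps differ in length")
  cat_k <- concat_channels(k_maps)
  feature_map(relu(conv1d(cat_k, params$mk.W, params$mk.b, 1L, 0L)), "MK_Fea")
}

#' Global channel dynamic fusion
#'
#' Global average pooling over positions compresses each channel to one
#' value; a 1-D convolution of adaptive kernel size across the channel axis
#' followed by a sigmoid yields per-channel weights in (0,1), which rescale
#' `MK_Fea`.
#'
#' @inheritParams embed_project
#' @param mk_fea feature map at stage `MK_Fea`.
#' @return list with `weight` (`out_channel` x n matrix) and `fea`
#'   (feature map `Global_Fea`).
#' @export
global_channel_fusion <- function(mk_fea, config, params) {
  f <- global_fusion_forward(mk_fea, config, params)
  list(weight = f$gw, fea = feature_map(f$GF, "Global_Fea"))
}

global_fusion_forward <- function(MK, cfg, p) {
  d <- dim(MK)
  a <- mean_positions(MK)                               # C x N
  a3 <- array(a, c(1L, d[1L], d[3L]))
  kad <- adaptive_kernel_size(cfg$out_channel, cfg$gamma, cfg$b)
  z3 <- conv1d(a3, p$eca.W, p$eca.b, kad)
  gw <- matrix(sigmoid(as.vector(z3)), d[1L], d[3L])
  GF <- MK * broadcast_cl(gw, d[2L])
  list(a = a, a3 = a3, gw = gw, GF = GF, kad = kad)
}

#' Local spatial dynamic fusion
#'
#' A squeeze convolution (channels `C -> C/r`) and an excitation convolution
#' (`C/r -> C`), both of adaptive kernel size along the positions axis,
#' produce per-position scores that a softmax (over positions, per channel,
#' by default) turns into spatial attention weights multiplying `MK_Fea`.
#'
#' @inheritParams global_channel_fusion
#' @return list with `weight` (array like `mk_fea`, summing to 1 along the
#'   softmax axis) and `fea` (feature map `Local_Fea`).
#' @export
local_spatial_fusion <- function(mk_fea, config, params) {
  f <- local_fusion_forward(mk_fea, config, params)
  list(weight = f$lw, fea = feature_map(f$LF, "Local_Fea"))
}

local_fusion_forward <- function(MK, cfg, p) {
  kad <- adaptive_kernel_size(cfg$out_channel, cfg$gamma, cfg$b)
  s <- conv1d(MK, p$sq.W, p$sq.b, kad)
  e <- conv1d(s, p$ex.W, p$ex.b, kad)
  lw <- if (identical(cfg$softmax_axis, "channels")) softmax_channels(e)
        else softmax_positions(e)
  LF <- MK * lw
  list(s = s, e = e, lw = lw, LF = LF, kad = kad)
}

#' Combine the fused branches and apply the residual connection
#'
#' The global and local branches are concatenated (or added / used singly,
#' per `config$fusion_mode`), mixed by a point-wise convolution back to
#' `out_channel` channels (`GLDF_Fea`), and added elementwise onto
#' `O_embed`.
#'
#' @inheritParams embed_project
#' @param global_fea,local_fea branch feature maps (either may be NULL
#'   under single-branch fusion modes).
#' @param o_embed the residual input, stage `O_embed`.
#' @return feature map `O_MKFF`.
#' @export
gldf_combine <- function(global_fea, local_fea, o_embed, config, params) {
  G0 <- switch(config$fusion_mode,
    gldf   = concat_channels(list(global_fea, local_fea)),
    add    = global_fea + local_fea,
    global = global_fea,
    local  = local_fea,
    stop("gldf_combine is undefined for fusion_mode = 'cat'"))
  GLDF <- relu(conv1d(G0, params$cmb.W, params$cmb.b, 1L, 0L))
  if (!all(dim(GLDF)[1L] == dim(o_embed)[1L]))
    stop("channel mismatch between GLDF_Fea and O_embed")
  feature_map(unclass(o_embed) + GLDF, "O_MKFF")
}

#' Run the full multi-kernel feature fusion module
#'
#' @inheritParams embed_project
#' @return feature map `O_MKFF` of dim `(out_channel, L_max, n)`.
#' @export
mkff_forward <- function(batch, config, params) {
  fwd <- mkff_forward_cache(t(batch$codes), config, params)
  feature_map(fwd$OM, "O_MKFF")
}

# ---- internal cached forward / backward --------------------------------

mkff_forward_cache <- function(codes_t, cfg, p) {
  E <- embed_forward(codes_t, p$embed)
  O <- conv1d(E, p$epw.W, p$epw.b, 1L, 0L)
  if (!cfg$use_mkff)
    return(list(codes_t = codes_t, E = E, O = O, OM = O))
  paths <- mk_paths_forward(O, cfg, p)
  cat_k <- concat_channels(paths$maps)
  MK <- relu(conv1d(cat_k, p$mk.W, p$mk.b, 1L, 0L))
  out <- list(codes_t = codes_t, E = E, O = O, paths = paths,
              cat_k = cat_k, MK = MK)
  mode <- cfg$fusion_mode
  if (mode == "cat") {
    out$GLDF <- MK
    out$OM <- O + MK
    return(out)
  }
  if (mode %in% c("gldf", "add", "global"))
    out$gf <- global_fusion_forward(MK, cfg, p)
  if (mode %in% c("gldf", "add", "local"))
    out$lf <- local_fusion_forward(MK, cfg, p)
  G0 <- switch(mode,
    gldf   = concat_channels(list(out$gf$GF, out$lf$LF)),
    add    = out$gf$GF + out$lf$LF,
    global = out$gf$GF,
    local  = out$lf$LF)
  out$G0 <- G0
  out$GLDF <- relu(conv1d(G0, p$cmb.W, p$cmb.b, 1L, 0L))
  out$OM <- O + out$GLDF
  out
}

mkff_backward <- function(dOM, fw, cfg, p) {
  g <- list()
  dO <- dOM
  if (!cfg$use_mkff) {
    bk <- conv1d_grad(fw$E, p$epw.W, dO, 1L, 0L)
    g$epw.W <- bk$dW; g$epw.b <- bk$db
    g$embed <- embed_backward(bk$dX, fw$codes_t, cfg$vocab)
    return(g)
  }
  mode <- cfg$fusion_mode
  dGLDF <- dOM
  if (mode == "cat") {
    dMK <- dGLDF
  } else {
    dZ <- relu_grad(dGLDF, fw$GLDF)
    bk <- conv1d_grad(fw$G0, p$cmb.W, dZ, 1L, 0L)
    g$cmb.W <- bk$dW; g$cmb.b <- bk$db
    C <- cfg$out_channel
    dGF <- dLF <- NULL
    if (mode == "gldf") {
      sp <- split_channels(bk$dX, c(C, C))
      dGF <- sp[[1L]]; dLF <- sp[[2L]]
    } else if (mode == "add") {
      dGF <- bk$dX; dLF <- bk$dX
    } else if (mode == "global") dGF <- bk$dX
    else dLF <- bk$dX
    dMK <- array(0, dim(fw$MK))
    if (!is.null(dGF)) {
      gf <- fw$gf
      d <- dim(fw$MK)
      dMK <- dMK + dGF * broadcast_cl(gf$gw, d[2L])
      dgw <- sum_positions(dGF * fw$MK)
      dz <- dgw * gf$gw * (1 - gf$gw)
      dz3 <- array(dz, c(1L, d[1L], d[3L]))
      bk2 <- conv1d_grad(gf$a3, p$eca.W, dz3, gf$kad)
      g$eca.W <- bk2$dW; g$eca.b <- bk2$db
      da <- matrix(bk2$dX, d[1L], d[3L])
      dMK <- dMK + broadcast_cl(da / d[2L], d[2L])
    }
    if (!is.null(dLF)) {
      lf <- fw$lf
      dMK <- dMK + dLF * lf$lw
      dlw <- dLF * fw$MK
      de <- if (identical(cfg$softmax_axis, "channels"))
        softmax_channels_grad(dlw, lf$lw)
      else softmax_positions_grad(dlw, lf$lw)
      bk2 <- conv1d_grad(lf$s, p$ex.W, de, lf$kad)
      g$ex.W <- bk2$dW; g$ex.b <- bk2$db
      bk3 <- conv1d_grad(fw$MK, p$sq.W, bk2$dX, lf$kad)
      g$sq.W <- bk3$dW; g$sq.b <- bk3$db
      dMK <- dMK + bk3$dX
    }
  }
  dMKpre <- relu_grad(dMK, fw$MK)
  bk <- conv1d_grad(fw$cat_k, p$mk.W, dMKpre, 1L, 0L)
  g$mk.W <- bk$dW; g$mk.b <- bk$db
  C4 <- path_channels(cfg)
  maps <- fw$paths$maps
  dparts <- split_channels(bk$dX, rep(C4, length(maps)))
  names(dparts) <- names(maps)
  cache <- fw$paths$cache
  ks <- cfg$kernel_sizes
  if (!is.null(dparts$k1)) {
    d1 <- relu_grad(dparts$k1, maps$k1)
    bk1 <- conv1d_grad(fw$O, p$k1.W, d1, ks[1L])
    g$k1.W <- bk1$dW; g$k1.b <- bk1$db
    dO <- dO + bk1$dX
  }
  if (!is.null(dparts$k2)) {
    d2 <- relu_grad(dparts$k2, maps$k2)
    bkb <- conv1d_grad(cache$k2a, p$k2b.W, d2, ks[2L])
    g$k2b.W <- bkb$dW; g$k2b.b <- bkb$db
    d2a <- relu_grad(bkb$dX, cache$k2a)
    bka <- conv1d_grad(fw$O, p$k2a.W, d2a, 1L, 0L)
    g$k2a.W <- bka$dW; g$k2a.b <- bka$db
    dO <- dO + bka$dX
  }
  if (!is.null(dparts$k3)) {
    d3 <- relu_grad(dparts$k3, maps$k3)
    bkb <- conv1d_grad(cache$k3a, p$k3b.W, d3, ks[3L])
    g$k3b.W <- bkb$dW; g$k3b.b <- bkb$db
    d3a <- relu_grad(bkb$dX, cache$k3a)
    bka <- conv1d_grad(fw$O, p$k3a.W, d3a, 1L, 0L)
    g$k3a.W <- bka$dW; g$k3a.b <- bka$db
    dO <- dO + bka$dX
  }
  if (!is.null(dparts$k4)) {
    d4 <- relu_grad(dparts$k4, maps$k4)
    bk4 <- conv1d_grad(cache$k4p, p$k4.W, d4, 1L, 0L)
    g$k4.W <- bk4$dW; g$k4.b <- bk4$db
    dO <- dO + maxpool1d_grad(bk4$dX, cache$k4_argmax, dim(fw$O))
  }
  bk <- conv1d_grad(fw$E, p$epw.W, dO, 1L, 0L)
  g$epw.W <- bk$dW; g$epw.b <- bk$db
  g$embed <- embed_backward(bk$dX, fw$codes_t, cfg$vocab)
  g
}
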