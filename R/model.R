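#' @title Full network assembly and training objective
#'
#' @description
#' Composes the multi-kernel feature fusion module, the downsampling
#' residual feature embedding module and a single-logit sigmoid head into
#' one classifier; the training objective is binary cross-entropy plus
#' (optionally) the batch contrastive loss,
#' \eqn{L_{total} = L_{cl} + L_{bce}}.
#'
#' @name model
NULL

# flattened embedding width entering the classifier head
head_width <- function(cfg) {
  L <- cfg$L_max
  if (cfg$use_drfe)
    for (i in seq_len(cfg$n_dr_blocks))
      L <- dr_out_length(L, cfg$pool_kernel, cfg$dr_pool_stride)
  cfg$out_channel * L
}

#' Build a model with deterministically initialised weights
#'
#' Weight initialisation is He-normal for ReLU-followed convolutions and
#' scaled-normal elsewhere, fully determined by `init_seed`; the padding
#' code's embedding row is fixed at zero and never updated.
#'
#' @param config an [m6a_config()].
#' @param init_seed integer seed (defaults to `config$seed`).
#' @return object of class `m6a_model` with elements `config`, `params`,
#'   `init_seed` and (after training) `history`.
#' @export
build_model <- function(config, init_seed = config$seed) {
  validate_config(config)
  cfg <- config
  C <- cfg$out_channel
  C4 <- path_channels(cfg)
  kad <- adaptive_kernel_size(C, cfg$gamma, cfg$b)
  ks <- cfg$kernel_sizes
  p <- list()
  with_preserved_seed(init_seed, {
    p$embed <- init_embedding(cfg$vocab, cfg$embed_dim)
    tmp <- init_conv(C, cfg$embed_dim, 1L, gain = 1)
    p$epw.W <- tmp$W; p$epw.b <- tmp$b
    if (cfg$use_mkff) {
      nk <- length(cfg$kernel_combo)
      if ("k1" %in% cfg$kernel_combo) {
        tmp <- init_conv(C4, C, ks[1L]); p$k1.W <- tmp$W; p$k1.b <- tmp$b
      }
      if ("k2" %in% cfg$kernel_combo) {
        tmp <- init_conv(C4, C, 1L);      p$k2a.W <- tmp$W; p$k2a.b <- tmp$b
        tmp <- init_conv(C4, C4, ks[2L]); p$k2b.W <- tmp$W; p$k2b.b <- tmp$b
      }
      if ("k3" %in% cfg$kernel_combo) {
        tmp <- init_conv(C4, C, 1L);      p$k3a.W <- tmp$W; p$k3a.b <- tmp$b
        tmp <- init_conv(C4, C4, ks[3L]); p$k3b.W <- tmp$W; p$k3b.b <- tmp$b
      }
      if ("k4" %in% cfg$kernel_combo) {
        tmp <- init_conv(C4, C, 1L); p$k4.W <- tmp$W; p$k4.b <- tmp$b
      }
      tmp <- init_conv(C, C4 * nk, 1L); p$mk.W <- tmp$W; p$mk.b <- tmp$b
      if (cfg$fusion_mode != "cat") {
        if (cfg$fusion_mode %in% c("gldf", "add", "global")) {
          tmp <- init_conv(1L, 1L, kad, gain = 1)
          p$eca.W <- tmp$W; p$eca.b <- tmp$b
        }
        if (cfg$fusion_mode %in% c("gldf", "add", "local")) {
          Cr <- C %/% cfg$reduction_ratio
          tmp <- init_conv(Cr, C, kad, gain = 1)
          p$sq.W <- tmp$W; p$sq.b <- tmp$b
          tmp <- init_conv(C, Cr, kad, gain = 1)
          p$ex.W <- tmp$W; p$ex.b <- tmp$b
        }
        cin <- if (cfg$fusion_mode == "gldf") 2L * C else C
        tmp <- init_conv(C, cin, 1L); p$cmb.W <- tmp$W; p$cmb.b <- tmp$b
      }
    }
    if (cfg$use_drfe) {
      tmp <- init_conv(C, C, 5L); p$stem1.W <- tmp$W; p$stem1.b <- tmp$b
      tmp <- init_conv(C, C, 5L); p$stem2.W <- tmp$W; p$stem2.b <- tmp$b
      for (i in seq_len(cfg$n_dr_blocks)) {
        tmp <- init_conv(C, C, 5L)
        p[[paste0("dr", i, "a.W")]] <- tmp$W
        p[[paste0("dr", i, "a.b")]] <- tmp$b
        tmp <- init_conv(C, C, 5L)
        p[[paste0("dr", i, "b.W")]] <- tmp$W
        p[[paste0("dr", i, "b.b")]] <- tmp$b
      }
    }
    tmp <- init_dense(1L, head_width(cfg))
    p$head.W <- tmp$W; p$head.b <- tmp$b
  })
  structure(list(config = cfg, params = p, init_seed = as.integer(init_seed),
                 history = NULL),
            class = "m6a_model")
}

#' @export
print.m6a_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("m6a sequence classifier\n",
      "  L_max ", cfg$L_max, ", out_channel ", cfg$out_channel,
      ", embed_dim ", cfg$embed_dim, "\n",
      "  fusion ", if (cfg$use_mkff) cfg$fusion_mode else "(no MKFF)",
      ", DR blocks ", if (cfg$use_drfe) cfg$n_dr_blocks else 0L,
      ", contrastive ", cfg$use_cl, "\n",
      "  parameters: ", format(n_par, big.mark = ","),
      if (!is.null(x$history)) paste0("\n  trained ",
                                      nrow(x$history$epochs), " epochs"),
      "\n", sep = "")
  invisible(x)
}

# full forward pass with caches for the backward pass
model_forward_cache <- function(model, codes) {
  cfg <- model$config
  p <- model$params
  mk <- mkff_forward_cache(t(codes), cfg, p)
  if (cfg$use_drfe) {
    dr <- drfe_forward_cache(mk$OM, cfg, p)
    X <- dr$X
  } else {
    dr <- NULL
    X <- mk$OM
  }
  d <- dim(X)
  Fmat <- matrix(X, nrow = d[1L] * d[2L], ncol = d[3L])
  logit <- as.vector(p$head.W %*% Fmat) + as.numeric(p$head.b)
  yhat <- sigmoid(logit)
  list(mk = mk, dr = dr, X = X, Fmat = Fmat, logit = logit, yhat = yhat)
}

# backward pass: dlogit is the gradient at the pre-sigmoid output, dFextra
# an optional gradient injected at the flattened embedding (contrastive)
model_backward <- function(model, fw, dlogit, dFextra = NULL) {
  cfg <- model$config
  p <- model$params
  g <- list()
  g$head.W <- matrix(fw$Fmat %*% dlogit, nrow = 1L)
  g$head.b <- sum(dlogit)
  dF <- p$head.W[1L, ] %o% dlogit          # (D, N)
  if (!is.null(dFextra)) dF <- dF + dFextra
  dX <- array(dF, dim(fw$X))
  if (cfg$use_drfe) {
    bk <- drfe_backward(dX, fw$mk$OM, fw$dr, cfg, p)
    g <- c(g, bk$g)
    dOM <- bk$dX
  } else {
    dOM <- dX
  }
  g <- c(g, mkff_backward(dOM, fw$mk, cfg, p))
  g
}

#' Predict probabilities from final embeddings
#'
#' Applies the fully connected sigmoid head to the flattened embedding
#' stage.
#'
#' @param x_drfe feature map at the final embedding stage.
#' @param params model parameter list.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(x_drfe, params) {
  d <- dim(x_drfe)
  Fmat <- matrix(x_drfe, nrow = d[1L] * d[2L], ncol = d[3L])
  as.vector(sigmoid(as.vector(params$head.W %*% Fmat) +
                      as.numeric(params$head.b)))
}

#' Binary cross-entropy loss
#'
#' \eqn{-\frac1N \sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]},
#' with probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y_hat predicted probabilities.
#' @param y binary labels.
#' @return scalar loss.
#' @export
bce_loss <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("y_hat and y differ in length")
  eps <- 1e-7
  ph <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(ph) + (1 - y) * log(1 - ph))
}

#' Total training loss
#'
#' Unweighted sum of the binary cross-entropy and the batch contrastive
#' loss on the flattened embeddings; the contrastive term is zero when
#' `config$use_cl` is FALSE.
#'
#' @param y_hat predicted probabilities.
#' @param y binary labels.
#' @param features matrix of flattened embeddings (one column per sample).
#' @param config an [m6a_config()].
#' @param pair_seed seed for the contrastive pairing.
#' @return list with elements `bce`, `cl`, `total`.
#' @export
total_loss <- function(y_hat, y, features, config, pair_seed = 0L) {
  bce <- bce_loss(y_hat, y)
  cl <- if (config$use_cl)
    batch_contrastive(features, y, config$margin, pair_seed,
                      config$pair_mode)
  else 0
  list(bce = bce, cl = cl, total = bce + cl)
}

#' Threshold probabilities into class calls
#'
#' A probability below the threshold is called negative; at or above it,
#' positive (so exactly 0.5 is positive under the default threshold).
#'
#' @param y_hat probabilities.
#' @param threshold decision threshold in (0, 1).
#' @return integer vector of 0/1 labels.
#' @export
classify <- function(y_hat, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  as.integer(y_hat >= threshold)
}

#' Predict on sequence records
#'
#' @param object a trained `m6a_model`.
#' @param records list of [sequence_record()]s (labels ignored).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return data.frame with columns id, probability, label.
#' @export
predict.m6a_model <- function(object, records, batch_size = 64L, ...) {
  cfg <- object$config
  n <- length(records)
  prob <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    ba <- batch_encode(records[idx], cfg$L_max, cfg$padding_side,
                       cfg$truncate)
    fw <- model_forward_cache(object, ba$codes)
    prob[idx] <- fw$yhat
  }
  data.frame(id = vapply(records, `[[`, "", "id"),
             probability = prob,
             label = classify(prob, cfg$threshold))
}
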