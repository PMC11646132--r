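#' @title Gradient saliency, window extraction and embedding export
#'
#' @description
#' The gradient of the predicted probability with respect to the embedding
#' vectors measures the model's sensitivity to each sequence position.  A
#' fixed sliding window over the per-position scores captures
#' high-contribution regions whose subsequences can be exported in FASTA
#' for downstream motif alignment; staged feature embeddings can be
#' exported and scored with the silhouette statistic.
#'
#' @name interpret
NULL

#' Per-position gradient saliency
#'
#' Backpropagates the predicted probability to the embedding layer and
#' aggregates the gradient across embedding dimensions (L2 norm by default,
#' absolute sum with `config$saliency_norm = "abs"`).  Padding positions are
#' excluded: each score vector has the original sequence length.
#'
#' @param model a trained `m6a_model`.
#' @param records one [sequence_record()] or a list of them.
#' @return list of `m6a_saliency` objects, each with `id`, `per_position`,
#'   `probability` and (after [extract_windows()]) `windows`.
#' @export
input_saliency <- function(model, records) {
  if (inherits(records, "m6a_record")) records <- list(records)
  if (is.null(model$params)) stop("model has no parameters loaded")
  cfg <- model$config
  batch <- batch_encode(records, cfg$L_max, cfg$padding_side, cfg$truncate)
  fw <- model_forward_cache(model, batch$codes)
  # d(yhat)/dlogit = yhat (1 - yhat); run the backward pass per batch
  dlogit <- fw$yhat * (1 - fw$yhat)
  dE <- embedding_gradient(model, fw, dlogit)
  n <- length(records)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- batch$lengths[i]
    cols <- (cfg$L_max - len + 1L):cfg$L_max     # non-padding positions
    G <- dE[, cols, i, drop = FALSE]
    score <- if (identical(cfg$saliency_norm, "abs"))
      colSums(abs(array(G, dim(G)[1:2])))
    else sqrt(colSums(array(G, dim(G)[1:2])^2))
    out[[i]] <- structure(list(id = records[[i]]$id,
                               per_position = as.numeric(score),
                               probability = fw$yhat[i],
                               windows = NULL),
                          class = "m6a_saliency")
  }
  out
}

# gradient of sum(dlogit * logit) w.r.t. the embedding output E
embedding_gradient <- function(model, fw, dlogit) {
  cfg <- model$config
  p <- model$params
  dF <- p$head.W[1L, ] %o% dlogit
  dX <- array(dF, dim(fw$X))
  dOM <- if (cfg$use_drfe)
    drfe_backward(dX, fw$mk$OM, fw$dr, cfg, p)$dX
  else dX
  # replay the MKFF backward but capture dE instead of the table gradient
  fwmk <- fw$mk
  g <- mkff_backward_dE(dOM, fwmk, cfg, p)
  g
}

mkff_backward_dE <- function(dOM, fwmk, cfg, p) {
  # reuse mkff_backward by temporarily swapping the embedding scatter for
  # an identity: cheapest is to recompute the final conv backward here.
  dO <- dOM
  if (cfg$use_mkff) {
    # everything between O and OM is linear in the cached maps; reuse the
    # full backward for dO by replaying it with a hook
    dO <- mkff_dO(dOM, fwmk, cfg, p)
  }
  conv1d_grad(fwmk$E, p$epw.W, dO, 1L, 0L)$dX
}

# dO accumulation identical to mkff_backward, without parameter gradients
mkff_dO <- function(dOM, fw, cfg, p) {
  mode <- cfg$fusion_mode
  dO <- dOM
  dGLDF <- dOM
  if (mode == "cat") {
    dMK <- dGLDF
  } else {
    dZ <- relu_grad(dGLDF, fw$GLDF)
    dG0 <- conv1d_grad(fw$G0, p$cmb.W, dZ, 1L, 0L)$dX
    C <- cfg$out_channel
    dGF <- dLF <- NULL
    if (mode == "gldf") {
      sp <- split_channels(dG0, c(C, C))
      dGF <- sp[[1L]]; dLF <- sp[[2L]]
    } else if (mode == "add") { dGF <- dG0; dLF <- dG0 }
    else if (mode == "global") dGF <- dG0
    else dLF <- dG0
    dMK <- array(0, dim(fw$MK))
    if (!is.null(dGF)) {
      gf <- fw$gf
      d <- dim(fw$MK)
      dMK <- dMK + dGF * broadcast_cl(gf$gw, d[2L])
      dgw <- sum_positions(dGF * fw$MK)
      dz <- dgw * gf$gw * (1 - gf$gw)
      dz3 <- array(dz, c(1L, d[1L], d[3L]))
      da <- matrix(conv1d_grad(gf$a3, p$eca.W, dz3, gf$kad)$dX, d[1L], d[3L])
      dMK <- dMK + broadcast_cl(da / d[2L], d[2L])
    }
    if (!is.null(dLF)) {
      lf <- fw$lf
      dMK <- dMK + dLF * lf$lw
      dlw <- dLF * fw$MK
      de <- if (identical(cfg$softmax_axis, "channels"))
        softmax_channels_grad(dlw, lf$lw)
      else softmax_positions_grad(dlw, lf$lw)
      ds <- conv1d_grad(lf$s, p$ex.W, de, lf$kad)$dX
      dMK <- dMK + conv1d_grad(fw$MK, p$sq.W, ds, lf$kad)$dX
    }
  }
  dMKpre <- relu_grad(dMK, fw$MK)
  dcat <- conv1d_grad(fw$cat_k, p$mk.W, dMKpre, 1L, 0L)$dX
  C4 <- path_channels(cfg)
  maps <- fw$paths$maps
  dparts <- split_channels(dcat, rep(C4, length(maps)))
  names(dparts) <- names(maps)
  cache <- fw$paths$cache
  ks <- cfg$kernel_sizes
  if (!is.null(dparts$k1))
    dO <- dO + conv1d_grad(fw$O, p$k1.W,
                           relu_grad(dparts$k1, maps$k1), ks[1L])$dX
  if (!is.null(dparts$k2)) {
    dk2a <- conv1d_grad(cache$k2a, p$k2b.W,
                        relu_grad(dparts$k2, maps$k2), ks[2L])$dX
    dO <- dO + conv1d_grad(fw$O, p$k2a.W,
                           relu_grad(dk2a, cache$k2a), 1L, 0L)$dX
  }
  if (!is.null(dparts$k3)) {
    dk3a <- conv1d_grad(cache$k3a, p$k3b.W,
                        relu_grad(dparts$k3, maps$k3), ks[3L])$dX
    dO <- dO + conv1d_grad(fw$O, p$k3a.W,
                           relu_grad(dk3a, cache$k3a), 1L, 0L)$dX
  }
  if (!is.null(dparts$k4)) {
    dk4p <- conv1d_grad(cache$k4p, p$k4.W,
                        relu_grad(dparts$k4, maps$k4), 1L, 0L)$dX
    dO <- dO + maxpool1d_grad(dk4p, cache$k4_argmax, dim(fw$O))
  }
  dO
}

#' Extract top-scoring sliding windows
#'
#' Slides a fixed window (stride 1) over the per-position scores, scoring
#' each window by the sum of its positions, and greedily selects the
#' `top_k` highest-scoring non-overlapping windows; ties break leftmost.
#'
#' @param per_position numeric score vector.
#' @param window window width (>= 1, <= length of the scores).
#' @param top_k number of windows to return.
#' @return matrix with columns `start`, `end` (0-based half-open) and
#'   `score`, ordered by decreasing score.
#' @export
extract_windows <- function(per_position, window, top_k = 3L) {
  n <- length(per_position)
  if (top_k < 1L) stop("top_k must be >= 1")
  if (window < 1L || window > n)
    stop("window must lie in 1..length(per_position)")
  nw <- n - window + 1L
  cs <- c(0, cumsum(per_position))
  scores <- cs[(window + 1L):(n + 1L)] - cs[1L:nw]
  ord <- order(-scores, seq_len(nw))           # ties leftmost
  sel <- matrix(numeric(0), ncol = 3L,
                dimnames = list(NULL, c("start", "end", "score")))
  taken <- logical(nw)
  for (j in ord) {
    if (nrow(sel) >= top_k) break
    s0 <- j - 1L                               # 0-based start
    if (nrow(sel) &&
        any(s0 < sel[, "end"] & s0 + window > sel[, "start"])) next
    sel <- rbind(sel, c(start = s0, end = s0 + window, score = scores[j]))
  }
  sel
}

#' Attach windows to saliency results
#'
#' @param saliency_results output of [input_saliency()].
#' @param window,top_k see [extract_windows()].
#' @return the saliency list with `windows` filled in.
#' @export
saliency_windows <- function(saliency_results, window = 10L, top_k = 3L) {
  lapply(saliency_results, function(sr) {
    w <- min(window, length(sr$per_position))
    sr$windows <- extract_windows(sr$per_position, w, top_k)
    sr
  })
}

#' Export high-contribution subsequences as FASTA
#'
#' One entry per selected window; headers carry the source id, the 0-based
#' half-open interval and the window score.
#'
#' @param records the records the saliency was computed on.
#' @param saliency_results output of [saliency_windows()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_subsequences <- function(records, saliency_results, path) {
  ids <- vapply(records, `[[`, "", "id")
  seqs <- character(0)
  hdrs <- character(0)
  for (sr in saliency_results) {
    if (is.null(sr$windows)) stop("windows not computed; run saliency_windows()")
    rec <- records[[match(sr$id, ids)]]
    for (r in seq_len(nrow(sr$windows))) {
      s0 <- sr$windows[r, "start"]; e0 <- sr$windows[r, "end"]
      seqs <- c(seqs, substr(rec$sequence, s0 + 1L, e0))
      hdrs <- c(hdrs, sprintf("%s|%d-%d|score=%.4g", sr$id,
                              as.integer(s0), as.integer(e0),
                              sr$windows[r, "score"]))
    }
  }
  x <- Biostrings::BStringSet(seqs)
  names(x) <- hdrs
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export staged feature embeddings
#'
#' Flattened per-sample feature vectors at a named network stage:
#' `"MP"` is the encoded max-length padded vector itself, `"MKC"` the
#' multi-kernel fused features entering the attention (MK_Fea), `"GLDF"`
#' the attention-fused features, and `"DRFE"` the final embedding.
#'
#' @param model a trained `m6a_model`.
#' @param records list of records.
#' @param stage one of `"MP"`, `"MKC"`, `"GLDF"`, `"DRFE"`.
#' @param batch_size forward-pass batch size.
#' @return list with `embeddings` (n x d matrix) and `labels`.
#' @export
export_embeddings <- function(model, records, stage = "DRFE",
                              batch_size = 128L) {
  stage <- match.arg(stage, c("MP", "MKC", "GLDF", "DRFE"))
  cfg <- model$config
  if (stage %in% c("MKC", "GLDF") && !cfg$use_mkff)
    stop("stage ", stage, " is not available without the MKFF module")
  n <- length(records)
  rows <- vector("list", n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    ba <- batch_encode(records[idx], cfg$L_max, cfg$padding_side,
                       cfg$truncate)
    if (stage == "MP") {
      for (k in seq_along(idx)) rows[[idx[k]]] <- as.numeric(ba$codes[k, ])
      next
    }
    fw <- model_forward_cache(model, ba$codes)
    M <- switch(stage,
      MKC  = fw$mk$MK,
      GLDF = fw$mk$GLDF,
      DRFE = fw$X)
    d <- dim(M)
    Fm <- matrix(M, nrow = d[1L] * d[2L])
    for (k in seq_along(idx)) rows[[idx[k]]] <- Fm[, k]
  }
  list(embeddings = do.call(rbind, rows),
       labels = vapply(records, `[[`, integer(1), "label"))
}

#' Mean silhouette score of labelled embeddings
#'
#' Standard mean silhouette width over samples with Euclidean distance.
#'
#' @param embeddings n x d numeric matrix.
#' @param labels class labels (>= 2 classes, >= 2 points each).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, labels) {
  labs <- as.integer(factor(labels))
  if (length(unique(labs)) < 2L)
    stop("silhouette requires at least two classes")
  sil <- cluster::silhouette(labs, stats::dist(embeddings))
  mean(sil[, "sil_width"])
}

#' Permutation test for motif-window enrichment
#'
#' Tests whether top-1 saliency windows overlap the known planted motif
#' intervals more than windows placed uniformly at random (one-sided).
#'
#' @param records positive records with `motif_intervals` ground truth.
#' @param saliency_results windowed saliency results for the same records.
#' @param n_perm number of random placements per record.
#' @param seed permutation seed.
#' @return list with `observed` mean overlap (nt), `null_mean`, and
#'   `p_value`.
#' @export
window_enrichment_test <- function(records, saliency_results,
                                   n_perm = 200L, seed = 1L) {
  ids <- vapply(records, `[[`, "", "id")
  obs <- numeric(0)
  nulls <- matrix(numeric(0), nrow = 0, ncol = n_perm)
  with_preserved_seed(derive_seed(seed, 131L), {
    for (sr in saliency_results) {
      rec <- records[[match(sr$id, ids)]]
      iv <- rec$motif_intervals
      if (is.null(iv) || !nrow(iv) || is.null(sr$windows) ||
          !nrow(sr$windows)) next
      w <- sr$windows[1L, , drop = FALSE]
      obs <- c(obs, interval_overlap(w[1, "start"], w[1, "end"], iv))
      len <- nchar(rec$sequence)
      width <- w[1, "end"] - w[1, "start"]
      starts <- sample.int(len - width + 1L, n_perm, replace = TRUE) - 1L
      nulls <- rbind(nulls, vapply(starts, function(s0)
        interval_overlap(s0, s0 + width, iv), numeric(1)))
    }
  })
  if (!length(obs)) stop("no records with both windows and motif intervals")
  null_means <- colMeans(nulls)
  observed <- mean(obs)
  p <- (1 + sum(null_means >= observed)) / (1 + n_perm)
  list(observed = observed, null_mean = mean(null_means), p_value = p)
}

# overlap (nt) between [s, e) and a set of intervals
interval_overlap <- function(s, e, intervals) {
  sum(pmax(0, pmin(e, intervals[, "end"]) - pmax(s, intervals[, "start"])))
}
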