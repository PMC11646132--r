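#' @title Seeded training loop and cross-validation
#' @name train_eval
NULL

# deterministic child seeds, kept inside 32-bit integer range
derive_seed <- function(base, offset) {
  as.integer((as.numeric(base) %% 65011 * 7919 + offset * 104729 + 17) %%
               2147483647)
}

predict_codes <- function(model, codes, batch_size = 256L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    fw <- model_forward_cache(model, codes[idx, , drop = FALSE])
    out[idx] <- fw$yhat
  }
  out
}

#' Train a model by minibatch gradient descent
#'
#' Minimises the total loss (binary cross-entropy plus, when enabled, the
#' contrastive term) with Adam.  Validation metrics are computed after each
#' epoch; training stops early when the validation AUC has not improved for
#' `config$patience` epochs, and the best-AUC weights are restored.  All
#' randomness (shuffling, contrastive pairing) derives from `config$seed`,
#' so identical inputs reproduce identical histories.
#'
#' @param model an untrained [build_model()] object.
#' @param train_records,val_records disjoint lists of labelled
#'   [sequence_record()]s.
#' @param config training configuration; defaults to the model's.
#' @param verbose print per-epoch progress.
#' @return the trained `m6a_model`, with `history` containing per-epoch
#'   losses and validation metrics plus a replayable description of the
#'   first minibatch.
#' @export
train_model <- function(model, train_records, val_records,
                        config = model$config, verbose = FALSE) {
  cfg <- config
  if (!length(train_records) || !length(val_records))
    stop("empty training or validation split")
  tb <- batch_encode(train_records, cfg$L_max, cfg$padding_side, cfg$truncate)
  vb <- batch_encode(val_records, cfg$L_max, cfg$padding_side, cfg$truncate)
  if (is.null(tb$labels) || is.null(vb$labels))
    stop("training requires labelled records")
  p <- model$params
  opt <- adam_state(p)
  n <- nrow(tb$codes)
  epochs <- data.frame()
  best <- list(auc = -Inf, params = p, epoch = 0L)
  first_batch <- NULL
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_preserved_seed(derive_seed(cfg$seed, 1000L + ep),
                               sample.int(n))
    tot_loss <- tot_bce <- tot_cl <- 0
    nb <- 0L
    for (at in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[at:min(at + cfg$batch_size - 1L, n)]
      nb <- nb + 1L
      y <- tb$labels[idx]
      model$params <- p
      fw <- model_forward_cache(model, tb$codes[idx, , drop = FALSE])
      pair_seed <- derive_seed(cfg$seed, ep * 100000L + nb)
      dFextra <- NULL
      cl <- 0
      if (cfg$use_cl && length(idx) >= 2L) {
        cg <- batch_contrastive_grad(fw$Fmat, y, cfg$margin, pair_seed,
                                     cfg$pair_mode)
        cl <- cg$loss
        dFextra <- cg$dF
      }
      bce <- bce_loss(fw$yhat, y)
      # d(BCE)/dlogit for the clipped sigmoid output
      dlogit <- (fw$yhat - y) / length(idx)
      g <- model_backward(model, fw, dlogit, dFextra)
      step <- adam_step(p, g, opt, lr = cfg$lr)
      p <- step$params
      opt <- step$state
      tot_loss <- tot_loss + bce + cl
      tot_bce <- tot_bce + bce
      tot_cl <- tot_cl + cl
      if (is.null(first_batch))
        first_batch <- list(indices = idx, pair_seed = pair_seed,
                            bce = bce, cl = cl, total = bce + cl)
    }
    model$params <- p
    vp <- predict_codes(model, vb$codes)
    vm <- compute_metrics(vb$labels, vp, cfg$threshold,
                          allow_degenerate = TRUE)
    epochs <- rbind(epochs, data.frame(
      epoch = ep, train_loss = tot_loss / nb, train_bce = tot_bce / nb,
      train_cl = tot_cl / nb, val_acc = vm$ACC, val_mcc = vm$MCC,
      val_auc = vm$AUC, val_aupr = vm$AUPR))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val AUC %.4f",
                      ep, tot_loss / nb, vm$AUC))
    if (!is.na(vm$AUC) && vm$AUC > best$auc) {
      best <- list(auc = vm$AUC, params = p, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$history <- list(epochs = epochs, best_epoch = best$epoch,
                        best_val_auc = best$auc, first_batch = first_batch)
  model
}

#' Stratified k-fold cross-validation
#'
#' Records are partitioned into `k` stratified folds (seeded); each fold in
#' turn is the validation set while the model trains on the remainder.  The
#' report aggregates per-fold ACC/MCC/AUC/AUPR as mean and sample standard
#' deviation.
#'
#' @param records labelled [sequence_record()]s.
#' @param config an [m6a_config()].
#' @param k number of folds (>= 2).
#' @param seed partition seed (defaults to `config$seed`).
#' @param verbose print fold progress.
#' @return an [metrics_report()] object, with the fold assignment in
#'   attribute `"folds"` and per-fold predictions in attribute
#'   `"predictions"`.
#' @export
cross_validate <- function(records, config, k = 5L, seed = config$seed,
                           verbose = FALSE) {
  if (k < 2L) stop("k must be >= 2")
  labels <- vapply(records, `[[`, integer(1), "label")
  if (anyNA(labels)) stop("cross-validation requires labelled records")
  folds <- stratified_folds(labels, k, seed)
  per <- data.frame()
  preds <- data.frame()
  for (f in seq_len(k)) {
    val_idx <- which(folds == f)
    tr_idx <- which(folds != f)
    if (length(unique(labels[val_idx])) < 2L)
      stop("fold ", f, " lost a class; use fewer folds")
    m <- build_model(config, init_seed = derive_seed(seed, 7L * f))
    m <- train_model(m, records[tr_idx], records[val_idx],
                     verbose = verbose)
    vb <- batch_encode(records[val_idx], config$L_max,
                       config$padding_side, config$truncate)
    vp <- predict_codes(m, vb$codes)
    vm <- compute_metrics(vb$labels, vp, config$threshold)
    per <- rbind(per, data.frame(fold = f, ACC = vm$ACC, MCC = vm$MCC,
                                 AUC = vm$AUC, AUPR = vm$AUPR))
    preds <- rbind(preds, data.frame(fold = f, id = vb$ids,
                                     label = vb$labels, probability = vp))
    if (verbose)
      message(sprintf("fold %d: ACC %.4f MCC %.4f AUC %.4f AUPR %.4f",
                      f, vm$ACC, vm$MCC, vm$AUC, vm$AUPR))
  }
  rep <- metrics_report(per)
  attr(rep, "folds") <- folds
  attr(rep, "predictions") <- preds
  rep
}

# seeded stratified fold assignment: both classes spread evenly
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_preserved_seed(derive_seed(seed, 31L), {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Split records into stratified train/validation sets
#'
#' @param records labelled records.
#' @param val_fraction fraction held out for validation.
#' @param seed split seed.
#' @return list with `train` and `val` record lists.
#' @export
train_val_split <- function(records, val_fraction = 0.2, seed = 1L) {
  labels <- vapply(records, `[[`, integer(1), "label")
  val <- logical(length(records))
  with_preserved_seed(derive_seed(seed, 97L), {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      nv <- max(1L, round(length(idx) * val_fraction))
      val[sample(idx, nv)] <- TRUE
    }
  })
  list(train = records[!val], val = records[val])
}
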