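cfg <- tiny_config()
recs <- tiny_records()
ba <- batch_encode(recs, cfg$L_max)

test_that("build_model is deterministic and respects variants", {
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, init_seed = 43L)
  expect_false(identical(m1$params$epw.W, m3$params$epw.W))
  # forward returns probabilities in (0,1)
  fw <- ns$model_forward_cache(m1, ba$codes)
  expect_length(fw$yhat, length(recs))
  expect_true(all(fw$yhat > 0 & fw$yhat < 1))
  # no-DRFE head consumes the full-length feature map
  nd <- m6a_config(use_drfe = FALSE)
  expect_identical(ns$head_width(nd), nd$out_channel * nd$L_max)
  mnd <- build_model(tiny_config(use_drfe = FALSE))
  expect_identical(ncol(mnd$params$head.W), 8L * 12L)
  # no-MKFF variant carries only embedding + point-wise parameters upstream
  mnm <- build_model(tiny_config(use_mkff = FALSE))
  expect_false(any(grepl("^mk\\.|^k1\\.|^cmb\\.", names(mnm$params))))
})

test_that("predict_proba applies the sigmoid head; zero head gives 0.5", {
  model <- randomize_params(build_model(cfg))
  X <- drfe_forward(mkff_forward(ba, cfg, model$params), cfg, model$params)
  pr <- predict_proba(X, model$params)
  expect_true(all(pr > 0 & pr < 1))
  p0 <- model$params
  p0$head.W[] <- 0; p0$head.b[] <- 0
  expect_equal(predict_proba(X, p0), rep(0.5, length(recs)))
  # dense oracle
  Fm <- matrix(X, nrow = prod(dim(X)[1:2]))
  manual <- 1 / (1 + exp(-(as.vector(model$params$head.W %*% Fm) +
                             as.numeric(model$params$head.b))))
  expect_equal(pr, manual, tolerance = 1e-12)
})

test_that("bce_loss matches closed-form hand computations", {
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)      # perfect prediction: ~0
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -log(0.9))
  expect_equal(bce_loss(c(0.9, 0.2, 0.7), c(1, 0, 1)),
               -(log(0.9) + log(0.8) + log(0.7)) / 3)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
  # clipping keeps the loss finite at the boundaries
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
})

test_that("total loss is the unweighted sum, with cl dropped when disabled", {
  set.seed(5)
  yh <- runif(6, 0.1, 0.9)
  y <- c(1, 0, 1, 0, 1, 0)
  Fm <- matrix(rnorm(24), nrow = 4)
  tl <- total_loss(yh, y, Fm, cfg, pair_seed = 9L)
  expect_equal(tl$total, tl$bce + tl$cl, tolerance = 1e-6)
  expect_equal(tl$bce, bce_loss(yh, y))
  expect_equal(tl$cl, batch_contrastive(Fm, y, cfg$margin, 9L))
  cfg0 <- tiny_config(use_cl = FALSE)
  tl0 <- total_loss(yh, y, Fm, cfg0, pair_seed = 9L)
  expect_identical(tl0$cl, 0)
  expect_identical(tl0$total, tl0$bce)
  # identical embeddings in same-class pairs contribute nothing
  Fi <- matrix(1, nrow = 4, ncol = 4)
  tli <- total_loss(runif(4, 0.2, 0.8), c(1, 1, 1, 1), Fi, cfg, 2L)
  expect_identical(tli$cl, 0)
})

test_that("classification boundary: below threshold negative, at it positive", {
  expect_identical(classify(0.49, 0.5), 0L)
  expect_identical(classify(0.5, 0.5), 1L)
  expect_identical(classify(1.0, 0.5), 1L)
  expect_identical(classify(c(0.1, 0.7), 0.5), c(0L, 1L))
  expect_error(classify(0.5, 1.5), "threshold")
})

test_that("full-model gradients agree with finite differences", {
  model <- randomize_params(build_model(cfg))
  y <- ba$labels
  loss_fn <- function(params) {
    m <- model; m$params <- params
    fw <- ns$model_forward_cache(m, ba$codes)
    total_loss(fw$yhat, y, fw$Fmat, cfg, pair_seed = 5L)$total
  }
  fw <- ns$model_forward_cache(model, ba$codes)
  cg <- ns$batch_contrastive_grad(fw$Fmat, y, cfg$margin, 5L, cfg$pair_mode)
  g <- ns$model_backward(model, fw, (fw$yhat - y) / length(y), cg$dF)
  set.seed(31)
  eps <- 1e-5
  for (nm in names(g)) {
    idx <- sample(length(model$params[[nm]]),
                  min(3, length(model$params[[nm]])))
    for (i in idx) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-3,
                   label = paste("analytic grad", nm))
    }
  }
  # gradients reach the embedding table from both loss terms
  expect_gt(sum(abs(g$embed)), 0)
  g_cl_only <- ns$model_backward(model, fw, rep(0, length(y)), cg$dF)
  expect_gt(sum(abs(g_cl_only$embed)), 0)
})

test_that("end-to-end determinism: same seeds give identical outputs", {
  m1 <- randomize_params(build_model(cfg))
  fw1 <- ns$model_forward_cache(m1, ba$codes)
  m2 <- randomize_params(build_model(cfg))
  fw2 <- ns$model_forward_cache(m2, ba$codes)
  expect_identical(fw1$yhat, fw2$yhat)
})

test_that("checkpoints round-trip config, weights and predictions", {
  model <- randomize_params(build_model(cfg))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$config$out_channel, cfg$out_channel)
  p1 <- predict(model, recs)
  p2 <- predict(back, recs)
  expect_identical(p1, p2)
  expect_true(all(p1$probability > 0 & p1$probability < 1))
  expect_identical(p1$label, classify(p1$probability, cfg$threshold))
})
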