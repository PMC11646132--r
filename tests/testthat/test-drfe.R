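cfg <- tiny_config()
model <- randomize_params(build_model(cfg))
recs <- tiny_records()
ba <- batch_encode(recs, cfg$L_max)
OM <- mkff_forward(ba, cfg, model$params)

test_that("stem is equal-length and matches the sliding-window oracle", {
  S <- stem_forward(OM, cfg, model$params)
  expect_identical(dim(S), dim(unclass(OM)))
  p <- model$params
  S2 <- pmax(oracle_conv1d(pmax(oracle_conv1d(OM, p$stem1.W, p$stem1.b,
                                              5L, 2L), 0),
                           p$stem2.W, p$stem2.b, 5L, 2L), 0)
  expect_equal(unclass(S)[TRUE], S2[TRUE], tolerance = 1e-6)
  # zero weights give zero output
  p0 <- model$params
  p0$stem1.W[] <- 0; p0$stem1.b[] <- 0
  p0$stem2.W[] <- 0; p0$stem2.b[] <- 0
  expect_equal(max(abs(stem_forward(OM, cfg, p0))), 0)
})

test_that("dr_block downsamples by the length formula with a residual", {
  S <- stem_forward(OM, cfg, model$params)
  B <- dr_block(S, cfg, model$params, block = 1L)
  Lout <- (dim(S)[2] + 2L - 3L) %/% cfg$dr_pool_stride + 1L
  expect_identical(dim(B)[2], Lout)
  # zeroed convolutions reduce the block to its pooled input exactly
  p0 <- model$params
  p0$dr1a.W[] <- 0; p0$dr1a.b[] <- 0
  p0$dr1b.W[] <- 0; p0$dr1b.b[] <- 0
  B0 <- dr_block(S, cfg, p0, block = 1L)
  pooled <- oracle_maxpool1d(S, 3L, 1L, cfg$dr_pool_stride)
  expect_identical(unclass(B0)[TRUE], pooled[TRUE])
  # full block against the explicit pooling + conv oracle
  p <- model$params
  conv2 <- pmax(oracle_conv1d(pmax(oracle_conv1d(pooled, p$dr1a.W, p$dr1a.b,
                                                 5L, 2L), 0),
                              p$dr1b.W, p$dr1b.b, 5L, 2L), 0)
  expect_equal(unclass(B)[TRUE], (conv2 + pooled)[TRUE], tolerance = 1e-6)
})

test_that("length arithmetic: 800 downsamples 400/200/100/50 per block", {
  L <- 800L
  outs <- integer(4)
  for (i in 1:4) {
    L <- ns$dr_out_length(L, 3L, 2L)
    outs[i] <- L
  }
  expect_identical(outs, c(400L, 200L, 100L, 50L))
  # drfe_forward applies stem then the configured number of blocks
  X <- drfe_forward(OM, cfg, model$params)
  L2 <- ns$dr_out_length(ns$dr_out_length(cfg$L_max, 3L, 2L), 3L, 2L)
  expect_identical(dim(X), c(cfg$out_channel, L2, length(recs)))
  # zero blocks return the stem output
  cfg0 <- tiny_config(n_dr_blocks = 0L)
  m0 <- randomize_params(build_model(cfg0))
  X0 <- drfe_forward(OM, cfg0, m0$params)
  S0 <- stem_forward(OM, cfg0, m0$params)
  expect_identical(unclass(X0)[TRUE], unclass(S0)[TRUE])
  # collapsing configurations are rejected up front
  expect_error(tiny_config(n_dr_blocks = 6L), "fewer blocks|collapses")
})

test_that("contrastive loss matches its closed forms", {
  f <- rnorm(10)
  expect_identical(contrastive_loss(f, f, TRUE, 2), 0)
  expect_identical(contrastive_loss(f, f, FALSE, 2), 2)
  g <- f + c(3, rep(0, 9))                     # distance exactly 3
  expect_identical(contrastive_loss(f, g, FALSE, 2), 0)
  expect_equal(contrastive_loss(f, g, TRUE, 2), 4.5)
  expect_error(contrastive_loss(f, g[1:5], TRUE, 2), "dimension")
  expect_error(contrastive_loss(f, g, TRUE, 0), "positive")
})

test_that("contrastive loss is non-negative and monotone in distance", {
  set.seed(3)
  for (rep in 1:50) {
    f <- rnorm(6); g <- rnorm(6)
    expect_gte(contrastive_loss(f, g, TRUE, 2), 0)
    expect_gte(contrastive_loss(f, g, FALSE, 2), 0)
  }
  M <- 2
  Ds <- seq(0, 4, by = 0.25)
  same <- sapply(Ds, function(D) contrastive_loss(c(0), c(D), TRUE, M))
  diff_ <- sapply(Ds, function(D) contrastive_loss(c(0), c(D), FALSE, M))
  expect_true(all(diff(same) >= 0))            # K=0: non-decreasing in D
  expect_true(all(diff(diff_) <= 0))           # K=1: non-increasing in D
  expect_true(all(diff_[Ds >= M] == 0))
})

test_that("batch contrastive averages seeded disjoint pairs", {
  F2 <- cbind(rep(0, 4), rep(0, 4))
  expect_identical(batch_contrastive(F2, c(1, 1), 2, 1L), 0)
  expect_identical(batch_contrastive(F2, c(1, 0), 2, 1L), 2)
  # six known embeddings: enumerate the seeded pairing by hand
  set.seed(8)
  F6 <- matrix(rnorm(18), nrow = 3)
  y6 <- c(1, 0, 1, 1, 0, 0)
  ord <- ns$with_preserved_seed(77L, sample.int(6))
  manual <- mean(sapply(1:3, function(t) {
    i <- ord[2 * t - 1]; j <- ord[2 * t]
    contrastive_loss(F6[, i], F6[, j], y6[i] == y6[j], 2)
  }))
  expect_equal(batch_contrastive(F6, y6, 2, 77L), manual)
  # determinism and single-sample degeneracy
  expect_identical(batch_contrastive(F6, y6, 2, 77L),
                   batch_contrastive(F6, y6, 2, 77L))
  expect_warning(z <- batch_contrastive(F6[, 1, drop = FALSE], 1, 2, 1L),
                 "two samples")
  expect_identical(z, 0)
})

test_that("contrastive gradient agrees with finite differences", {
  set.seed(21)
  F6 <- matrix(rnorm(12, sd = 0.5), nrow = 2)
  y6 <- c(1, 0, 1, 0, 1, 0)
  cg <- ns$batch_contrastive_grad(F6, y6, 2, 5L)
  eps <- 1e-6
  for (i in sample(length(F6), 6)) {
    Fp <- F6; Fp[i] <- Fp[i] + eps
    Fm <- F6; Fm[i] <- Fm[i] - eps
    fd <- (batch_contrastive(Fp, y6, 2, 5L) -
             batch_contrastive(Fm, y6, 2, 5L)) / (2 * eps)
    expect_equal(cg$dF[i], fd, tolerance = 1e-4)
  }
})

test_that("DRFE compresses the classifier head 8-fold at defaults", {
  full <- m6a_config()
  no_drfe <- m6a_config(use_drfe = FALSE)
  expect_identical(ns$head_width(full), 128L * 100L)
  expect_identical(ns$head_width(no_drfe), 128L * 800L)
  expect_identical(ns$head_width(no_drfe), 8L * ns$head_width(full))
})
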