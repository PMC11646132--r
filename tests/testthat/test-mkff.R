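cfg <- tiny_config()
model <- randomize_params(build_model(cfg))
recs <- tiny_records()
ba <- batch_encode(recs, cfg$L_max)

test_that("adaptive kernel size matches hand-derived values and invariants", {
  expect_identical(adaptive_kernel_size(128, 2, 1), 3L)
  expect_identical(adaptive_kernel_size(2, 2, 1), 1L)
  expect_identical(adaptive_kernel_size(1024, 2, 1), 5L)
  ks <- vapply(2:4096, adaptive_kernel_size, integer(1))
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(ks >= 1L))
  expect_true(all(diff(ks) >= 0L))             # non-decreasing in C
  expect_error(adaptive_kernel_size(0), ">= 1")
})

test_that("embed_project has the right shape and zero-padding embedding", {
  O <- embed_project(ba, cfg, model$params)
  expect_identical(dim(O), c(cfg$out_channel, cfg$L_max, length(recs)))
  expect_identical(fm_stage(O), "O_embed")
  # with zero point-wise weights and bias the output vanishes
  p0 <- model$params
  p0$epw.W[] <- 0; p0$epw.b[] <- 0
  expect_equal(max(abs(embed_project(ba, cfg, p0))), 0)
  # dense-oracle comparison: embedding gather + pointwise conv by hand
  E <- ns$embed_forward(t(ba$codes), model$params$embed)
  O2 <- oracle_conv1d(E, model$params$epw.W, model$params$epw.b, 1L, 0L)
  expect_equal(unclass(O)[TRUE], O2[TRUE], tolerance = 1e-6)
  # padding positions embed to exactly zero, per sample
  for (i in seq_along(recs)) {
    npad <- cfg$L_max - ba$lengths[i]
    if (npad > 0L)
      expect_equal(max(abs(E[, seq_len(npad), i])), 0)
  }
  # out-of-range codes rejected
  bad <- ba; bad$codes[1, 1] <- 7L
  expect_error(embed_project(bad, cfg, model$params), "codes")
})

test_that("kernel paths match explicit sliding-window oracles", {
  O <- embed_project(ba, cfg, model$params)
  km <- multi_kernel_extract(O, cfg, model$params)
  C4 <- cfg$out_channel %/% 4L
  for (m in km)
    expect_identical(dim(m), c(C4, cfg$L_max, length(recs)))
  p <- model$params
  rl <- function(x) pmax(x, 0)
  k1 <- rl(oracle_conv1d(O, p$k1.W, p$k1.b, 1L, 0L))
  k2 <- rl(oracle_conv1d(rl(oracle_conv1d(O, p$k2a.W, p$k2a.b, 1L, 0L)),
                         p$k2b.W, p$k2b.b, 3L, 1L))
  k3 <- rl(oracle_conv1d(rl(oracle_conv1d(O, p$k3a.W, p$k3a.b, 1L, 0L)),
                         p$k3b.W, p$k3b.b, 5L, 2L))
  k4 <- rl(oracle_conv1d(oracle_maxpool1d(O, 3L, 1L, 1L),
                         p$k4.W, p$k4.b, 1L, 0L))
  expect_equal(unclass(km$k1)[TRUE], k1[TRUE], tolerance = 1e-6)
  expect_equal(unclass(km$k2)[TRUE], k2[TRUE], tolerance = 1e-6)
  expect_equal(unclass(km$k3)[TRUE], k3[TRUE], tolerance = 1e-6)
  expect_equal(unclass(km$k4)[TRUE], k4[TRUE], tolerance = 1e-6)
})

test_that("stride-1 pad-1 max-pool of a constant map is the constant", {
  X <- array(3.7, c(2L, 9L, 1L))
  Y <- oracle_maxpool1d(X, 3L, 1L, 1L)
  expect_equal(Y, X)
  mp <- ns$maxpool1d(X, 3L, 1L, 1L)
  expect_equal(mp$Y[TRUE], X[TRUE])
})

test_that("concat_fuse concatenates in path order then mixes point-wise", {
  O <- embed_project(ba, cfg, model$params)
  km <- multi_kernel_extract(O, cfg, model$params)
  MK <- concat_fuse(km, cfg, model$params)
  expect_identical(dim(MK), c(cfg$out_channel, cfg$L_max, length(recs)))
  # identity-initialized point-wise conv returns the raw concatenation
  # (path maps are ReLU outputs, hence non-negative)
  p <- model$params
  p$mk.W <- diag(cfg$out_channel); p$mk.b[] <- 0
  MKi <- concat_fuse(km, cfg, p)
  catk <- ns$concat_channels(km)
  expect_equal(unclass(MKi)[TRUE], catk[TRUE])
  expect_true(all(catk >= 0))
  # dense oracle
  MK2 <- pmax(oracle_conv1d(catk, model$params$mk.W, model$params$mk.b,
                            1L, 0L), 0)
  expect_equal(unclass(MK)[TRUE], MK2[TRUE], tolerance = 1e-6)
  # mismatched lengths rejected
  short <- km
  short$k1 <- km$k1[, 1:6, , drop = FALSE]
  expect_error(concat_fuse(short, cfg, model$params), "length")
})

test_that("global channel fusion matches the explicit-loop oracle", {
  O <- embed_project(ba, cfg, model$params)
  MK <- concat_fuse(multi_kernel_extract(O, cfg, model$params), cfg,
                    model$params)
  gf <- global_channel_fusion(MK, cfg, model$params)
  kad <- adaptive_kernel_size(cfg$out_channel, cfg$gamma, cfg$b)
  orc <- oracle_global_fusion(MK, as.vector(model$params$eca.W),
                              as.numeric(model$params$eca.b), kad)
  expect_equal(gf$weight, orc$weight, tolerance = 1e-6)
  expect_equal(unclass(gf$fea)[TRUE], orc$fea[TRUE], tolerance = 1e-6)
  expect_true(all(gf$weight > 0 & gf$weight < 1))
  # zero conv weights and bias give sigmoid(0) = 0.5 everywhere
  p <- model$params
  p$eca.W[] <- 0; p$eca.b[] <- 0
  gf0 <- global_channel_fusion(MK, cfg, p)
  expect_equal(max(abs(gf0$weight - 0.5)), 0)
  expect_equal(unclass(gf0$fea)[TRUE], 0.5 * unclass(MK)[TRUE])
  # constant input: channel means equal the constant
  K <- array(2.5, dim(MK))
  expect_equal(ns$mean_positions(K), matrix(2.5, dim(MK)[1], dim(MK)[3]))
})

test_that("local spatial fusion matches the oracle and normalizes", {
  O <- embed_project(ba, cfg, model$params)
  MK <- concat_fuse(multi_kernel_extract(O, cfg, model$params), cfg,
                    model$params)
  lf <- local_spatial_fusion(MK, cfg, model$params)
  p <- model$params
  kad <- adaptive_kernel_size(cfg$out_channel, cfg$gamma, cfg$b)
  orc <- oracle_local_fusion(MK, p$sq.W, p$sq.b, p$ex.W, p$ex.b, kad)
  expect_equal(lf$weight[TRUE], orc$weight[TRUE], tolerance = 1e-6)
  expect_equal(unclass(lf$fea)[TRUE], orc$fea[TRUE], tolerance = 1e-6)
  # rows sum to 1 along positions
  sums <- apply(lf$weight, c(1, 3), sum)
  expect_true(max(abs(sums - 1)) < 1e-5)
  # zero excitation: softmax of constants is uniform, Local_Fea = MK / L
  p0 <- model$params
  p0$ex.W[] <- 0; p0$ex.b[] <- 0
  lf0 <- local_spatial_fusion(MK, cfg, p0)
  expect_equal(max(abs(lf0$weight - 1 / cfg$L_max)), 0, tolerance = 1e-12)
  expect_equal(unclass(lf0$fea)[TRUE], unclass(MK)[TRUE] / cfg$L_max,
               tolerance = 1e-12)
})

test_that("gldf_combine applies the residual; zero combine conv is identity", {
  O <- embed_project(ba, cfg, model$params)
  km <- multi_kernel_extract(O, cfg, model$params)
  MK <- concat_fuse(km, cfg, model$params)
  gf <- global_channel_fusion(MK, cfg, model$params)
  lf <- local_spatial_fusion(MK, cfg, model$params)
  OM <- gldf_combine(gf$fea, lf$fea, O, cfg, model$params)
  expect_identical(dim(OM), dim(unclass(O)))
  # zeroing the combine conv makes O_MKFF identical to O_embed
  p0 <- model$params
  p0$cmb.W[] <- 0; p0$cmb.b[] <- 0
  OM0 <- gldf_combine(gf$fea, lf$fea, O, cfg, p0)
  expect_identical(unclass(OM0)[TRUE], unclass(O)[TRUE])
  # dense oracle for the combine conv
  G0 <- ns$concat_channels(list(gf$fea, lf$fea))
  GLDF <- pmax(oracle_conv1d(G0, model$params$cmb.W, model$params$cmb.b,
                             1L, 0L), 0)
  expect_equal(unclass(OM)[TRUE], (unclass(O) + GLDF)[TRUE],
               tolerance = 1e-6)
})

test_that("mkff_forward composes the per-op pipeline for every variant", {
  OM <- mkff_forward(ba, cfg, model$params)
  O <- embed_project(ba, cfg, model$params)
  km <- multi_kernel_extract(O, cfg, model$params)
  MK <- concat_fuse(km, cfg, model$params)
  gf <- global_channel_fusion(MK, cfg, model$params)
  lf <- local_spatial_fusion(MK, cfg, model$params)
  OM2 <- gldf_combine(gf$fea, lf$fea, O, cfg, model$params)
  expect_equal(unclass(OM)[TRUE], unclass(OM2)[TRUE], tolerance = 1e-12)
  # cat variant: Eqs. of the attention collapse onto the fused features
  ccfg <- tiny_config(fusion_mode = "cat")
  cmodel <- randomize_params(build_model(ccfg))
  OMc <- mkff_forward(ba, ccfg, cmodel$params)
  Oc <- embed_project(ba, ccfg, cmodel$params)
  MKc <- concat_fuse(multi_kernel_extract(Oc, ccfg, cmodel$params),
                     ccfg, cmodel$params)
  expect_equal(unclass(OMc)[TRUE], (unclass(Oc) + unclass(MKc))[TRUE])
  # add variant: branches summed before the combine conv
  acfg <- tiny_config(fusion_mode = "add")
  am <- randomize_params(build_model(acfg))
  OMa <- mkff_forward(ba, acfg, am$params)
  Oa <- embed_project(ba, acfg, am$params)
  MKa <- concat_fuse(multi_kernel_extract(Oa, acfg, am$params), acfg,
                     am$params)
  gfa <- global_channel_fusion(MKa, acfg, am$params)
  lfa <- local_spatial_fusion(MKa, acfg, am$params)
  G0 <- unclass(gfa$fea) + unclass(lfa$fea)
  GLDFa <- pmax(oracle_conv1d(G0, am$params$cmb.W, am$params$cmb.b, 1L, 0L), 0)
  expect_equal(unclass(OMa)[TRUE], (unclass(Oa) + GLDFa)[TRUE],
               tolerance = 1e-6)
  # kernel subsets change the fused width but keep the module length
  for (combo in list("k1", c("k1", "k2"), c("k1", "k2", "k3"))) {
    scfg <- tiny_config(kernel_combo = combo)
    sm <- randomize_params(build_model(scfg))
    OMs <- mkff_forward(ba, scfg, sm$params)
    expect_identical(dim(OMs), c(scfg$out_channel, scfg$L_max, length(recs)))
  }
  expect_error(tiny_config(kernel_combo = character(0)), "at least one")
})
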