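test_that("channel attention scales and re-adds features", {
  cfg <- fusion_config()
  ps <- init_fusion_params(cfg, seed = 2)
  p_att <- ps$params$branch1$stages[[2]]$icbam
  x <- array(abs(rnorm(1 * 64 * 450)) + 0.1, c(1, 64, 450))
  f1 <- channel_attention(x, p_att)
  expect_same_shape(f1, c(1, 64, 450))
  # weights in (0,1): elementwise F < F1 < 2F for positive F
  expect_true(all(f1 > x))
  expect_true(all(f1 < 2 * x))
  # zero input with zero-initialized weights stays zero
  pz <- init_fusion_params(cfg, seed = 1, init = "zeros")
  z <- array(0, c(1, 64, 450))
  expect_equal(channel_attention(z, pz$params$branch1$stages[[2]]$icbam), z)
})

test_that("spatial attention preserves shape and reuses the block input", {
  cfg <- fusion_config()
  ps <- init_fusion_params(cfg, seed = 3)
  p_att <- ps$params$branch1$stages[[2]]$icbam
  x0 <- array(rnorm(2 * 64 * 225), c(2, 64, 225))
  f1 <- array(rnorm(2 * 64 * 225), c(2, 64, 225))
  f2 <- spatial_attention(f1, x0, p_att, k = cfg$spatial_kernel)
  expect_same_shape(f2, c(2, 64, 225))
  # attention map is in (0,1): |f2 - x0| < |f1| elementwise
  expect_true(all(abs(f2 - x0) <= abs(f1)))
  # zero input with zero-initialized conv gives x0 + f1 * sigmoid(0) = f1/2 + x0;
  # with everything zero the output is zero
  pz <- init_fusion_params(cfg, seed = 1, init = "zeros")
  z <- array(0, c(1, 64, 225))
  expect_equal(spatial_attention(z, z, pz$params$branch1$stages[[2]]$icbam, 7L), z)
})

test_that("attention forced to 1 collapses ICBAM to a fixed residual sum", {
  # with both sigmoids bypassed: channel stage gives 2F, spatial gives
  # 2F * 1 + F = 3F — independent of every attention parameter
  cfg <- fusion_config()
  for (seed in c(2, 9)) {
    ps <- init_fusion_params(cfg, seed = seed)
    x <- array(rnorm(1 * 32 * 450), c(1, 32, 450))
    out <- ecgfusion:::icbam_fwd(x, ps$params$branch1$stages[[1]]$icbam,
                                 cfg$spatial_kernel, sigmoid_bypass = TRUE)$out
    expect_equal(out, 3 * x, tolerance = 1e-12)
  }
})

test_that("residual blocks reproduce the stage geometry", {
  cfg <- fusion_config()
  ps <- init_fusion_params(cfg, seed = 4)
  st <- ps$state$stages
  p <- ps$params$branch1$stages
  x3 <- array(rnorm(1 * 64 * 225), c(1, 64, 225))
  expect_same_shape(icbam_residual_block(x3, p[[3]], st[[3]], stride = 2L),
                    c(1, 128, 113))
  x4 <- array(rnorm(1 * 128 * 113), c(1, 128, 113))
  expect_same_shape(icbam_residual_block(x4, p[[4]], st[[4]], stride = 2L),
                    c(1, 256, 57))
  x1 <- array(rnorm(1 * 32 * 450), c(1, 32, 450))
  p_same <- ecgfusion:::init_resblock(32L, 32L, 1L, 4L, 7L, "kaiming")
  s_same <- ecgfusion:::resblock_state(32L, 32L, 1L)
  expect_same_shape(icbam_residual_block(x1, p_same, s_same, stride = 1L),
                    c(1, 32, 450))
  expect_error(icbam_residual_block(x1, p[[1]], st[[1]], stride = 3L),
               "stride")
})

test_that("both branch forward passes produce the designed feature widths", {
  model <- fusion_model(seed = 5)
  segs <- matrix(rnorm(3 * 1800), 3)
  f1 <- branch1_forward(segs, model, training = TRUE)
  expect_equal(dim(f1), c(3L, 256L))
  imgs <- array(runif(3 * 100 * 100 * 3) * 255, c(3, 100, 100, 3))
  f2 <- branch2_forward(imgs, model)
  expect_equal(dim(f2), c(3L, 144L))
  probs <- fuse_and_classify(f1, f2, model)
  expect_equal(dim(probs), c(3L, 5L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_error(branch1_forward(matrix(0, 1, 17), model), "1800")
  expect_error(fuse_and_classify(f1[, 1:10, drop = FALSE], f2, model),
               "mismatch")
  # all-zero image through zero weights gives an all-zero feature
  mz <- fusion_model(seed = 1, init = "zeros")
  expect_equal(branch2_forward(array(0, c(1, 100, 100, 3)), mz),
               matrix(0, 1, 144))
})

test_that("every audited layer shape matches the design table", {
  shapes <- audit_shapes()
  expect_equal(shapes$stem[-1], c(64L, 900L))
  expect_equal(shapes$pool[-1], c(64L, 450L))
  expect_equal(shapes$stage1[-1], c(32L, 450L))
  expect_equal(shapes$stage2[-1], c(64L, 225L))
  expect_equal(shapes$stage3[-1], c(128L, 113L))
  expect_equal(shapes$stage4[-1], c(256L, 57L))
  expect_equal(shapes$flatten1, 256L)
  expect_equal(shapes$conv1[-1], c(64L, 94L, 94L))
  expect_equal(shapes$pool1[-1], c(64L, 31L, 31L))
  expect_equal(shapes$conv2[-1], c(32L, 27L, 27L))
  expect_equal(shapes$pool2[-1], c(32L, 9L, 9L))
  expect_equal(shapes$conv3[-1], c(16L, 7L, 7L))
  expect_equal(shapes$adaptive[-1], c(16L, 3L, 3L))
  expect_equal(shapes$flatten2, 144L)
  expect_equal(shapes$fused, 400L)
  expect_equal(shapes$hidden, 200L)
  expect_equal(shapes$classes, 5L)
})

test_that("config invariants reject inconsistent architectures", {
  expect_error(fusion_config(spatial_kernel = 4L), "odd")
  expect_error(fusion_config(stage_channels = c(30L, 64L, 128L, 256L)),
               "divisible")
  cfg <- fusion_config()
  expect_equal(cfg$fused_dim, cfg$feat1_dim + cfg$feat2_dim)
})
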