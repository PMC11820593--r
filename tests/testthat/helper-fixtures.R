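# Shared fixtures: everything is generated in code at test time.

# a short clean all-class record (default 20 s at 360 Hz)
fixture_record <- function(duration_s = 20, seed = 11,
                           class_mix = c(N = 0.4, S = 0.15, V = 0.2,
                                         F = 0.15, Q = 0.1)) {
  generate_clean_record(synth_config(duration_s = duration_s,
                                     class_mix = class_mix,
                                     beat_rate_bpm = 90, seed = seed))
}

# a small ICEEMDAN config that keeps decomposition tests fast
fast_iceemdan <- function(seed = 3) {
  iceemdan_config(ensemble_size = 8L, max_imfs = 10L, seed = seed)
}

# a scaled-down fusion network exercising every layer type
tiny_net_cfg <- function(n_classes = 5L, dropout = 0) {
  fusion_config(input_len = 128L, image_size = 48L,
                stem_channels = 8L, stage_channels = c(8L, 8L, 16L, 16L),
                reduction = 2L, spatial_kernel = 3L,
                conv2d_channels = c(8L, 8L, 4L),
                conv2d_kernels = c(7L, 5L, 3L),
                adaptive2d = 3L, hidden_dim = 16L,
                n_classes = n_classes, dropout = dropout)
}

# labeled toy data matching a scaled-down net: two well-separated classes
# rendered into both the 1-D slices and the image channel
tiny_two_class_data <- function(n_per_class = 10, cfg = tiny_net_cfg(),
                                seed = 21) {
  ecgfusion:::with_seed(seed, {
  n <- 2 * n_per_class
  t_ax <- seq(0, 1, length.out = cfg$input_len)
  segs <- matrix(0, n, cfg$input_len)
  imgs <- array(0, c(n, cfg$image_size, cfg$image_size, 3))
  labs <- rep(c("N", "V"), each = n_per_class)
  for (i in seq_len(n)) {
    f <- if (labs[i] == "N") 3 else 9
    segs[i, ] <- sin(2 * pi * f * t_ax) + rnorm(cfg$input_len, sd = 0.1)
    imgs[i, , , ] <- encode_segment(segs[i, ] * 200,
                                    imaging_config(image_size = cfg$image_size))$rgb
  }
  list(segments = segs, images = imgs, labels = labs)
  })
}

expect_same_shape <- function(x, dims) {
  expect_equal(unname(dim(x)), as.integer(dims))
}
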