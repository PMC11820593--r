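# User-facing forward passes over the network pieces. These wrap the
# internal cached forward/backward machinery with plain array-in /
# array-out interfaces, which is what the architecture-audit tests drive.

#' Channel attention forward pass
#'
#' Per-channel global average and max pooling are summed, passed through
#' the bottleneck MLP (`FC1: C -> C/r`, ReLU, `FC2: C/r -> C`) and a
#' sigmoid; the resulting per-channel weights scale the input, which is
#' then re-added (`F1 = F * Wc + F`). Output shape equals input shape.
#'
#' @param x Array `(B, C, L)` feature map.
#' @param params ICBAM parameter list (see [init_fusion_params()]); only
#'   `fc1`/`fc2` are used.
#' @return Array `(B, C, L)`.
#' @export
channel_attention <- function(x, params) {
  channel_attention_fwd(x, params)$out
}

#' Spatial attention forward pass
#'
#' Across-channel max and mean pooling give two `1 x L` maps, concatenated
#' and convolved (kernel `k`, length-preserving padding), squashed by a
#' sigmoid and multiplied into `f1`; the block input `x0` is re-added
#' (global-feature reuse).
#'
#' @param f1 Array `(B, C, L)`: channel-attention output.
#' @param x0 Array `(B, C, L)`: the block input being reused.
#' @param params ICBAM parameter list; only `sconv` is used.
#' @param k Spatial kernel size (odd).
#' @return Array `(B, C, L)`.
#' @export
spatial_attention <- function(f1, x0, params, k = 7L) {
  spatial_attention_fwd(f1, x0, params, k)$out
}

#' ICBAM residual block forward pass
#'
#' `conv(3, stride, pad 1) -> BN -> ReLU -> ICBAM -> conv(3, 1, pad 1) ->
#' BN -> + shortcut -> ReLU`, with a 1x1 projection shortcut when shape
#' changes. `L_out = floor((L_in + 2 - 3)/stride) + 1`.
#'
#' @param x Array `(B, C_in, L_in)`.
#' @param params Block parameter list from [init_fusion_params()].
#' @param state Block batch-norm state.
#' @param stride 1 or 2.
#' @param k Spatial-attention kernel.
#' @param training Batch-norm mode.
#' @return Array `(B, C_out, L_out)`.
#' @export
icbam_residual_block <- function(x, params, state, stride = 1L, k = 7L,
                                 training = TRUE) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  resblock_fwd(x, params, state, stride, k, training)$out
}

#' 1-D branch forward pass (segment -> 256-vector)
#'
#' @param segments Matrix `(B, input_len)` of raw slices, or a numeric
#'   vector for a single slice.
#' @param model A fitted or initialized model (list with `params`,
#'   `state`, `cfg`).
#' @param training Batch-norm mode. Default `FALSE`.
#' @return Matrix `(B, feat1_dim)`.
#' @export
branch1_forward <- function(segments, model, training = FALSE) {
  x1 <- as_branch1_input(segments, model$cfg)
  branch1_fwd(x1, model$params$branch1, model$state, model$cfg, training)$out
}

#' 2-D branch forward pass (image -> 144-vector)
#'
#' @param images Array `(B, size, size, 3)` (or `(size, size, 3)` for one
#'   image) of 8-bit channel values.
#' @param model A fitted or initialized model.
#' @return Matrix `(B, feat2_dim)`.
#' @export
branch2_forward <- function(images, model) {
  x2 <- as_branch2_input(images, model$cfg)
  branch2_fwd(x2, model$params$branch2, model$cfg)$out
}

#' Fuse branch features and classify
#'
#' Concatenates the two feature vectors (256 + 144 = 400), applies the
#' fully connected head (400 -> 200, ReLU; 200 -> classes) and softmax.
#'
#' @param x1 Matrix `(B, feat1_dim)`.
#' @param x2 Matrix `(B, feat2_dim)`.
#' @param model A fitted or initialized model.
#' @return Matrix `(B, n_classes)` of class probabilities (rows sum to 1).
#' @export
fuse_and_classify <- function(x1, x2, model) {
  cfg <- model$cfg
  if (ncol(x1) != cfg$feat1_dim || ncol(x2) != cfg$feat2_dim)
    stop("feature dimension mismatch")
  hd <- fusion_head_fwd(x1, x2, model$params$fusion, cfg, training = FALSE)
  softmax_probs(hd$out)
}

# input coercion helpers -------------------------------------------------

as_branch1_input <- function(segments, cfg) {
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1)
  if (ncol(segments) != cfg$input_len)
    stop("segments must have ", cfg$input_len, " samples")
  x1 <- array(0, c(nrow(segments), 1L, cfg$input_len))
  x1[, 1L, ] <- segments
  x1
}

# images arrive as (B, H, W, 3) in 0..255; network wants (B, 3, H, W),
# scaled to [0, 1]
as_branch2_input <- function(images, cfg) {
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, c(1L, d))
    d <- dim(images)
  }
  if (d[2] != cfg$image_size || d[3] != cfg$image_size || d[4] != 3L)
    stop("images must be (B, ", cfg$image_size, ", ", cfg$image_size, ", 3)")
  aperm(images, c(1, 4, 2, 3)) / 255
}

#' Create an untrained fusion model
#'
#' @param cfg A [fusion_config()].
#' @param seed Integer seed for weight initialization.
#' @param init `"kaiming"` (default) or `"zeros"`.
#' @return An object of class `ecgfusion_model`: list with `params`,
#'   `state` (batch-norm statistics) and `cfg`.
#' @export
fusion_model <- function(cfg = fusion_config(), seed = 1L, init = "kaiming") {
  ps <- init_fusion_params(cfg, seed, init)
  structure(list(params = ps$params, state = ps$state, cfg = cfg),
            class = "ecgfusion_model")
}

#' @export
print.ecgfusion_model <- function(x, ...) {
  n_par <- tree_reduce_sum(length, x$params)
  cat(sprintf(paste0("<ecgfusion_model> dual-channel classifier: ",
                     "1-D ResNet-ICBAM (len %d -> %d) + 2-D CNN ",
                     "(%dx%dx3 -> %d) -> %d -> %d classes; %s parameters\n"),
              x$cfg$input_len, x$cfg$feat1_dim, x$cfg$image_size,
              x$cfg$image_size, x$cfg$feat2_dim, x$cfg$fused_dim,
              x$cfg$n_classes, format(n_par, big.mark = ",")))
  invisible(x)
}

#' Audit the layer output shapes of the fusion network
#'
#' Runs a probe batch through both branches and returns every
#' intermediate output size, for comparison against the design layer
#' table.
#'
#' @param model An `ecgfusion_model` (default: a fresh one).
#' @return Named list of `dim()` vectors `(B, C, ...)` per layer.
#' @export
audit_shapes <- function(model = fusion_model()) {
  cfg <- model$cfg
  x1 <- array(0, c(1L, 1L, cfg$input_len))
  x2 <- array(0, c(1L, 3L, cfg$image_size, cfg$image_size))
  b1 <- branch1_fwd(x1, model$params$branch1, model$state, cfg, training = TRUE)
  b2 <- branch2_fwd(x2, model$params$branch2, cfg)
  c(b1$cache$shapes,
    list(flatten1 = ncol(b1$out)),
    b2$cache$shapes,
    list(flatten2 = ncol(b2$out),
         fused = cfg$fused_dim, hidden = cfg$hidden_dim,
         classes = cfg$n_classes))
}
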