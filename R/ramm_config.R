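#' Network architecture configuration
#'
#' Describes the residual-attention mixer network: two convolutional
#' branches applied in parallel to the same spectrogram — a residual
#' branch (strided convolutions with identity-shortcut blocks) and an
#' attention branch (strided convolutions followed by a
#' squeeze-and-excitation channel-attention block) — merged and passed
#' to an MLP-Mixer stage, a 1000-unit ReLU feature layer, and a softmax
#' head.
#'
#' Each entry of `residual_widths` adds one stride-2 convolution (in
#' both branches) followed, in the residual branch, by an
#' identity-shortcut block at that width; the spatial side length is
#' divided by `2^length(residual_widths)`. `mixer_patch` is given in
#' input pixels and must be divisible by the total downsampling factor
#' and divide `input_size`.
#'
#' The default configuration has 577,610 learnable parameters and a
#' 1000-unit last-ReLU feature layer.
#'
#' @param input_size Input image side length in pixels.
#' @param input_channels Image channels (1 = grayscale intensity).
#' @param residual_widths Channel widths of the strided stages.
#' @param attention_kind Only `"channel_SE"` (squeeze-and-excitation).
#' @param se_reduction Squeeze bottleneck ratio.
#' @param merge `"concat"` (channel concatenation) or `"add"`.
#' @param mixer_patch Patch side length in input pixels.
#' @param mixer_depth Number of mixer blocks.
#' @param mixer_hidden_dim Per-token channel width after patch embedding.
#' @param mixer_token_dim Hidden width of the token-mixing MLP.
#' @param mixer_channel_dim Hidden width of the channel-mixing MLP.
#' @param feature_dim Width of the last ReLU feature layer.
#' @param n_classes Output classes.
#' @param input_center Subtract each image's mean intensity at the
#'   input (default `TRUE`). Spectrogram images are min-max scaled to
#'   `[0, 1]`, and all-positive inputs produce strongly correlated
#'   first-layer gradients that stall small-batch SGD; per-image
#'   centering removes that pathology without changing the information
#'   content.
#' @return A `ramm_config` list.
#' @export
ramm_config <- function(input_size = 200L, input_channels = 1L,
                        residual_widths = c(16L, 32L),
                        attention_kind = "channel_SE",
                        se_reduction = 4L,
                        merge = c("concat", "add"),
                        mixer_patch = 20L, mixer_depth = 2L,
                        mixer_hidden_dim = 128L,
                        mixer_token_dim = 64L,
                        mixer_channel_dim = 352L,
                        feature_dim = 1000L, n_classes = 2L,
                        input_center = TRUE) {
  merge <- match.arg(merge)
  stopifnot(attention_kind == "channel_SE",
            length(residual_widths) >= 1L, all(residual_widths >= 1L),
            mixer_depth >= 1L, feature_dim >= n_classes, n_classes >= 2L)
  down <- 2L^length(residual_widths)
  if (input_size %% mixer_patch != 0L) {
    stop("input_size (", input_size, ") must be divisible by mixer_patch (",
         mixer_patch, ")")
  }
  if (mixer_patch %% down != 0L || input_size %% down != 0L) {
    stop("input_size and mixer_patch must be divisible by the downsampling ",
         "factor 2^length(residual_widths) = ", down)
  }
  structure(list(
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    residual_widths = as.integer(residual_widths),
    attention_kind = attention_kind,
    se_reduction = as.integer(se_reduction),
    merge = merge,
    mixer_patch = as.integer(mixer_patch),
    mixer_depth = as.integer(mixer_depth),
    mixer_hidden_dim = as.integer(mixer_hidden_dim),
    mixer_token_dim = as.integer(mixer_token_dim),
    mixer_channel_dim = as.integer(mixer_channel_dim),
    feature_dim = as.integer(feature_dim),
    n_classes = as.integer(n_classes),
    input_center = isTRUE(input_center)
  ), class = "ramm_config")
}

# Derived shapes shared by build/forward/backward.
.ramm_shapes <- function(cfg) {
  down <- 2L^length(cfg$residual_widths)
  map_size <- cfg$input_size %/% down
  patch <- cfg$mixer_patch %/% down
  grid <- map_size %/% patch
  w_last <- cfg$residual_widths[length(cfg$residual_widths)]
  merged_c <- if (cfg$merge == "concat") 2L * w_last else w_last
  list(map_size = map_size, patch = patch, n_tokens = grid * grid,
       patch_dim = patch * patch * merged_c, merged_c = merged_c,
       branch_c = w_last)
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum (SGDM) and cross-entropy
#' loss, the study's training regime. The momentum coefficient defaults
#' to the conventional 0.9.
#'
#' @param learning_rate Step size (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         epochs = 50L, batch_size = 16L, seed = 1L) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            epochs >= 1L, batch_size >= 1L)
  structure(list(optimizer = "sgd_momentum", loss = "cross_entropy",
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}
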