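#' Model and training configuration
#'
#' Collects every architecture and training hyperparameter of the network in
#' one validated list.  The defaults are the tuned settings of the full model:
#' batch size 128, 128 output channels, attention reduction ratio 4, three
#' downsampling residual blocks, and contrastive margin 2.
#'
#' @param L_max maximum (padded) sequence length in nucleotides.
#' @param embed_dim width of the learned base embedding.
#' @param out_channel number of feature channels `C` carried through the
#'   multi-kernel fusion module; must be divisible by 4 (one quarter per
#'   kernel path) and by `reduction_ratio`.
#' @param gamma,b hyperparameters of the adaptive attention kernel size
#'   \eqn{k_{adp} = | \log_2(C)/\gamma + b/\gamma |_{odd}}.
#' @param reduction_ratio channel reduction ratio `r` of the local spatial
#'   attention bottleneck.
#' @param kernel_sizes convolution kernel sizes of the three conv paths
#'   (the fourth path pools); all odd.
#' @param pool_kernel max-pool kernel used by the fourth path and the
#'   downsampling blocks.
#' @param n_dr_blocks number of downsampling residual blocks.
#' @param dr_pool_stride stride of the downsampling max-pool; with the
#'   defaults the positions axis shrinks 800 -> 400 -> 200 -> 100.
#' @param margin margin `M` of the contrastive loss.
#' @param threshold decision threshold on the predicted probability; a
#'   probability >= threshold is called positive.
#' @param batch_size minibatch size for training.
#' @param seed integer seed controlling weight initialisation and every other
#'   source of randomness derived from it.
#' @param use_mkff,use_drfe,use_cl ablation switches: drop the multi-kernel
#'   fusion module, the downsampling residual module, or the contrastive
#'   loss term.
#' @param fusion_mode how the attention branches are fused: `"gldf"`
#'   (concatenate global and local branches, the full model), `"cat"`
#'   (skip attention, use the concatenated multi-kernel features directly),
#'   `"add"` (sum the two branches), `"global"` or `"local"` (single branch).
#' @param kernel_combo subset of `c("k1","k2","k3","k4")` naming which kernel
#'   paths are active.
#' @param softmax_axis axis of the spatial-attention softmax: `"positions"`
#'   (default, per channel) or `"channels"` (per position).
#' @param ambiguous_policy `"strict"` rejects non-ACGT bases;
#'   `"map_to_pad"` encodes them as the padding code 0 with a warning.
#' @param padding_side `"left"` (default) or `"right"` padding of short
#'   sequences.
#' @param truncate `"error"` (default) rejects sequences longer than `L_max`;
#'   `"center"` keeps the central `L_max` bases.
#' @param lr,epochs,patience Adam learning rate, maximum training epochs and
#'   early-stopping patience (epochs without validation-AUC improvement).
#' @param pair_mode contrastive pair construction: `"shuffle"` (seeded random
#'   disjoint pairs, the default) or `"all"` (every pair in the batch).
#' @param saliency_norm aggregation of the embedding gradient per position:
#'   `"l2"` (default) or `"abs"`.
#'
#' @return a list of class `m6a_config`.
#' @export
m6a_config <- function(L_max = 800L, embed_dim = 64L, out_channel = 128L,
                       gamma = 2, b = 1, reduction_ratio = 4L,
                       kernel_sizes = c(1L, 3L, 5L), pool_kernel = 3L,
                       n_dr_blocks = 3L, dr_pool_stride = 2L,
                       margin = 2, threshold = 0.5, batch_size = 128L,
                       seed = 1L,
                       use_mkff = TRUE, use_drfe = TRUE, use_cl = TRUE,
                       fusion_mode = c("gldf", "cat", "add", "global", "local"),
                       kernel_combo = c("k1", "k2", "k3", "k4"),
                       softmax_axis = c("positions", "channels"),
                       ambiguous_policy = c("strict", "map_to_pad"),
                       padding_side = c("left", "right"),
                       truncate = c("error", "center"),
                       lr = 1e-3, epochs = 50L, patience = 5L,
                       pair_mode = c("shuffle", "all"),
                       saliency_norm = c("l2", "abs")) {
  cfg <- list(
    L_max = as.integer(L_max), vocab = 5L, embed_dim = as.integer(embed_dim),
    out_channel = as.integer(out_channel), gamma = gamma, b = b,
    reduction_ratio = as.integer(reduction_ratio),
    kernel_sizes = as.integer(kernel_sizes),
    pool_kernel = as.integer(pool_kernel),
    n_dr_blocks = as.integer(n_dr_blocks),
    dr_pool_stride = as.integer(dr_pool_stride),
    margin = margin, threshold = threshold,
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    use_mkff = isTRUE(use_mkff), use_drfe = isTRUE(use_drfe),
    use_cl = isTRUE(use_cl),
    fusion_mode = match.arg(fusion_mode),
    kernel_combo = kernel_combo,
    softmax_axis = match.arg(softmax_axis),
    ambiguous_policy = match.arg(ambiguous_policy),
    padding_side = match.arg(padding_side),
    truncate = match.arg(truncate),
    lr = lr, epochs = as.integer(epochs), patience = as.integer(patience),
    pair_mode = match.arg(pair_mode),
    saliency_norm = match.arg(saliency_norm))
  class(cfg) <- "m6a_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$L_max >= 1L, cfg$embed_dim >= 1L, cfg$out_channel >= 4L)
  if (cfg$out_channel %% 4L != 0L)
    stop("out_channel must be divisible by 4 (one quarter per kernel path)")
  if (cfg$out_channel %% cfg$reduction_ratio != 0L)
    stop("out_channel must be divisible by reduction_ratio")
  if (any(cfg$kernel_sizes %% 2L == 0L) || any(cfg$kernel_sizes < 1L))
    stop("all kernel sizes must be odd and positive")
  if (!length(cfg$kernel_combo))
    stop("kernel_combo must name at least one of k1..k4")
  if (!all(cfg$kernel_combo %in% c("k1", "k2", "k3", "k4")))
    stop("kernel_combo entries must be among k1, k2, k3, k4")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  if (cfg$margin <= 0) stop("margin must be positive")
  if (cfg$n_dr_blocks < 0L) stop("n_dr_blocks must be >= 0")
  # each DR block maps L -> floor((L + 2 - pool_kernel)/stride) + 1
  L <- cfg$L_max
  for (i in seq_len(cfg$n_dr_blocks)) {
    if (L < cfg$pool_kernel)
      stop("positions axis (", L, ") collapses below the pool kernel at ",
           "DR block ", i, "; use fewer blocks or a smaller stride")
    L <- dr_out_length(L, cfg$pool_kernel, cfg$dr_pool_stride)
  }
  invisible(cfg)
}

# output length of one pooled downsampling step (pad 1, kernel k, stride s)
dr_out_length <- function(L, k, s) as.integer((L + 2L - k) %/% s + 1L)

#' Adaptive attention kernel size
#'
#' Channel-count-dependent kernel width for the global channel-attention
#' convolution: the largest odd integer not exceeding
#' \eqn{| \log_2(C)/\gamma + b/\gamma |}, with a floor of 1.
#'
#' @param C number of channels (>= 1).
#' @param gamma,b positive hyperparameters (defaults 2 and 1).
#' @return an odd positive integer.
#' @examples
#' adaptive_kernel_size(128) # 3
#' @export
adaptive_kernel_size <- function(C, gamma = 2, b = 1) {
  if (!is.numeric(C) || length(C) != 1L || C < 1)
    stop("C must be a single value >= 1")
  if (gamma <= 0) stop("gamma must be positive")
  x <- abs(log2(C) / gamma + b / gamma)
  k <- floor(x)
  if (k %% 2 == 0) k <- k - 1          # round down to the nearest odd
  max(1L, as.integer(k))
}
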