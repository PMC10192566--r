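#' Architecture configuration for the two modality branches
#'
#' The EEG branch is a bidirectional LSTM reading the window time axis (one
#' channel vector per step) followed by four 1-D convolution blocks; the ECG
#' branch is five 2-D convolution blocks over the scalogram image. Each
#' branch ends in a two-layer fully connected classifier head, and each
#' episode discriminator is a two-layer fully connected head on the branch
#' features.
#'
#' @param lstm_hidden hidden units per LSTM direction.
#' @param conv1d_channels length-4 integer vector of 1-D conv channels.
#' @param conv2d_channels length-5 integer vector of 2-D conv channels.
#' @param fc_sizes length-2 vector: hidden width and output width of every
#'   fully connected head (output forced to `n_classes` /
#'   `n_episode_classes` at build time).
#' @param feature_dim dimension of the branch feature vector.
#' @param n_classes number of class labels (2: interictal/preictal).
#' @param n_episode_classes number of episode labels the discriminators see;
#'   set per cross-validation fold.
#' @param grl_on whether discriminators are attached through gradient
#'   reversal during training.
#' @param dropout dropout rate in the classifier heads.
#' @return Object of class `branch_config`.
#' @export
branch_config <- function(lstm_hidden = 64L, conv1d_channels = c(32L, 32L, 64L, 64L),
                          conv2d_channels = c(8L, 16L, 32L, 64L, 64L),
                          fc_sizes = c(64L, 2L), feature_dim = 128L,
                          n_classes = 2L, n_episode_classes = 2L,
                          grl_on = TRUE, dropout = 0.2) {
  cfg <- list(lstm_hidden = as.integer(lstm_hidden),
              conv1d_channels = as.integer(conv1d_channels),
              conv2d_channels = as.integer(conv2d_channels),
              fc_sizes = as.integer(fc_sizes),
              feature_dim = as.integer(feature_dim),
              n_classes = as.integer(n_classes),
              n_episode_classes = as.integer(n_episode_classes),
              grl_on = isTRUE(grl_on), dropout = dropout)
  if (length(cfg$conv1d_channels) != 4L) {
    stop("branch_config: conv1d_channels must have length 4 (four 1-D conv layers)")
  }
  if (length(cfg$conv2d_channels) != 5L) {
    stop("branch_config: conv2d_channels must have length 5 (five 2-D conv layers)")
  }
  if (length(cfg$fc_sizes) != 2L) {
    stop("branch_config: fc_sizes must have length 2 (two fully connected layers)")
  }
  if (cfg$lstm_hidden < 1L || cfg$feature_dim < 1L) {
    stop("branch_config: lstm_hidden and feature_dim must be >= 1")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    stop("branch_config: dropout must be in [0, 1)")
  }
  class(cfg) <- "branch_config"
  cfg
}

# (n, C, T) -> (n, T, C) so the Bi-LSTM consumes time steps of channel
# vectors; also centers the [0, 1]-normalized input (zero-mean inputs keep
# the LSTM gates out of saturation at initialization).
layer_permute_tc <- function(center = 0.5) {
  L <- new_layer("permute_tc")
  L$center <- center
  L$forward <- function(x, train = FALSE) aperm(x - L$center, c(1L, 3L, 2L))
  L$backward <- function(g) aperm(g, c(1L, 3L, 2L))
  L
}

build_head <- function(n_in, hidden, n_out, dropout) {
  list(layer_dense(n_in, hidden), layer_relu(), layer_dropout(dropout),
       layer_dense(hidden, n_out), layer_softmax())
}

#' Build the EEG branch (Bi-LSTM + 1-D CNN)
#'
#' The feature extractor reads a window as a time series of channel vectors
#' through a bidirectional LSTM, feeds the hidden sequence to four 1-D
#' convolution blocks (kernel 3, ReLU, max-pool 2), and projects the
#' flattened output to `feature_dim`. The head is a two-layer fully
#' connected classifier emitting class probabilities.
#'
#' @param cfg a [branch_config()].
#' @param n_channels,n_samples input window shape (channels x samples).
#' @return List of class `szfuse_branch` with elements `extractor` and
#'   `head` (layer lists), plus shape bookkeeping.
#' @export
build_eeg_branch <- function(cfg, n_channels, n_samples) {
  ch <- cfg$conv1d_channels
  len <- n_samples
  layers <- list(layer_permute_tc(),
                 layer_bilstm(n_channels, cfg$lstm_hidden))
  in_ch <- 2L * cfg$lstm_hidden
  for (k in seq_along(ch)) {
    layers <- c(layers, list(layer_conv1d(in_ch, ch[k]), layer_relu(),
                             layer_maxpool1d()))
    in_ch <- ch[k]
    len <- len %/% 2L
    if (len < 1L) stop("build_eeg_branch: window too short for four pooling stages")
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(in_ch * len, cfg$feature_dim),
                           layer_batchnorm(cfg$feature_dim),
                           layer_relu()))
  structure(list(extractor = layers,
                 head = build_head(cfg$feature_dim, cfg$fc_sizes[1L],
                                   cfg$n_classes, cfg$dropout),
                 cfg = cfg, input_shape = c(n_channels, n_samples),
                 modality = "eeg"),
            class = "szfuse_branch")
}

#' Build the ECG branch (2-D CNN over scalograms)
#'
#' Five 2-D convolution blocks (kernel 3x3, ReLU, 2x2 max-pool whenever a
#' spatial axis still has at least two elements) over the scalogram treated
#' as a one-channel image, flattened and projected to `feature_dim`, with
#' the same two-layer fully connected head as the EEG branch.
#'
#' @param cfg a [branch_config()].
#' @param n_scales,n_time scalogram shape (scales x pooled time).
#' @return `szfuse_branch`, as [build_eeg_branch()].
#' @export
build_ecg_branch <- function(cfg, n_scales, n_time) {
  ch <- cfg$conv2d_channels
  H <- n_scales; W <- n_time
  layers <- list(layer_expand_image())
  in_ch <- 1L
  for (k in seq_along(ch)) {
    layers <- c(layers, list(layer_conv2d(in_ch, ch[k]), layer_relu(),
                             layer_maxpool2d()))
    in_ch <- ch[k]
    if (H >= 2L) H <- H %/% 2L
    if (W >= 2L) W <- W %/% 2L
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(in_ch * H * W, cfg$feature_dim),
                           layer_batchnorm(cfg$feature_dim),
                           layer_relu()))
  structure(list(extractor = layers,
                 head = build_head(cfg$feature_dim, cfg$fc_sizes[1L],
                                   cfg$n_classes, cfg$dropout),
                 cfg = cfg, input_shape = c(n_scales, n_time),
                 modality = "ecg"),
            class = "szfuse_branch")
}

#' Build an episode discriminator head
#'
#' Two fully connected layers mapping branch features to a probability
#' distribution over the training episodes of the current fold.
#'
#' @param cfg a [branch_config()]; uses `feature_dim`, `fc_sizes[1]` and
#'   `n_episode_classes`.
#' @return Layer list.
#' @export
build_discriminator <- function(cfg) {
  list(layer_dense(cfg$feature_dim, cfg$fc_sizes[1L]), layer_relu(),
       layer_dense(cfg$fc_sizes[1L], cfg$n_episode_classes), layer_softmax())
}

#' Gradient reversal connector
#'
#' Identity in the forward pass; multiplies the back-propagated gradient by
#' `-lambda`. Placed between a feature extractor and its episode
#' discriminator it turns the discriminator's learning signal into feature
#' confusion pressure.
#'
#' @param lambda nonnegative reversal strength (default 1; the adversarial
#'   trade-off weight lives in the loss, not here).
#' @return A layer object with `$forward(x)` and `$backward(g)`.
#' @export
gradient_reversal <- function(lambda = 1) {
  if (lambda < 0) stop("gradient_reversal: lambda must be >= 0")
  layer_grl(lambda)
}

#' Compact architecture and training settings for CPU-scale experiments
#'
#' The full-scale architecture widths target GPU-scale training; these
#' reduced settings keep the same topology (Bi-LSTM + four 1-D conv blocks,
#' five 2-D conv blocks, two-layer heads) at widths and a schedule that a
#' single CPU core trains in seconds per fold, and are the configuration
#' used throughout the package's experiments on the bundled synthetic
#' patients (64 Hz, 8 channels).
#'
#' @param feature_dim branch feature dimension (default 16; the tight
#'   bottleneck also makes episode-marginal feature alignment effective).
#' @return `compact_branch_config()`: a [branch_config()];
#'   `compact_train_config(...)`: a [train_config()] with 20 epochs, batch
#'   16, Adam 0.003.
#' @export
compact_branch_config <- function(feature_dim = 16L) {
  branch_config(lstm_hidden = 8L, conv1d_channels = c(8L, 8L, 16L, 16L),
                conv2d_channels = c(4L, 4L, 8L, 8L, 16L),
                fc_sizes = c(16L, 2L), feature_dim = feature_dim)
}

#' @rdname compact_branch_config
#' @param ... overrides passed to [train_config()].
#' @export
compact_train_config <- function(...) {
  args <- utils::modifyList(list(epochs = 20L, batch_size = 16L, lr = 0.003),
                            list(...))
  do.call(train_config, args)
}

#' Run a branch on a batch of windows
#'
#' @param branch an `szfuse_branch`.
#' @param x input batch (EEG: n x channels x samples; ECG: n x scales x time).
#' @param train logical; enables dropout.
#' @return List with `features` (n x feature_dim) and `prob`
#'   (n x n_classes, rows summing to 1).
#' @export
branch_forward <- function(branch, x, train = FALSE) {
  f <- net_forward(branch$extractor, x, train = train)
  list(features = f, prob = net_forward(branch$head, f, train = train))
}

#' Count the trainable parameters of a branch or layer list
#'
#' @param x an `szfuse_branch` or a plain layer list.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "szfuse_branch")) {
    return(net_n_params(x$extractor) + net_n_params(x$head))
  }
  net_n_params(x)
}
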