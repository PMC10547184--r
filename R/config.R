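#' Encoder configuration
#'
#' The encoder is a classic UNet contracting path: at each level two 3x3
#' same-padding convolutions with ReLU, then 2x2 max pooling with stride 2.
#' Channel width doubles per level up to `channel_cap`; dropout is applied at
#' the deepest level only.
#'
#' @param levels number of resolutions (the default 7 means 6 poolings)
#' @param base_channels channels at the first level
#' @param channel_cap maximum channels at any level
#' @param dropout_rate dropout probability at the bottleneck and inside
#'   gating units (disabled in eval mode)
#' @return an `encoder_config` list
#' @export
encoder_config <- function(levels = 7L, base_channels = 64L,
                           channel_cap = 512L, dropout_rate = 0.5) {
  stopifnot(levels >= 3, base_channels >= 8, channel_cap >= base_channels,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap),
                 dropout_rate = dropout_rate),
            class = "encoder_config")
}

#' Cross-scale feature integration (CSFI) configuration
#'
#' A stack of `n_layers` bidirectional weighted-fusion pyramid layers over a
#' contiguous subset of encoder levels, each fusion node carrying its own
#' learnable non-negative scalar weights.
#'
#' @param n_layers number of stacked bidirectional layers
#' @param fpn_channels working width after the lateral 1x1 projections
#' @param levels_used contiguous pyramid levels fed to the fusion stack
#' @return a `csfi_config` list
#' @export
csfi_config <- function(n_layers = 3L, fpn_channels = 64L,
                        levels_used = 3:7) {
  levels_used <- sort(as.integer(levels_used))
  stopifnot(n_layers >= 1, fpn_channels >= 4, length(levels_used) >= 2)
  if (!all(diff(levels_used) == 1L)) {
    stop("levels_used must be contiguous, got: ",
         paste(levels_used, collapse = ", "))
  }
  structure(list(n_layers = as.integer(n_layers),
                 fpn_channels = as.integer(fpn_channels),
                 levels_used = levels_used),
            class = "csfi_config")
}

#' Wide context unit (WCU) configuration
#'
#' Two parallel compositions of orthogonal 1-D convolutions
#' (Nx1 then 1xN, and 1xN then Nx1), summed; each branch has an NxN
#' effective receptive field at the cost of 1-D kernels.
#'
#' @param kernel_extent odd 1-D kernel length N (>= 3)
#' @return a `wcu_config` list
#' @export
wcu_config <- function(kernel_extent = 7L) {
  kernel_extent <- as.integer(kernel_extent)
  if (kernel_extent %% 2L == 0L || kernel_extent < 3L) {
    stop("kernel_extent must be odd and >= 3, got ", kernel_extent)
  }
  structure(list(kernel_extent = kernel_extent), class = "wcu_config")
}

#' Loss configuration for the two decoder heads
#'
#' The segmentation head is trained with focal Tversky + w_seg * (Dice + BCE);
#' the boundary head with focal Tversky + w_bou * combo loss. Both composite
#' weights default to 0.4, the best-performing setting of the model's loss
#' ablation; the smoothness constant E defaults to 1e-3.
#'
#' @param w_seg weight on (Dice + BCE) in the segmentation head
#' @param w_bou weight on the combo loss in the boundary head
#' @param E smoothness constant in Dice/Tversky denominators
#' @param alpha_ft,beta_ft Tversky false-positive / false-negative weights
#' @param gamma_ft focal exponent (loss is (1 - TI)^(1/gamma_ft))
#' @param alpha_combo,beta_combo combo-loss CE/Dice mix and class weight
#' @param head_balance weight of the boundary-head loss in the total
#' @return a `loss_config` list
#' @export
loss_config <- function(w_seg = 0.4, w_bou = 0.4, E = 1e-3,
                        alpha_ft = 0.3, beta_ft = 0.7, gamma_ft = 4 / 3,
                        alpha_combo = 0.5, beta_combo = 0.5,
                        head_balance = 1.0) {
  stopifnot(w_seg >= 0, w_bou >= 0, E > 0, gamma_ft > 0,
            alpha_ft >= 0, beta_ft >= 0,
            alpha_combo >= 0, alpha_combo <= 1,
            beta_combo >= 0, beta_combo <= 1, head_balance >= 0)
  structure(list(w_seg = w_seg, w_bou = w_bou, E = E,
                 alpha_ft = alpha_ft, beta_ft = beta_ft, gamma_ft = gamma_ft,
                 alpha_combo = alpha_combo, beta_combo = beta_combo,
                 head_balance = head_balance),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: SGD with learning rate
#' 0.001, momentum 0.9, weight decay 5e-4, batch size 10, batch-norm
#' running-statistics momentum 0.99, random 256-pixel training crops,
#' 512-pixel evaluation size, and an 80/10/10 train/val/test split.
#'
#' @param learning_rate,momentum,weight_decay SGD hyper-parameters
#' @param batch_size images per optimizer step
#' @param bn_momentum batch-norm running-statistics momentum
#' @param train_crop square crop side used during training
#' @param eval_size square side used at prediction time
#' @param max_epochs maximum number of epochs (required)
#' @param early_stop_patience epochs without validation-Dice improvement
#'   tolerated before stopping (0 stops after the first epoch)
#' @param split train/val/test fractions summing to 1
#' @param seed RNG seed for cropping, augmentation and shuffling
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 5e-4, batch_size = 10L,
                         bn_momentum = 0.99, train_crop = 256L,
                         eval_size = 512L, max_epochs,
                         early_stop_patience = 15L,
                         split = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            weight_decay >= 0, batch_size >= 1,
            bn_momentum >= 0, bn_momentum < 1,
            train_crop >= 8, eval_size >= 8, max_epochs >= 1,
            early_stop_patience >= 0, length(split) == 3)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 bn_momentum = bn_momentum,
                 train_crop = as.integer(train_crop),
                 eval_size = as.integer(eval_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}
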