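# layer constructors ---------------------------------------------------

l_conv <- function(in_ch, out_ch, trainable = TRUE) {
  list(type = "conv",
       W = matrix(rnorm(out_ch * in_ch * 9, sd = sqrt(2 / (in_ch * 9))),
                  out_ch, in_ch * 9),
       b = rep(0, out_ch), trainable = trainable)
}
l_bn <- function(ch) list(type = "bn", gamma = rep(1, ch), beta = rep(0, ch),
                          rmean = rep(0, ch), rvar = rep(1, ch),
                          trainable = TRUE)
l_relu <- function() list(type = "relu")
l_pool <- function() list(type = "pool")
l_zeropad <- function(t, b, l, r) list(type = "zeropad",
                                       pad = as.integer(c(t, b, l, r)))
l_flatten <- function() list(type = "flatten")
l_linear <- function(in_dim, out_dim, trainable = TRUE) {
  list(type = "linear",
       W = matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                  out_dim, in_dim),
       b = rep(0, out_dim), trainable = trainable)
}

new_branch <- function(layers, tap, input_shape, name, backbone_end = NULL) {
  structure(list(layers = layers, tap = tap, input_shape = input_shape,
                 name = name, backbone_end = backbone_end),
            class = "dot_cnn")
}

#' @export
print.dot_cnn <- function(x, ...) {
  cat(sprintf("<dot_cnn '%s'>: %d layers, input %s, feature tap after layer %d\n",
              x$name, length(x$layers),
              paste(x$input_shape, collapse = "x"), x$tap))
  invisible(x)
}

# VGG-11 feature stack (convolution widths 64,128,256,256,512,512,512,512
# with five 2x2 poolings); 224 input -> 512 x 7 x 7
vgg11_features <- function() {
  list(l_conv(3, 64), l_relu(), l_pool(),
       l_conv(64, 128), l_relu(), l_pool(),
       l_conv(128, 256), l_relu(), l_conv(256, 256), l_relu(), l_pool(),
       l_conv(256, 512), l_relu(), l_conv(512, 512), l_relu(), l_pool(),
       l_conv(512, 512), l_relu(), l_conv(512, 512), l_relu(), l_pool())
}

#' US image classification branch
#'
#' Truncated VGG-11 feature extractor (ending in the 512 x 7 x 7 tensor),
#' zero-padding to 512 x 8 x 8, a 3 x 3 convolution with batch
#' normalisation producing the 64 x 8 x 8 feature tap, and three fully
#' connected layers giving the malignancy probability. The first nine
#' layers (counting each convolution, activation and pooling as one
#' layer) are frozen: their weights are never updated by training.
#' Pretrained natural-image backbone weights can be supplied; without
#' them the backbone keeps its random initialisation and only fine-tuning
#' shapes the classifier.
#'
#' @param seed Integer seed for weight initialisation.
#' @param pretrained Optional list of `layers` to copy backbone weights
#'   from (same architecture).
#' @return A `dot_cnn` branch; input 224 x 224 x 3.
#' @export
us_branch <- function(seed = 1, pretrained = NULL) {
  set.seed(seed)
  feat <- vgg11_features()
  # shape audit: five poolings halve 224 down to 7
  stopifnot(224 / 2^5 == 7)
  if (!is.null(pretrained))
    for (i in seq_along(feat))
      if (!is.null(pretrained[[i]]$W)) {
        stopifnot(all(dim(pretrained[[i]]$W) == dim(feat[[i]]$W)))
        feat[[i]]$W <- pretrained[[i]]$W
        feat[[i]]$b <- pretrained[[i]]$b
      }
  for (i in 1:9) if (!is.null(feat[[i]]$trainable))
    feat[[i]]$trainable <- FALSE
  head <- list(l_zeropad(0, 1, 0, 1),       # 512x7x7 -> 512x8x8
               l_conv(512, 64), l_bn(64), l_relu(),
               l_flatten(),
               l_linear(64 * 8 * 8, 256), l_relu(),
               l_linear(256, 64), l_relu(),
               l_linear(64, 2))
  new_branch(c(feat, head), tap = length(feat) + 4,
             input_shape = c(224, 224, 3), name = "us",
             backbone_end = length(feat))
}

#' DOT histogram classification branch
#'
#' Two (3 x 3 convolution + batch norm + 2 x 2 max pool) blocks taking
#' the 1 x 32 x 32 histogram to the 64 x 8 x 8 feature tap, one further
#' 3 x 3 convolution, and two fully connected layers.
#'
#' @param seed Integer seed for weight initialisation.
#' @return A `dot_cnn` branch; input 32 x 32 x 1.
#' @export
hist_branch <- function(seed = 1) {
  set.seed(seed)
  layers <- list(l_conv(1, 32), l_bn(32), l_relu(), l_pool(),
                 l_conv(32, 64), l_bn(64), l_relu(), l_pool(),
                 l_conv(64, 64), l_bn(64), l_relu(),
                 l_flatten(), l_linear(64 * 8 * 8, 128), l_relu(),
                 l_linear(128, 2))
  new_branch(layers, tap = 8, input_shape = c(32, 32, 1), name = "hist")
}

#' DOT reconstructed-image classification branch
#'
#' Three 3 x 3 convolutions with batch normalisation (the first two
#' followed by 2 x 2 max pooling, so the 3 x 32 x 32 tHb map reaches the
#' 64 x 8 x 8 feature tap after the second block) and two fully connected
#' layers.
#'
#' @param seed Integer seed for weight initialisation.
#' @return A `dot_cnn` branch; input 32 x 32 x 3.
#' @export
img_branch <- function(seed = 1) {
  set.seed(seed)
  layers <- list(l_conv(3, 32), l_bn(32), l_relu(), l_pool(),
                 l_conv(32, 64), l_bn(64), l_relu(), l_pool(),
                 l_conv(64, 64), l_bn(64), l_relu(),
                 l_flatten(), l_linear(64 * 8 * 8, 128), l_relu(),
                 l_linear(128, 2))
  new_branch(layers, tap = 8, input_shape = c(32, 32, 3), name = "img")
}

#' Second-stage fusion classifier
#'
#' Takes the channel-concatenation of the three 64 x 8 x 8 branch feature
#' maps (192 x 8 x 8), applies one 3 x 3 convolution with batch
#' normalisation and two fully connected layers.
#'
#' @param seed Integer seed for weight initialisation.
#' @return A `dot_cnn` head; input 8 x 8 x 192.
#' @export
fusion_head <- function(seed = 1) {
  set.seed(seed)
  layers <- list(l_conv(192, 64), l_bn(64), l_relu(),
                 l_flatten(), l_linear(64 * 8 * 8, 128), l_relu(),
                 l_linear(128, 2))
  new_branch(layers, tap = 3, input_shape = c(8, 8, 192), name = "fusion")
}

check_input <- function(branch, x) {
  d <- dim(x)
  if (length(d) == 3L) { x <- array(x, c(d, 1)); d <- dim(x) }
  if (length(d) != 4L || !all(d[1:3] == branch$input_shape))
    stop(sprintf("branch '%s' expects input %s, got %s", branch$name,
                 paste(branch$input_shape, collapse = "x"),
                 paste(d[1:3], collapse = "x")))
  x
}

#' Predict malignancy probabilities
#'
#' Evaluation-mode forward pass (batch statistics frozen); deterministic.
#'
#' @param branch A `dot_cnn`.
#' @param x Input array dim (H, W, C, N) matching the branch input shape.
#' @return Numeric vector of malignancy probabilities in `[0, 1]`.
#' @export
nn_predict <- function(branch, x) {
  x <- check_input(branch, x)
  out <- cpp_nn_forward(branch$layers, as.numeric(x), dim(x), 0L)
  out$prob[, 2]
}

#' Extract the 64 x 8 x 8 feature maps of a branch
#'
#' Evaluation-mode features at the branch's tap layer (before the fully
#' connected classifier), the representation consumed by the fusion head.
#'
#' @param branch A `dot_cnn`.
#' @param x Input array dim (H, W, C, N).
#' @return Array dim (8, 8, 64, N).
#' @export
extract_features <- function(branch, x) {
  x <- check_input(branch, x)
  out <- cpp_nn_forward(branch$layers, as.numeric(x), dim(x),
                        as.integer(branch$tap))
  out$tap
}

#' Train a branch with an explicit phase schedule
#'
#' Softmax cross-entropy training. Each phase is a list with `epochs`,
#' `lr`, `optimizer` ("sgd" or "adam"), optional `momentum` and `cosine`
#' (per-phase cosine annealing of the learning rate). Layers marked
#' non-trainable are left bit-identical.
#'
#' @param branch A `dot_cnn`.
#' @param x Input array (H, W, C, N); `y` integer/factor labels with two
#'   classes (1 = malignant).
#' @param y Labels: 0/1 vector, logical, or factor with levels
#'   benign/malignant.
#' @param phases List of phase lists.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling shuffling.
#' @return The trained branch, with `loss` (per-epoch mean training
#'   loss) and `lr` (per-epoch learning rate) attached.
#' @export
nn_train <- function(branch, x, y, phases, batch_size = 16, seed = 1) {
  x <- check_input(branch, x)
  y <- as_label(y)
  if (length(unique(y)) < 2L)
    stop("training requires both classes to be present")
  if (length(y) != dim(x)[4]) stop("label length does not match inputs")
  res <- cpp_nn_train(branch$layers, as.numeric(x), dim(x),
                      as.integer(y), phases, as.integer(batch_size),
                      as.integer(seed))
  branch$layers <- res$layers
  branch$loss <- res$loss
  branch$lr <- res$lr
  branch
}

as_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) y <- as.integer(y == "malignant")
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be benign/malignant (0/1)")
  as.integer(y)
}

# default schedules ----------------------------------------------------

schedule_us <- function() list(
  list(epochs = 5, lr = 1e-3, optimizer = "sgd", momentum = 0.9),
  list(epochs = 5, lr = 1e-4, optimizer = "sgd", momentum = 0.9))

schedule_hist <- function() list(
  list(epochs = 20, lr = 1e-4, optimizer = "adam", cosine = TRUE))

schedule_img <- function(pretrain = TRUE) list(
  list(epochs = if (pretrain) 60 else 10, lr = 1e-3, optimizer = "adam",
       cosine = TRUE))

schedule_fusion <- function() list(
  list(epochs = 30, lr = 1e-3, optimizer = "adam", cosine = TRUE))

#' Fine-tune the US branch
#'
#' Two-phase stochastic gradient descent with momentum 0.9: 5 epochs at
#' learning rate 1e-3 then 5 epochs at 1e-4. The frozen prefix (first
#' nine layers) is left untouched.
#'
#' @param branch A [us_branch()].
#' @param x Preprocessed images (224, 224, 3, N); `y` labels.
#' @inheritParams nn_train
#' @return Trained branch with loss history attached.
#' @export
train_us_branch <- function(branch, x, y, seed = 1, batch_size = 16)
  nn_train(branch, x, y, schedule_us(), batch_size, seed)

#' Cache the frozen-backbone output of the US branch
#'
#' Runs images through the convolutional feature stack only, returning
#' the 512 x 7 x 7 tensors. Because the backbone carries no batch
#' normalisation, these features are training-invariant whenever the
#' backbone weights are, and can be cached once per image.
#'
#' @param branch A [us_branch()].
#' @param x Preprocessed images (224, 224, 3, N).
#' @param chunk Number of images per forward chunk (memory control).
#' @return Array dim (7, 7, 512, N).
#' @export
us_backbone_features <- function(branch, x, chunk = 16) {
  x <- check_input(branch, x)
  n <- dim(x)[4]
  bb <- c(branch$layers[seq_len(branch$backbone_end)],
          list(l_flatten(), l_linear(1, 1)))  # dummy head for the engine
  bb[[length(bb)]]$W <- matrix(0, 2, 512 * 7 * 7)
  bb[[length(bb)]]$b <- c(0, 0)
  out <- array(0, c(7, 7, 512, n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    xi <- x[, , , s:e, drop = FALSE]
    f <- cpp_nn_forward(bb, as.numeric(xi), dim(xi),
                        as.integer(branch$backbone_end))
    out[, , , s:e] <- f$tap
  }
  out
}

#' View of the trainable head of the US branch
#'
#' The layers above the frozen backbone as a standalone network taking
#' cached 512 x 7 x 7 backbone features. Training this view and writing
#' it back with [us_set_head()] is equivalent to training the full
#' branch with the whole backbone frozen.
#'
#' @param branch A [us_branch()].
#' @return A `dot_cnn` over inputs (7, 7, 512).
#' @export
us_head_view <- function(branch) {
  idx <- (branch$backbone_end + 1):length(branch$layers)
  new_branch(branch$layers[idx], tap = branch$tap - branch$backbone_end,
             input_shape = c(7, 7, 512), name = "us_head")
}

#' Write a trained head view back into the US branch
#' @param branch A [us_branch()]; `head` a trained [us_head_view()].
#' @param head The trained head.
#' @return The updated branch.
#' @export
us_set_head <- function(branch, head) {
  idx <- (branch$backbone_end + 1):length(branch$layers)
  branch$layers[idx] <- head$layers
  branch$loss <- head$loss
  branch
}

#' Train the US head on cached backbone features
#'
#' Applies the US fine-tuning schedule to the layers above the (frozen)
#' backbone, consuming cached [us_backbone_features()].
#'
#' @param branch A [us_branch()].
#' @param feats Cached features (7, 7, 512, N); `y` labels.
#' @inheritParams nn_train
#' @return The updated full branch.
#' @export
train_us_head <- function(branch, feats, y, seed = 1, batch_size = 16) {
  head <- nn_train(us_head_view(branch), feats, y, schedule_us(),
                   batch_size, seed)
  us_set_head(branch, head)
}

#' Predict / featurise from cached US backbone features
#' @param branch A [us_branch()]; `feats` cached backbone features.
#' @param feats Array (7, 7, 512, N).
#' @return For `us_head_predict` a probability vector; for
#'   `us_head_features` the (8, 8, 64, N) tap array.
#' @export
us_head_predict <- function(branch, feats) nn_predict(us_head_view(branch), feats)

#' @rdname us_head_predict
#' @export
us_head_features <- function(branch, feats)
  extract_features(us_head_view(branch), feats)

#' Train the DOT histogram branch
#'
#' Adam with cosine annealing, 20 epochs at learning rate 1e-4; the same
#' schedule is used to pretrain on simulated histograms and to fine-tune
#' on cohort histograms.
#'
#' @param branch A [hist_branch()].
#' @param x Histogram array (32, 32, 1, N); `y` labels.
#' @inheritParams nn_train
#' @return Trained branch.
#' @export
train_hist_branch <- function(branch, x, y, seed = 1, batch_size = 16)
  nn_train(branch, x, y, schedule_hist(), batch_size, seed)

#' Train the DOT image branch
#'
#' Adam with cosine annealing at learning rate 1e-3: 60 epochs for
#' pretraining on simulated reconstructions, 10 for fine-tuning.
#'
#' @param branch An [img_branch()].
#' @param x tHb map array (32, 32, 3, N); `y` labels.
#' @param pretrain Use the 60-epoch pretraining schedule (default) or
#'   the 10-epoch fine-tuning schedule.
#' @inheritParams nn_train
#' @return Trained branch.
#' @export
train_img_branch <- function(branch, x, y, seed = 1, pretrain = TRUE,
                             batch_size = 16)
  nn_train(branch, x, y, schedule_img(pretrain), batch_size, seed)

#' Concatenate branch feature maps for the fusion head
#'
#' @param us_f,hist_f,img_f Arrays (8, 8, 64, N) from
#'   [extract_features()].
#' @return Array (8, 8, 192, N).
#' @export
fuse_features <- function(us_f, hist_f, img_f) {
  stopifnot(all(dim(us_f)[1:3] == c(8, 8, 64)),
            all(dim(hist_f)[1:3] == c(8, 8, 64)),
            all(dim(img_f)[1:3] == c(8, 8, 64)),
            dim(us_f)[4] == dim(hist_f)[4],
            dim(hist_f)[4] == dim(img_f)[4])
  n <- dim(us_f)[4]
  out <- array(0, c(8, 8, 192, n))
  out[, , 1:64, ] <- us_f
  out[, , 65:128, ] <- hist_f
  out[, , 129:192, ] <- img_f
  out
}

#' Train the fusion head on concatenated suspicious-group features
#'
#' Adam with cosine annealing. Branch weights are not touched (the head
#' only ever sees extracted features). If the suspicious training group
#' contains a single class the head cannot be trained; a flag is set and
#' downstream prediction falls back to the stage-1 averaged probability.
#'
#' @param head A [fusion_head()].
#' @param feats Array (8, 8, 192, N); `y` labels.
#' @inheritParams nn_train
#' @return Trained head (possibly with `$fallback = TRUE`).
#' @export
train_fusion <- function(head, feats, y, seed = 1, batch_size = 16) {
  y <- as_label(y)
  if (length(unique(y)) < 2L) {
    warning("single-class suspicious group: fusion head untrained, ",
            "stage-2 will fall back to the stage-1 averaged probability")
    head$fallback <- TRUE
    return(head)
  }
  nn_train(head, feats, y, schedule_fusion(), batch_size, seed)
}

#' Parameters of selected layers (for frozen-weight audits)
#'
#' @param branch A `dot_cnn`.
#' @param idx Layer indices; default all.
#' @return List of parameter arrays, suitable for `identical()`
#'   comparison before and after training.
#' @export
branch_parameters <- function(branch, idx = seq_along(branch$layers)) {
  lapply(branch$layers[idx], function(l)
    l[intersect(names(l), c("W", "b", "gamma", "beta"))])
}
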