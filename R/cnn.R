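#' Convolutional architecture specification
#'
#' Describes a VGG-style stack of 3x3 convolutions (each followed by ReLU and,
#' where `pool_after` is `TRUE`, 2x2 max pooling), fully connected hidden
#' layers with ReLU and dropout, and a softmax output layer. The default is
#' the compact network used for training from scratch: five convolutional
#' layers with 64, 128, 256, 512, 512 filters, each pooled, a 1024-unit fully
#' connected layer with dropout p = 0.5, and a 3-class softmax output.
#'
#' @param conv_filters Integer vector of filter counts, one per conv layer.
#' @param pool_after Logical vector, same length: whether a 2x2 max pool
#'   follows that conv layer.
#' @param fc_units Integer vector of hidden fully-connected layer sizes.
#' @param dropout_p Dropout probability applied to each hidden FC layer
#'   during training.
#' @param n_classes Number of output classes.
#' @param in_channels Input channels (1 for grayscale; 3 for backbones that
#'   expect RGB, fed by channel replication).
#'
#' @return An object of class `cem_arch`.
#' @export
architecture_spec <- function(conv_filters = c(64L, 128L, 256L, 512L, 512L),
                              pool_after = rep(TRUE, length(conv_filters)),
                              fc_units = 1024L,
                              dropout_p = 0.5,
                              n_classes = 3L,
                              in_channels = 1L) {
  stopifnot(length(conv_filters) >= 1L, all(conv_filters >= 1L),
            length(pool_after) == length(conv_filters),
            all(fc_units >= 1L) || length(fc_units) == 0L,
            dropout_p >= 0, dropout_p < 1, n_classes >= 2L,
            in_channels %in% c(1L, 3L))
  structure(list(conv_filters = as.integer(conv_filters),
                 pool_after = as.logical(pool_after),
                 fc_units = as.integer(fc_units),
                 dropout_p = dropout_p,
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "cem_arch")
}

#' Training configuration for the CNN
#'
#' @param learning_rate ADAM learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum number of training epochs.
#' @param early_stopping_patience Stop after this many epochs without
#'   validation-loss improvement; the best-validation weights are retained.
#'   Ignored when no validation set is supplied.
#' @param seed Integer seed governing weight updates' data order and dropout.
#' @param input_size Spatial side the network operates on; frames are
#'   resized or cropped to `input_size x input_size`. Must be divisible by
#'   `2^(number of pooling stages)`.
#' @param resize_mode `"resize"` (bilinear, default) or `"crop"` (centered
#'   crop, preserving native texture scale).
#'
#' @return An object of class `cem_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 100L, early_stopping_patience = 10L,
                         seed = 1L, input_size = 288L,
                         resize_mode = c("resize", "crop")) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, max_epochs >= 1L)
  structure(list(loss = "cross_entropy", optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed), input_size = as.integer(input_size),
                 resize_mode = match.arg(resize_mode)),
            class = "cem_train_config")
}

arch_for_engine <- function(model) {
  c(model$arch[c("conv_filters", "pool_after", "fc_units", "n_classes",
                 "in_channels", "dropout_p")],
    list(input_size = model$input_size))
}

init_layer <- function(n_out, n_in, gain = 2) {
  list(W = matrix(rnorm(n_out * n_in, sd = sqrt(gain / n_in)), n_out, n_in),
       b = numeric(n_out))
}

init_weights <- function(arch, input_size) {
  cin <- arch$in_channels
  conv <- vector("list", length(arch$conv_filters))
  for (l in seq_along(arch$conv_filters)) {
    conv[[l]] <- init_layer(arch$conv_filters[l], 9L * cin)
    cin <- arch$conv_filters[l]
  }
  s <- input_size %/% 2L^sum(arch$pool_after)
  sizes <- c(cin * s * s, arch$fc_units, arch$n_classes)
  fc <- vector("list", length(sizes) - 1L)
  for (j in seq_along(fc)) fc[[j]] <- init_layer(sizes[j + 1L], sizes[j])
  list(conv = conv, fc = fc)
}

#' Build the compact CNN trained from scratch
#'
#' Instantiates the default [architecture_spec()] (or a custom one) with He
#' weight initialization. The forward pass maps a batch of grayscale frames
#' to per-frame probability vectors on the 3-class simplex.
#'
#' @param spec An [architecture_spec()].
#' @param input_size Spatial input side; must be divisible by
#'   `2^(number of pooling stages)` so the pooled grid is integral.
#' @param seed Seed for weight initialization.
#'
#' @return A `cem_cnn` model handle.
#' @export
build_scratch_model <- function(spec = architecture_spec(), input_size = 288L,
                                seed = 1L) {
  stopifnot(inherits(spec, "cem_arch"))
  input_size <- as.integer(input_size)
  npool <- sum(spec$pool_after)
  if (input_size %% 2L^npool != 0L)
    stop("`input_size` must be divisible by 2^", npool)
  weights <- withr::with_seed(as.integer(seed), init_weights(spec, input_size))
  structure(list(arch = spec, weights = weights, input_size = input_size,
                 frozen_conv = 0L, classes = CEM_CLASS_ORDER[seq_len(spec$n_classes)],
                 svm_head = NULL, history = NULL, backbone = "scratch"),
            class = "cem_cnn")
}

#' Build a transfer-learning model with frozen convolutional layers
#'
#' Instantiates a backbone, replaces its task-specific output layer with a
#' new 3-class head, and marks the first `n_frozen_conv_layers` convolutional
#' layers as frozen (excluded from gradient updates). Grayscale frames are
#' adapted to the RGB-shaped backbone by channel replication. Weights may be
#' supplied by the user as an RDS file holding a `list(conv = ..., fc = ...)`
#' of the matching shapes (e.g. converted from an ImageNet checkpoint);
#' without one the backbone is randomly initialized, which exercises the
#' scaffold structurally but carries no transferred knowledge.
#'
#' Only the VGG16 backbone (13 convolutional layers) is implemented;
#' `ResNet50` and `DenseNet` identifiers are reserved and raise an error.
#'
#' @param backbone One of `"VGG16"`, `"ResNet50"`, `"DenseNet"`.
#' @param n_frozen_conv_layers How many leading conv layers to freeze
#'   (default 3; at most 13 for VGG16).
#' @param head `"dense_softmax"` (default) or `"svm_on_last_features"`, in
#'   which case [svm_on_features()] should be called after fine-tuning.
#' @param pretrained_weights Optional path to an RDS weights file.
#' @param input_size Spatial input side (divisible by 32).
#' @param seed Seed for (random) initialization.
#'
#' @return A `cem_cnn` model handle with `frozen_conv` set.
#' @export
build_transfer_model <- function(backbone = c("VGG16", "ResNet50", "DenseNet"),
                                 n_frozen_conv_layers = 3L,
                                 head = c("dense_softmax", "svm_on_last_features"),
                                 pretrained_weights = NULL,
                                 input_size = 224L, seed = 1L) {
  backbone <- match.arg(backbone)
  head <- match.arg(head)
  if (backbone != "VGG16")
    stop(backbone, " backbone is not implemented; use VGG16")
  spec <- architecture_spec(
    conv_filters = c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                     512L, 512L, 512L, 512L, 512L, 512L),
    pool_after = seq_len(13L) %in% c(2L, 4L, 7L, 10L, 13L),
    fc_units = c(4096L, 4096L), dropout_p = 0.5, n_classes = 3L,
    in_channels = 3L)
  n_frozen_conv_layers <- as.integer(n_frozen_conv_layers)
  if (n_frozen_conv_layers < 0L || n_frozen_conv_layers > 13L)
    stop("`n_frozen_conv_layers` must be between 0 and 13 for VGG16")
  model <- build_scratch_model(spec, input_size = input_size, seed = seed)
  if (!is.null(pretrained_weights)) {
    w <- readRDS(pretrained_weights)
    for (l in seq_along(model$weights$conv)) {
      if (!all(dim(w$conv[[l]]$W) == dim(model$weights$conv[[l]]$W)))
        stop("pretrained conv layer ", l, " has incompatible shape")
    }
    model$weights$conv <- w$conv
    # The task head is always re-initialized for the 3 target classes; any
    # supplied fc weights are used where shapes agree (all but the new head).
    for (j in seq_along(w$fc)) {
      if (j < length(model$weights$fc) &&
          all(dim(w$fc[[j]]$W) == dim(model$weights$fc[[j]]$W)))
        model$weights$fc[[j]] <- w$fc[[j]]
    }
  }
  model$frozen_conv <- n_frozen_conv_layers
  model$backbone <- backbone
  model$head <- head
  model
}

#' @export
print.cem_cnn <- function(x, ...) {
  cat(sprintf("<cem_cnn> %s backbone, %d conv layers (%s), fc [%s], input %dx%dx%d\n",
              x$backbone, length(x$arch$conv_filters),
              paste(x$arch$conv_filters, collapse = ","),
              paste(x$arch$fc_units, collapse = ","),
              x$input_size, x$input_size, x$arch$in_channels))
  if (x$frozen_conv > 0L)
    cat(sprintf("  first %d conv layers frozen\n", x$frozen_conv))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final train loss %.4f\n",
                nrow(x$history), x$history$train_loss[nrow(x$history)]))
  invisible(x)
}

#' Prepare frames as CNN input
#'
#' Converts a list of frames (or an `H x W x N` array) into the
#' `S x S x (N * channels)` array of `[0, 1]` intensities the network engine
#' consumes, either by bilinear resizing or by centered cropping. Grayscale
#' content is replicated across channels when the model expects 3.
#'
#' @param frames List of [cem_frame]/matrices, or a 3-d array.
#' @param input_size Target spatial side.
#' @param resize_mode `"resize"` or `"crop"`.
#' @param in_channels 1 or 3.
#' @return Numeric array of dimension `c(input_size, input_size, N * in_channels)`.
#' @export
prepare_cnn_input <- function(frames, input_size, resize_mode = "resize",
                              in_channels = 1L) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (inherits(frames, "cem_frame") || is.matrix(frames)) frames <- list(frames)
  n <- length(frames)
  s <- as.integer(input_size)
  out <- array(0, dim = c(s, s, n * in_channels))
  for (i in seq_len(n)) {
    px <- frame_pixels(frames[[i]])
    if (resize_mode == "crop") {
      if (nrow(px) < s || ncol(px) < s)
        stop("frame smaller than crop size ", s)
      r0 <- (nrow(px) - s) %/% 2L
      c0 <- (ncol(px) - s) %/% 2L
      m <- px[r0 + seq_len(s), c0 + seq_len(s)] / 255
    } else {
      m <- EBImage::resize(px / 255, w = s, h = s)
    }
    for (ch in seq_len(in_channels)) out[, , (i - 1L) * in_channels + ch] <- m
  }
  attr(out, "cem_prepared") <- as.integer(in_channels)
  out
}

is_prepared <- function(x, input_size, in_channels) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[1] == input_size &&
    identical(attr(x, "cem_prepared"), as.integer(in_channels))
}

labels_to_int <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("labels outside the model's class set: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx - 1L
}

adam_update <- function(weights, grads, state, lr, frozen_conv,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(part, l, key) {
    g <- grads[[part]][[l]][[key]]
    if (is.null(dim(weights[[part]][[l]][[key]]))) dim(g) <- NULL
    m <- beta1 * state$m[[part]][[l]][[key]] + (1 - beta1) * g
    v <- beta2 * state$v[[part]][[l]][[key]] + (1 - beta2) * g^2
    state$m[[part]][[l]][[key]] <<- m
    state$v[[part]][[l]][[key]] <<- v
    weights[[part]][[l]][[key]] <<-
      weights[[part]][[l]][[key]] - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }
  for (l in seq_along(weights$conv)) {
    if (l <= frozen_conv || is.null(grads$conv[[l]])) next
    upd("conv", l, "W"); upd("conv", l, "b")
  }
  for (j in seq_along(weights$fc)) {
    upd("fc", j, "W"); upd("fc", j, "b")
  }
  list(weights = weights, state = state)
}

zero_like <- function(weights) {
  lapply(weights, function(part)
    lapply(part, function(layer) lapply(layer, function(w) w * 0)))
}

batch_slices <- function(idx, in_channels) {
  as.integer(t(outer((idx - 1L) * in_channels, seq_len(in_channels), `+`)))
}

#' Train a CNN by ADAM on softmax cross-entropy
#'
#' Minimizes mean cross-entropy over the training frames with the ADAM
#' optimizer (learning rate 0.001 by default), shuffling each epoch. When a
#' validation set is given, the weights with the best validation loss are
#' retained and training stops early after `early_stopping_patience` epochs
#' without improvement. Frozen convolutional layers (transfer models) are
#' excluded from updates. All randomness (shuffling, dropout) is governed by
#' `cfg$seed`, so identical configurations reproduce identical training runs.
#'
#' @param model A `cem_cnn` handle from [build_scratch_model()] or
#'   [build_transfer_model()].
#' @param x Training input: list of frames or a prepared array from
#'   [prepare_cnn_input()] (with the model's `in_channels`).
#' @param y Training class labels.
#' @param val_x,val_y Optional validation inputs/labels (must be disjoint
#'   from training frames; this is the caller's split contract).
#' @param cfg A [train_config()].
#'
#' @return The trained `cem_cnn`, with a `history` data frame of per-epoch
#'   losses and accuracies.
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL,
                        cfg = train_config()) {
  stopifnot(inherits(model, "cem_cnn"), inherits(cfg, "cem_train_config"))
  if (length(y) == 0L) stop("empty training set")
  arch <- arch_for_engine(model)
  if (!is_prepared(x, model$input_size, model$arch$in_channels))
    x <- prepare_cnn_input(x, model$input_size, cfg$resize_mode,
                           model$arch$in_channels)
  yi <- labels_to_int(y, model$classes)
  n <- length(yi)
  has_val <- !is.null(val_x)
  if (has_val) {
    if (!is_prepared(val_x, model$input_size, model$arch$in_channels))
      val_x <- prepare_cnn_input(val_x, model$input_size, cfg$resize_mode,
                                 model$arch$in_channels)
    val_yi <- labels_to_int(val_y, model$classes)
  }

  weights <- model$weights
  state <- list(m = zero_like(weights), v = zero_like(weights), t = 0L)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  hist <- list()

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        res <- cnn_batch_cpp(weights,
                             x[, , batch_slices(idx, model$arch$in_channels),
                               drop = FALSE],
                             yi[idx], arch, training = TRUE, want_grads = TRUE,
                             want_features = FALSE,
                             n_frozen_conv = model$frozen_conv)
        au <- adam_update(weights, res$grads, state, cfg$learning_rate,
                          model$frozen_conv)
        weights <- au$weights; state <- au$state
        tot_loss <- tot_loss + res$loss * length(idx)
        tot_correct <- tot_correct + res$n_correct
      }
      row <- data.frame(epoch = epoch, train_loss = tot_loss / n,
                        train_acc = tot_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        ev <- cnn_eval(weights, arch, val_x, val_yi, model$arch$in_channels)
        row$val_loss <- ev$loss; row$val_acc <- ev$acc
        if (ev$loss < best$loss)
          best <- list(loss = ev$loss, weights = weights, epoch = epoch)
      }
      hist[[epoch]] <- row
      if (has_val && epoch - best$epoch >= cfg$early_stopping_patience) break
    }
  })

  model$weights <- if (has_val) best$weights else weights
  model$history <- do.call(rbind, hist)
  model$train_config <- cfg
  model
}

# Loss/accuracy over a prepared array, batched to bound memory.
cnn_eval <- function(weights, arch, x, yi, in_channels, batch_size = 64L) {
  n <- length(yi)
  tot_loss <- 0; tot_correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    res <- cnn_batch_cpp(weights, x[, , batch_slices(idx, in_channels),
                                    drop = FALSE],
                         yi[idx], arch, training = FALSE, want_grads = FALSE,
                         want_features = FALSE, n_frozen_conv = 0L)
    tot_loss <- tot_loss + res$loss * length(idx)
    tot_correct <- tot_correct + res$n_correct
  }
  list(loss = tot_loss / n, acc = tot_correct / n)
}

#' Predict from a trained CNN
#'
#' @param object A `cem_cnn` model handle.
#' @param newdata Frames (list/array) to classify.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix, or
#'   `"features"` for penultimate-layer activations (dropout disabled, so
#'   repeated featurization of the same frame is identical).
#' @param ... Unused.
#' @return Per `type`: a character vector, an `N x K` matrix, or an `N x F`
#'   matrix. When an `svm_head` is attached (see [svm_on_features()]),
#'   `type = "class"` predictions come from the SVM head.
#' @export
predict.cem_cnn <- function(object, newdata,
                            type = c("class", "prob", "features"), ...) {
  type <- match.arg(type)
  resize_mode <- if (!is.null(object$train_config))
    object$train_config$resize_mode else "resize"
  if (!is_prepared(newdata, object$input_size, object$arch$in_channels))
    newdata <- prepare_cnn_input(newdata, object$input_size, resize_mode,
                                 object$arch$in_channels)
  arch <- arch_for_engine(object)
  n <- dim(newdata)[3] %/% object$arch$in_channels
  probs <- NULL; feats <- NULL
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    res <- cnn_batch_cpp(object$weights,
                         newdata[, , batch_slices(idx, object$arch$in_channels),
                                 drop = FALSE],
                         integer(length(idx)), arch, training = FALSE,
                         want_grads = FALSE, want_features = TRUE,
                         n_frozen_conv = 0L)
    probs <- rbind(probs, res$prob)
    feats <- rbind(feats, res$features)
  }
  colnames(probs) <- object$classes
  switch(type,
         prob = probs,
         features = feats,
         class = {
           if (!is.null(object$svm_head)) as.character(predict(object$svm_head, feats))
           else object$classes[max.col(probs, ties.method = "first")]
         })
}

#' Replace the softmax head with a linear SVM on deep features
#'
#' Extracts the penultimate ("last feature layer") activations of a trained
#' network for the given frames and fits a linear SVM on them; the SVM then
#' replaces the softmax head for class prediction.
#'
#' @param model A trained `cem_cnn`.
#' @param x Frames (list/array) to featurize for SVM training.
#' @param y Their class labels.
#' @param C SVM regularization constant.
#' @return The model with an `svm_head` attached.
#' @export
svm_on_features <- function(model, x, y, C = 1) {
  stopifnot(inherits(model, "cem_cnn"))
  if (length(y) == 0L) stop("cannot extract features from an empty input")
  feats <- predict(model, x, type = "features")
  model$svm_head <- train_linear_svm(feats, y, C = C)
  model
}
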