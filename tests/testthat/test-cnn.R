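# Small architectures are used throughout so the suite stays fast; the
# default five-stage architecture itself is checked structurally.

tiny_spec <- function(dropout_p = 0) {
  architecture_spec(conv_filters = c(4L, 8L), fc_units = 8L,
                    dropout_p = dropout_p)
}

tiny_frames <- function(n, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    matrix(sample(0L:255L, 16L * 16L, replace = TRUE), 16L, 16L)))
}

test_that("the default architecture has the documented structure", {
  spec <- architecture_spec()
  expect_identical(spec$conv_filters, c(64L, 128L, 256L, 512L, 512L))
  expect_true(all(spec$pool_after))
  m <- build_scratch_model(spec, input_size = 32L, seed = 1L)
  # first conv layer: 3*3*1*64 weights + 64 biases = 640 parameters
  expect_identical(length(m$weights$conv[[1]]$W) + length(m$weights$conv[[1]]$b),
                   640L)
  expect_identical(nrow(m$weights$fc[[2]]$W), 3L)    # 3-class head
  expect_identical(ncol(m$weights$fc[[1]]$W), 512L)  # 1x1x512 after 5 pools
  expect_error(build_scratch_model(spec, input_size = 100L), "divisible")
})

test_that("softmax outputs are probability vectors of length 3", {
  m <- build_scratch_model(tiny_spec(), input_size = 16L, seed = 2L)
  p <- predict(m, tiny_frames(5), type = "prob")
  expect_identical(dim(p), c(5L, 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(colnames(p), cem_classes())
})

test_that("analytic gradients match finite differences", {
  spec <- architecture_spec(conv_filters = c(3L, 4L), fc_units = 5L,
                            dropout_p = 0)
  m <- build_scratch_model(spec, input_size = 8L, seed = 7L)
  x <- withr::with_seed(8L, array(runif(8 * 8 * 3), c(8L, 8L, 3L)))
  attr(x, "cem_prepared") <- 1L
  yi <- 0:2
  arch <- cemclass:::arch_for_engine(m)
  res <- cemclass:::cnn_batch_cpp(m$weights, x, yi, arch, TRUE, TRUE, FALSE, 0L)
  lossfun <- function(w)
    cemclass:::cnn_batch_cpp(w, x, yi, arch, FALSE, FALSE, FALSE, 0L)$loss
  eps <- 1e-6
  withr::with_seed(9L, {
    for (part in c("conv", "fc")) {
      for (l in seq_along(m$weights[[part]])) {
        g <- res$grads[[part]][[l]]$W
        for (trial in 1:4) {
          i <- sample(length(g), 1L)
          w2 <- m$weights
          w2[[part]][[l]]$W[i] <- w2[[part]][[l]]$W[i] + eps
          num <- (lossfun(w2) - res$loss) / eps
          expect_equal(num, g[i], tolerance = 1e-3)
        }
      }
    }
  })
})

test_that("the network memorizes a small labeled set (capacity check)", {
  fs <- small_frame_set()
  idx <- withr::with_seed(10L, unlist(lapply(
    split(seq_len(60), fs$manifest$class_label), sample, 4L)))
  frames <- fs$frames[idx]
  y <- fs$manifest$class_label[idx]
  m <- build_scratch_model(tiny_spec(), input_size = 16L, seed = 3L)
  cfg <- train_config(batch_size = 4L, max_epochs = 60L, input_size = 16L,
                      resize_mode = "crop", seed = 4L)
  m <- train_model(m, frames, y, cfg = cfg)
  expect_identical(predict(m, frames), y)
})

test_that("a zero learning rate leaves weights and loss untouched", {
  m <- build_scratch_model(tiny_spec(dropout_p = 0), input_size = 16L, seed = 5L)
  frames <- tiny_frames(9, seed = 6)
  y <- rep(cem_classes(), 3L)
  cfg <- train_config(learning_rate = 0, batch_size = 4L, max_epochs = 3L,
                      input_size = 16L, resize_mode = "crop", seed = 7L)
  t <- train_model(m, frames, y, cfg = cfg)
  expect_identical(t$weights, m$weights)
  expect_lt(diff(range(t$history$train_loss)), 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  m <- build_scratch_model(tiny_spec(0.5), input_size = 16L, seed = 5L)
  frames <- tiny_frames(9, seed = 6)
  y <- rep(cem_classes(), 3L)
  cfg <- train_config(batch_size = 4L, max_epochs = 2L, input_size = 16L,
                      resize_mode = "crop", seed = 11L)
  h1 <- train_model(m, frames, y, cfg = cfg)$history
  h2 <- train_model(m, frames, y, cfg = cfg)$history
  expect_identical(h1$train_loss, h2$train_loss)
  cfg2 <- train_config(batch_size = 4L, max_epochs = 2L, input_size = 16L,
                       resize_mode = "crop", seed = 12L)
  h3 <- train_model(m, frames, y, cfg = cfg2)$history
  expect_false(identical(h1$train_loss[1], h3$train_loss[1]))
})

test_that("frozen conv layers stay bit-identical through training", {
  m <- build_transfer_model("VGG16", n_frozen_conv_layers = 3L,
                            input_size = 32L, seed = 13L)
  frames <- withr::with_seed(14L, lapply(1:3, function(i)
    matrix(sample(0L:255L, 32L * 32L, replace = TRUE), 32L, 32L)))
  y <- cem_classes()
  cfg <- train_config(batch_size = 3L, max_epochs = 1L, input_size = 32L,
                      resize_mode = "crop", seed = 15L)
  t <- train_model(m, frames, y, cfg = cfg)
  same <- vapply(1:13, function(l)
    identical(m$weights$conv[[l]]$W, t$weights$conv[[l]]$W), logical(1))
  expect_identical(which(same), 1:3)
  # freezing all 13 conv layers leaves only the head trainable
  m13 <- build_transfer_model("VGG16", n_frozen_conv_layers = 13L,
                              input_size = 32L, seed = 13L)
  t13 <- train_model(m13, frames, y, cfg = cfg)
  expect_identical(m13$weights$conv, t13$weights$conv)
  expect_false(identical(m13$weights$fc[[3]]$W, t13$weights$fc[[3]]$W))
  expect_error(build_transfer_model("VGG16", n_frozen_conv_layers = 14L),
               "between 0 and 13")
})

test_that("unimplemented backbones are refused, heads are 3-class", {
  expect_error(build_transfer_model("ResNet50"), "not implemented")
  expect_error(build_transfer_model("DenseNet"), "not implemented")
  m <- build_transfer_model("VGG16", input_size = 32L)
  expect_identical(length(m$weights$conv), 13L)
  expect_identical(nrow(m$weights$fc[[3]]$W), 3L)
  expect_identical(m$arch$in_channels, 3L)
})

test_that("svm_on_features replaces the softmax head deterministically", {
  m <- build_scratch_model(tiny_spec(0.5), input_size = 16L, seed = 16L)
  frames <- tiny_frames(9, seed = 17)
  y <- rep(cem_classes(), 3L)
  f1 <- predict(m, frames[1], type = "features")
  f2 <- predict(m, frames[1], type = "features")
  expect_identical(f1, f2)  # dropout disabled at inference
  ms <- svm_on_features(m, frames, y)
  expect_true(all(predict(ms, frames) %in% cem_classes()))
  expect_error(svm_on_features(m, list(), character(0)), "empty")
})

test_that("prepare_cnn_input crops, resizes and replicates channels", {
  px <- rand_frame(40, 44, 18)
  xc <- prepare_cnn_input(list(px), 16L, "crop", 1L)
  expect_identical(dim(xc), c(16L, 16L, 1L))
  expect_identical(matrix(as.integer(xc[, , 1] * 255), 16L, 16L),
                   px[13:28, 15:30])
  xr <- prepare_cnn_input(list(px), 16L, "resize", 3L)
  expect_identical(dim(xr), c(16L, 16L, 3L))
  expect_identical(xr[, , 1], xr[, , 3])
  expect_error(prepare_cnn_input(list(px), 64L, "crop", 1L), "smaller")
})
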