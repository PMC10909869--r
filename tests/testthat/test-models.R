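tiny_arch <- function(dropout = 0)
  arch_config(conv_filters = c(2L, 3L, 4L, 5L), dense_widths = 4L,
              dropout_rate = dropout)

rand_examples <- function(n, shape, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(x = array(rnorm(prod(shape)), shape), y = i %% 2,
         subject_id = sprintf("S%02d", i), scan_id = sprintf("S%02d_v1", i)))
}

test_that("binary cross-entropy matches its closed form on a dense grid", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(1, 0.9), -log(0.9), tolerance = 1e-12)
  yh <- seq(0.01, 0.99, by = 0.01)
  for (y in c(0, 1)) {
    direct <- -(y * log(yh) + (1 - y) * log(1 - yh))
    expect_lt(max(abs(bce_loss(y, yh) - direct)), 1e-6)
  }
  expect_error(bce_loss(2, 0.5), "0 or 1")
})

test_that("analytic BCE gradient matches finite differences", {
  yh <- seq(0.05, 0.95, by = 0.05)
  eps <- 1e-6
  for (y in c(0, 1)) {
    fd <- (bce_loss(y, yh + eps) - bce_loss(y, yh - eps)) / (2 * eps)
    expect_lt(max(abs(bce_loss_grad(y, yh) - fd)), 1e-4)
    expect_lt(max(abs(bce_loss_grad(y, yh) - (yh - y) / (yh * (1 - yh)))), 1e-9)
  }
})

test_that("learning rate decays exponentially per epoch", {
  expect_equal(lr_at(0), 5e-5)
  expect_equal(lr_at(10), 5e-5 * 0.96^10)
})

test_that("models output probabilities and respect variant dimensionality", {
  m2 <- build_model("mri_2d", tiny_arch(), c(12L, 12L), seed = 1)
  ex2 <- rand_examples(3, c(12, 12))
  p <- predict(m2, ex2)
  expect_true(all(p$y_hat > 0 & p$y_hat < 1))

  m3 <- build_model("pet_3d", tiny_arch(), c(12L, 12L, 8L), seed = 1)
  expect_error(build_model("mri_3d", tiny_arch(), c(12L, 12L), seed = 1),
               "3D input")

  # same filter list: 2D and 3D builds differ only in kernel dimensionality
  types2 <- vapply(m2$branches$main, `[[`, "", "type")
  types3 <- vapply(m3$branches$main, `[[`, "", "type")
  expect_identical(types2, types3)
  k2 <- nrow(m2$branches$main[[1]]$par$W)   # 3^2 * in_ch
  k3 <- nrow(m3$branches$main[[1]]$par$W)   # 3^3 * in_ch
  expect_identical(c(k2, k3), c(9L, 27L))
})

test_that("fusion builds two independent branches with more parameters", {
  n_par <- function(layers) sum(vapply(layers, function(l)
    sum(lengths(l$par)), 0))
  mf <- build_model("fusion_3d", tiny_arch(), c(12L, 12L, 8L), seed = 1)
  ms <- build_model("mri_3d", tiny_arch(), c(12L, 12L, 8L), seed = 1)
  expect_gt(n_par(mf$branches$mri) + n_par(mf$branches$pet) + n_par(mf$classifier),
            n_par(ms$branches$main) + n_par(ms$classifier))
  # twin branches are not weight-shared
  expect_false(identical(mf$branches$mri[[1]]$par$W, mf$branches$pet[[1]]$par$W))
})

test_that("training is seeded, early-stops and restores the best epoch", {
  ex <- rand_examples(12, c(10, 10), seed = 3)
  m <- build_model("mri_2d", tiny_arch(), c(10L, 10L), seed = 2)
  cfg <- train_config(learning_rate = 1e-3, decay = 0.96, patience = 3L,
                      max_epochs = 8L, batch_size = 4L, seed = 5L)
  r1 <- train(m, ex, ex, cfg)
  r2 <- train(m, ex, ex, cfg)
  expect_identical(r1$history, r2$history)
  expect_lte(nrow(r1$history), 8L)
  expect_equal(r1$best_val, max(r1$history$val_acc))
  expect_identical(r1$history$lr, lr_at(r1$history$epoch - 1, 1e-3, 0.96))

  one_class <- lapply(ex, function(e) { e$y <- 1; e })
  expect_error(train(m, one_class, ex, cfg), "both classes")
  expect_error(train_config(patience = 10, max_epochs = 10), "patience")
})

test_that("training separates an easy synthetic signal", {
  # class difference: a bright square planted in one corner
  set.seed(11)
  ex <- lapply(1:16, function(i) {
    x <- matrix(rnorm(100, 0, 0.2), 10, 10)
    y <- i %% 2
    if (y == 1) x[2:5, 2:5] <- x[2:5, 2:5] + 2
    list(x = x, y = y, subject_id = sprintf("S%02d", i),
         scan_id = sprintf("S%02d_v1", i))
  })
  m <- build_model("mri_2d", tiny_arch(), c(10L, 10L), seed = 4)
  r <- train(m, ex, ex, train_config(learning_rate = 5e-3, decay = 0.99,
                                     patience = 59L, max_epochs = 60L,
                                     batch_size = 4L, seed = 4L))
  p <- predict(r$model, ex)
  expect_gte(mean((p$y_hat >= 0.5) == (p$y == 1)), 0.9)
  # loss trends downward over training
  h <- r$history$train_loss
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
})

test_that("transfer fine-tuning freezes the feature extractor bit-exactly", {
  ex <- rand_examples(8, c(10, 10, 6), seed = 6)
  m <- build_model("mri_3d", tiny_arch(), c(10L, 10L, 6L), seed = 3)
  cfg <- train_config(learning_rate = 1e-3, decay = 0.96, patience = 2L,
                      max_epochs = 3L, batch_size = 4L, seed = 7L)
  src <- train(m, ex, ex, cfg)$model
  before <- feature_checksum(src)
  before_w <- src$branches$main[[1]]$par$W
  ft <- transfer_finetune(src, ex, ex, cfg)$model
  expect_identical(feature_checksum(ft), before)
  expect_identical(ft$branches$main[[1]]$par$W, before_w)
  # classifier parameters did change
  expect_false(identical(ft$classifier[[1]]$par$W, src$classifier[[1]]$par$W))
  expect_error(transfer_finetune(m, ex, ex, cfg), "trained")
})

test_that("alternating training interleaves modalities and accepts either", {
  mri <- rand_examples(8, c(10, 10, 6), seed = 8)
  pet <- rand_examples(6, c(10, 10, 6), seed = 9)
  m <- build_model("combined_input_3d", tiny_arch(), c(10L, 10L, 6L), seed = 5)
  cfg <- train_config(learning_rate = 1e-3, decay = 0.96, patience = 2L,
                      max_epochs = 3L, batch_size = 4L, seed = 2L)
  r <- train_alternating(m, mri, pet, c(mri, pet), cfg)
  lg <- r$batch_log
  expect_true(all(lg[seq(1, length(lg), 2)] == "MRI"))
  expect_true(all(lg[seq(2, length(lg), 2)] == "PET"))
  # the trained single-branch model predicts a lone volume of either stream
  expect_s3_class(predict(r$model, mri[1]), "data.frame")
  expect_s3_class(predict(r$model, pet[1]), "data.frame")
  bad <- rand_examples(2, c(8, 8, 6))
  expect_error(train_alternating(m, mri, bad, mri, cfg), "share one shape")
})

test_that("inference is deterministic and fusion demands pairs", {
  mf <- build_model("fusion_3d", tiny_arch(), c(10L, 10L, 6L), seed = 9)
  set.seed(10)
  pair <- list(list(mri = array(rnorm(600), c(10, 10, 6)),
                    pet = array(rnorm(600), c(10, 10, 6)), y = 1,
                    subject_id = "S1", scan_id = "S1_v1"))
  p1 <- predict(mf, pair); p2 <- predict(mf, pair)
  expect_identical(p1$y_hat, p2$y_hat)
  expect_identical(nrow(p1), 1L)
  expect_error(predict(mf, rand_examples(2, c(10, 10, 6))), "paired")
})
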