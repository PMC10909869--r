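tiny_arch <- function()
  arch_config(conv_filters = c(2L, 3L, 4L, 5L), dense_widths = 4L,
              dropout_rate = 0)

test_that("a linear single-map read-out has the closed-form alpha and map", {
  # one feature map A (2 x 2); a dense read-out with every weight s/Z makes
  # the logit s * mean(A), so dlogit/dA_ij = s/Z everywhere, alpha = s/Z
  # and L = ReLU(A) * s/Z (proportional to ReLU of the map)
  A <- matrix(c(1.5, -0.5, 2, 0.25), 2, 2)
  s <- 3; Z <- 4
  layers <- list(neurofuse:::layer_flatten("flatten"),
                 neurofuse:::layer_dense(4L, 1L, "dense_out"))
  layers[[2]]$par$W <- matrix(s / Z, 4, 1)
  layers[[2]]$par$b <- 0
  tn <- list(x = matrix(as.vector(A), ncol = 1), spatial = c(2L, 2L), B = 1L)
  fw <- neurofuse:::net_forward(layers, tn, training = FALSE)
  expect_equal(fw$out[1, 1], s * mean(A), tolerance = 1e-12)
  bb <- neurofuse:::net_backward(layers, fw$caches, matrix(1, 1, 1))
  alpha <- colMeans(bb$din$x)
  expect_equal(alpha, s / Z, tolerance = 1e-12)
  L <- pmax(as.vector(tn$x %*% alpha), 0)
  expect_equal(L, pmax(as.vector(A), 0) * s / Z, tolerance = 1e-12)
})

test_that("Grad-CAM weights match finite differences on a small random net", {
  m <- build_model("mri_2d", tiny_arch(), c(12L, 12L), seed = 21)
  set.seed(22)
  for (rep in 1:6) {
    e <- list(x = matrix(rnorm(144), 12, 12), y = 1)
    for (stage in c(2L, 4L)) {
      cam <- gradcam(m, e, class_index = 1, stage = stage)
      t <- neurofuse:::relu_index(stage)
      layers <- m$branches$main
      ncl <- length(m$classifier)
      fw <- neurofuse:::model_forward(m, list(e), training = FALSE, record = TRUE)
      A <- fw$branch$main$outputs[[t]]
      logit_from <- function(Ax) {
        tn <- list(x = Ax, spatial = A$spatial, B = 1L)
        z <- neurofuse:::net_forward(layers[(t + 1):length(layers)], tn,
                                     training = FALSE)$out
        neurofuse:::net_forward(m$classifier[-ncl], z, training = FALSE)$out[1, 1]
      }
      K <- ncol(A$x); Z <- nrow(A$x)
      fd_alpha <- numeric(K)
      eps <- 1e-4
      for (k in seq_len(K)) {
        Ap <- A$x; Ap[, k] <- Ap[, k] + eps
        Am <- A$x; Am[, k] <- Am[, k] - eps
        # pooled gradient = (1/Z) sum_ij dlogit/dA_ij; perturbing the whole
        # map by eps measures Z times the mean gradient
        fd_alpha[k] <- (logit_from(Ap) - logit_from(Am)) / (2 * eps) / Z
      }
      expect_lt(max(rel_err(cam$alpha, fd_alpha)), 1e-3)
      L_direct <- pmax(as.vector(A$x %*% fd_alpha), 0)
      expect_lt(max(abs(as.vector(cam$L) - L_direct)), 1e-6)
    }
  }
})

test_that("relevance maps are nonnegative and ReLU floors negative mixes", {
  m <- build_model("mri_2d", tiny_arch(), c(12L, 12L), seed = 3)
  set.seed(4)
  e <- list(x = matrix(rnorm(144), 12, 12), y = 1)
  for (stage in 1:4) {
    cam <- gradcam(m, e, stage = stage)
    expect_gte(min(cam$L), 0)
  }
  # flipping the class flips the score's sign: maps for both classes are
  # still nonnegative
  camn <- gradcam(m, e, class_index = 0, stage = 4)
  expect_gte(min(camn$L), 0)
})

test_that("Grad-CAM scales covariantly with the logit", {
  m <- build_model("mri_2d", tiny_arch(), c(12L, 12L), seed = 5)
  set.seed(6)
  e <- list(x = matrix(rnorm(144), 12, 12), y = 1)
  cam1 <- gradcam(m, e, stage = 3)
  m2 <- m
  iout <- length(m2$classifier) - 1L  # final dense layer
  m2$classifier[[iout]]$par$W <- 4 * m2$classifier[[iout]]$par$W
  m2$classifier[[iout]]$par$b <- 4 * m2$classifier[[iout]]$par$b
  cam4 <- gradcam(m2, e, stage = 3)
  expect_equal(cam4$L, 4 * cam1$L, tolerance = 1e-9)
})

test_that("upsampling preserves constants, shape and nonnegativity", {
  const <- array(2.5, c(3, 3, 2))
  up <- upsample_cam(const, c(9, 9, 4))
  expect_identical(dim(up), c(9L, 9L, 4L))
  expect_equal(unique(round(as.vector(up), 12)), 2.5)

  expect_equal(upsample_cam(const, c(3, 3, 2)), const)

  hot <- array(0, c(4, 4, 1)); hot[2, 3, 1] <- 1
  up2 <- upsample_cam(hot, c(8, 8, 1))
  expect_gte(min(up2), 0)
  w <- which(up2 == max(up2), arr.ind = TRUE)
  # the maximum lands at the location corresponding to the hot voxel
  expect_true(all(w[, 1] %in% 3:4) && all(w[, 2] %in% 5:6))
  expect_error(upsample_cam(const, c(2, 3, 2)), ">=")
})

test_that("region means match brute-force loops and select by percentile", {
  a <- make_toy_atlas(c(16, 16, 16), 4, seed = 2)
  set.seed(7)
  rel <- array(runif(16^3), c(16, 16, 16))
  ra <- region_attribution(rel, a)
  oracle <- oracle_region_means(as.vector(rel), as.vector(a$labels))
  expect_lt(max(abs(unname(ra$means) - unname(oracle))), 1e-12)

  # indicator relevance: only that region selected
  ind <- array(0, c(16, 16, 16)); ind[a$labels == 3] <- 1
  ra3 <- region_attribution(ind, a)
  expect_identical(ra3$selected, unname(a$names["3"]))
  expect_identical(ra3$selected_ids, 3L)

  # constant relevance: all means tie, all selected
  rc <- region_attribution(array(1, c(16, 16, 16)), a)
  expect_length(rc$selected, 4L)
  expect_error(region_attribution(array(1, c(8, 8, 8)), a), "match")
})

test_that("region means are partition-consistent with the brain-wide mean", {
  a <- make_toy_atlas(c(16, 16, 16), 5, seed = 3)
  set.seed(8)
  rel <- array(runif(16^3), c(16, 16, 16))
  ra <- region_attribution(rel, a)
  nvox <- table(a$labels[a$labels > 0])
  weighted <- sum(ra$means * as.vector(nvox)) / sum(nvox)
  expect_equal(weighted, mean(rel[a$labels > 0]), tolerance = 1e-9)
})

test_that("group attribution of identical scans equals the single-scan result", {
  a <- make_toy_atlas(c(32, 32, 32), 4, seed = 4)
  sp <- effect_spec("MRI", 2, noise_sd = 0.5)
  v <- simulate_volume(a, 1, sp, seed = 9)
  cfg <- preproc_config(size = 32, n_slices = 12)
  x <- preprocess_volume(v, cfg)
  ex <- list(x = x, y = 1, subject_id = "S1", scan_id = "S1_v1_MRI")
  m <- build_model("mri_3d", tiny_arch(), c(32L, 32L, 12L), seed = 6)

  g1 <- group_attribution(m, list(ex), a, stage = 2)
  g3 <- group_attribution(m, list(ex, ex, ex), a, stage = 2)
  expect_equal(g3$group$means, g1$group$means, tolerance = 1e-12)
  expect_true(all(g3$selection_frequency >= 0 & g3$selection_frequency <= 1))
  expect_error(group_attribution(m, list(), a), "empty")
})

test_that("fusion models yield one relevance map per branch", {
  mf <- build_model("fusion_3d", tiny_arch(), c(10L, 10L, 6L), seed = 8)
  set.seed(9)
  pair <- list(mri = array(rnorm(600), c(10, 10, 6)),
               pet = array(rnorm(600), c(10, 10, 6)), y = 1)
  cm <- gradcam(mf, pair, stage = 4, branch = "mri")
  cp <- gradcam(mf, pair, stage = 4, branch = "pet")
  expect_gte(min(cm$L), 0); expect_gte(min(cp$L), 0)
  expect_false(identical(cm$L, cp$L))
})
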