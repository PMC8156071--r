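test_that("compound scaling derives depth, width and resolution by rounding", {
  s0 <- scaling_spec(phi = 0)
  expect_equal(c(s0$depth, s0$width, s0$resolution), c(2L, 8L, 32L))
  s1 <- scaling_spec(phi = 1)
  expect_equal(s1$depth, round(2 * 1.2))
  expect_equal(s1$width, 9L)        # round(8 * 1.1)
  expect_equal(s1$resolution, 37L)  # round(32 * 1.15)
  # parameter count strictly increases with phi
  n <- vapply(0:3, function(p) {
    n_parameters(build_model(scaling_spec(p), n_classes = 5, seed = 1))
  }, 0)
  expect_true(all(diff(n) > 0))
  expect_error(build_model(scaling_spec(0, base_resolution = 16), 5),
               "32 px minimum")
})

test_that("probability outputs are normalized and batching-invariant", {
  m <- build_model(scaling_spec(0), n_classes = 5, seed = 3)
  withr::with_seed(4, x <- array(runif(32 * 32 * 3 * 40), c(32, 32, 3, 40)))
  p <- cnn_probs(m, x)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  p1 <- cnn_probs(m, x, batch_size = 1L)
  p64 <- cnn_probs(m, x, batch_size = 64L)
  expect_lt(max(abs(p1 - p64)), 1e-5)
  # duplicate inputs give identical rows
  x2 <- x; x2[, , , 2] <- x2[, , , 1]
  p2 <- cnn_probs(m, x2)
  expect_equal(p2[1, ], p2[2, ])
  expect_error(cnn_forward(m, array(0, c(32, 32, 4, 1))), "3 channels")
})

test_that("analytic parameter gradients match finite differences", {
  m <- cnn_init(depth = 1, width = 2, resolution = 32, n_classes = 3,
                seed = 5)
  withr::with_seed(6, x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  y <- c(1L, 3L)
  fwd <- cnn_forward(m, x, keep_cache = TRUE)
  Y <- matrix(0, 2, 3); Y[cbind(1:2, y)] <- 1
  g <- cnn_backward(m, fwd, (fwd$probs - Y) / 2)
  loss_of <- function(model) {
    p <- cnn_forward(model, x)$probs
    -mean(log(p[cbind(1:2, y)]))
  }
  eps <- 1e-6
  withr::with_seed(7, idx <- sample(length(m$conv_W[[1]]), 4))
  for (ii in idx) {
    m1 <- m; m1$conv_W[[1]][ii] <- m1$conv_W[[1]][ii] + eps
    m2 <- m; m2$conv_W[[1]][ii] <- m2$conv_W[[1]][ii] - eps
    expect_equal(g$conv_W[[1]][ii], (loss_of(m1) - loss_of(m2)) / (2 * eps),
                 tolerance = 1e-4)
  }
  m1 <- m; m1$dense_b[2] <- m1$dense_b[2] + eps
  m2 <- m; m2$dense_b[2] <- m2$dense_b[2] - eps
  expect_equal(g$dense_b[2], (loss_of(m1) - loss_of(m2)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("input gradients match finite differences of the class logit", {
  m <- cnn_init(depth = 2, width = 3, resolution = 32, n_classes = 3,
                seed = 8)
  withr::with_seed(9, x <- array(runif(32 * 32 * 3), c(32, 32, 3)))
  gi <- input_gradient(m, x, 2L)
  logit_of <- function(xx) cnn_forward(m, xx)$logits[1, 2]
  eps <- 1e-6
  withr::with_seed(10, idx <- sample(length(x), 5))
  for (ii in idx) {
    x1 <- x; x1[ii] <- x1[ii] + eps
    x2 <- x; x2[ii] <- x2[ii] - eps
    expect_equal(gi[ii], (logit_of(x1) - logit_of(x2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training config enforces the power-of-two batch convention", {
  expect_error(train_config(batch_size = 48), "power of two")
  expect_no_error(train_config(batch_size = 64))
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("zero-epoch training returns initial weights and empty curves", {
  demo <- demo_fit()
  sets <- demo$sets
  cfg <- train_config(scaling_spec(0), epochs = 0L, seed = 21,
                      class_list = demo_classes)
  fit <- train(sets$TRAIN, sets$VAL, cfg)
  expect_equal(nrow(fit$curves), 0)
  init <- build_model(scaling_spec(0), length(demo_classes), seed = 21)
  expect_equal(fit$model$conv_W, init$conv_W)
  expect_true(is.na(fit$best_val_acc))
})

test_that("training refuses case leakage between subsets", {
  demo <- demo_fit()
  sets <- demo$sets
  leaky_val <- sets$TRAIN  # same cases on both sides
  expect_error(
    train(sets$TRAIN, leaky_val,
          train_config(scaling_spec(0), epochs = 1L,
                       class_list = demo_classes)),
    "leak")
})

test_that("the demo model learns and its curves satisfy the gap identity", {
  demo <- demo_fit()
  fit <- demo$fit
  expect_gte(fit$best_val_acc, 0.9)
  expect_equal(fit$curves$overfit_gap,
               fit$curves$train_acc - fit$curves$val_acc)
  expect_equal(fit$best_val_acc, max(fit$curves$val_acc))
  expect_equal(fit$curves$val_acc[fit$best_epoch], fit$best_val_acc)
  # held-out accuracy of the checkpoint
  preds <- predict_patches(fit, demo$sets$TEST)
  P <- as.matrix(preds[, paste0("p_", demo_classes)])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
  acc <- mean(demo_classes[max.col(P, ties.method = "first")] ==
                preds$true_class)
  expect_gte(acc, 0.85)
})

test_that("learning-rate screening picks the argmax of its own curves", {
  demo <- demo_fit()
  sets <- demo$sets
  sw <- lr_sweep(sets$TRAIN, sets$VAL, scaling_spec(0),
                 candidate_lrs = c(1e-2, 1e-4), screen_epochs = 2L,
                 seed = 31, class_list = demo_classes)
  # oracle: scan the emitted curves
  best_by_lr <- vapply(split(sw$curves$val_acc, sw$curves$lr), max, 0)
  expect_equal(sw$chosen_lr,
               as.numeric(names(best_by_lr)[which.max(best_by_lr)]))
  expect_equal(sort(unique(sw$curves$lr)), c(1e-4, 1e-2))
  expect_equal(nrow(sw$curves), 4)  # 2 lrs x 2 epochs
  expect_error(lr_sweep(sets$TRAIN, sets$VAL, scaling_spec(0), 1e-3),
               "at least two")
})

test_that("model selection follows accuracy, then BACC, then smaller phi", {
  cand <- function(phi, acc, bacc = NULL) {
    list(scaling = scaling_spec(phi),
         curves = data.frame(epoch = 1, val_acc = acc),
         fitted = NULL, val_bacc = bacc)
  }
  # plain argmax
  pick <- select_model(list(cand(0, 0.91), cand(1, 0.94)))
  expect_equal(pick$scaling$phi, 1L)
  # accuracy tie broken by BACC
  pick2 <- select_model(list(cand(0, 0.94, 0.90), cand(1, 0.94, 0.93)))
  expect_equal(pick2$scaling$phi, 1L)
  # full tie falls back to smaller phi
  pick3 <- select_model(list(cand(2, 0.94, 0.93), cand(1, 0.94, 0.93)))
  expect_equal(pick3$scaling$phi, 1L)
  # fuzz against an independent restatement of the rule
  withr::with_seed(55, {
    for (trial in 1:50) {
      n <- sample(2:5, 1)
      accs <- round(runif(n, 0.8, 0.95), 3)
      baccs <- round(runif(n, 0.7, 0.95), 3)
      phis <- sample(0:4, n)
      cands <- lapply(seq_len(n), function(i) cand(phis[i], accs[i], baccs[i]))
      got <- select_model(cands)$scaling$phi
      contend <- which(accs >= max(accs) - 0.0025)
      if (length(contend) > 1L) {
        contend <- contend[baccs[contend] == max(baccs[contend])]
        want <- phis[contend][which.min(phis[contend])]
      } else {
        want <- phis[contend]
      }
      expect_equal(got, want)
    }
  })
})
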