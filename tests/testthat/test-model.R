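# Classifier: architecture arithmetic, training behaviour, chance bounds.

test_that("default architecture has the documented parameter count", {
  net <- build_rotation_net(model_config())
  # hand arithmetic: weights 1024*512 + 512*256 + 256*6 + 6*3,
  # biases 512 + 256 + 6 + 3
  expected <- 1024 * 512 + 512 * 256 + 256 * 6 + 6 * 3 + (512 + 256 + 6 + 3)
  expect_identical(n_parameters(net), expected)
  expect_equal(dim(net$W[[1]]), c(1024, 512))
  expect_equal(dim(net$W[[4]]), c(6, 3))
})

test_that("forward pass maps any input to three sigmoid outputs", {
  cfg <- model_config(seed = 2)
  x <- matrix(rnorm(5 * 1024), 5, 1024)
  y <- factor(rep(c("none", "left", "right"), length.out = 5),
              levels = c("none", "left", "right"))
  m <- fit_rotation_model(x, y, config = model_config(epochs = 1, seed = 2))
  p <- predict(m, matrix(0, 1, 1024))
  expect_equal(dim(p), c(1, 3))
  expect_identical(colnames(p), c("none", "left", "right"))
  expect_true(all(p > 0 & p < 1))
  # duplicate inputs give identical outputs
  p2 <- predict(m, rbind(x[1, ], x[1, ]))
  expect_equal(p2[1, ], p2[2, ])
  expect_error(predict(m, matrix(0, 1, 100)), "input_dim")
  expect_error(fit_rotation_model(x[, 1:100], y,
                                  config = model_config(epochs = 1)),
               "input_dim")
})

test_that("training is seed-deterministic and reduces the loss", {
  set.seed(99)
  n <- 90
  y <- factor(rep(c("none", "left", "right"), each = n / 3),
              levels = c("none", "left", "right"))
  # separable synthetic features: class-dependent mean shift
  mu <- model.matrix(~ y - 1) %*% matrix(rnorm(3 * 1024), 3, 1024)
  x <- mu + matrix(rnorm(n * 1024), n, 1024)
  cfg <- model_config(epochs = 12, batch_size = 30, seed = 7)
  m1 <- fit_rotation_model(x, y, config = cfg)
  m2 <- fit_rotation_model(x, y, config = cfg)
  expect_identical(m1$net$W, m2$net$W)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  expect_equal(nrow(m1$history), 12)
})

test_that("planted lateralized signal is learned to high validation accuracy", {
  skip_if_not_installed("glmnet")
  cfg <- synth_config(block_duration = 300, rp_amplitude = 60,
                      lateralization_fraction = 0.7, artifact_rate = 0,
                      seed = 61)
  dss <- lapply(1:2, function(b) {
    s <- synth_session(cfg, block = b)
    dp <- detect_and_preprocess(s)
    build_epoch_dataset(dp$session, dp$scored, dp$labels,
                        all_events = dp$events, seed = b)
  })
  bal <- balance_classes(combine_epochs(dss), seed = 4)
  ho <- group_holdout(bal, 0.25, seed = 8)
  tr <- ho$train; va <- ho$test

  # independent oracle: penalized multinomial logistic regression on the
  # same features must already separate the classes well
  fit <- glmnet::glmnet(tr$features, tr$label, family = "multinomial",
                        lambda = 0.01)
  pl <- predict(fit, va$features, type = "class")
  acc_lr <- mean(pl == as.character(va$label))
  expect_gt(acc_lr, 0.90)

  m <- fit_rotation_model(tr, validation = va,
                          config = model_config(epochs = 30, seed = 5))
  acc_net <- tail(m$history$val_accuracy, 1)
  expect_gt(acc_net, 0.90)
})

test_that("evaluation returns argmax accuracy and a conserving confusion matrix", {
  set.seed(11)
  x <- matrix(rnorm(60 * 1024), 60, 1024)
  y <- factor(rep(c("none", "left", "right"), each = 20),
              levels = c("none", "left", "right"))
  m <- fit_rotation_model(x, y, config = model_config(epochs = 2, seed = 3))
  ev <- evaluate_model(m, x, y)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(as.vector(rowSums(ev$confusion)), rep(20L, 3))
  expect_equal(sum(ev$confusion), 60)
  expect_error(evaluate_model(m, x[0, , drop = FALSE], y[0]), "empty")
  # a uniform-random predictor on balanced classes sits near 1/3
  set.seed(12)
  accs <- replicate(200, mean(sample(3, 300, TRUE) == rep(1:3, each = 100)))
  expect_lt(abs(mean(accs) - 1 / 3), 0.01)
})

test_that("chance threshold matches exact binomial summation", {
  # independent oracle: cumulative binomial probabilities from log-factorials
  brute <- function(n, c, alpha = 0.05) {
    p <- 1 / c
    pmf <- exp(lchoose(n, 0:n) + (0:n) * log(p) + (n:0) * log(1 - p))
    cdf <- cumsum(pmf)
    (which(cdf >= 1 - alpha)[1] - 1) / n
  }
  expect_equal(chance_threshold(330, 3, 0.05), brute(330, 3))
  expect_equal(chance_threshold(330, 3, 0.05), 124 / 330)
  expect_equal(round(100 * chance_threshold(330, 3, 0.05)), 38)
  expect_equal(chance_threshold(100, 2, 0.05), 58 / 100)
  # alpha -> 1 limit: threshold collapses to zero
  expect_equal(chance_threshold(50, 3, 1 - 1e-12), 0)
  for (n in c(1, 7, 33, 110, 256, 500)) {
    for (cl in 2:4) {
      expect_equal(chance_threshold(n, cl), brute(n, cl),
                   info = sprintf("n=%d c=%d", n, cl))
    }
  }
})

test_that("left-right accuracy stays at coin-flip without lateralization", {
  # direction information only enters through lateralization_fraction; at 0
  # the model may detect rotation-vs-none but not the side
  n_lr <- 0; n_correct <- 0
  for (seed in 1:4) {
    s <- synth_session(synth_config(block_duration = 100, rp_amplitude = 25,
                                    lateralization_fraction = 0,
                                    artifact_rate = 0, seed = 100 + seed))
    dp <- detect_and_preprocess(s)
    ds <- build_epoch_dataset(dp$session, dp$scored, dp$labels,
                              all_events = dp$events, seed = seed)
    bal <- balance_classes(ds, seed = seed)
    ho <- group_holdout(bal, 0.25, seed = seed)
    m <- fit_rotation_model(ho$train, config = model_config(epochs = 15,
                                                            seed = seed))
    is_rot <- ho$test$label %in% c("left", "right")
    p <- predict(m, ho$test$features[is_rot, , drop = FALSE])
    side <- ifelse(p[, "left"] >= p[, "right"], "left", "right")
    n_lr <- n_lr + sum(is_rot)
    n_correct <- n_correct + sum(side == as.character(ho$test$label[is_rot]))
  }
  expect_gt(n_lr, 30)
  ci <- qbinom(c(0.005, 0.995), n_lr, 0.5) / n_lr
  expect_gte(n_correct / n_lr, ci[1])
  expect_lte(n_correct / n_lr, ci[2])
})
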