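# Per-participant 3-class rotation classifier: a dense multi-layer
# perceptron (1024 -> 512 -> 256 -> 6 -> 3) with ReLU hidden units, sigmoid
# outputs, dropout on the first two hidden layers, L2 weight penalty, and
# Adam optimization of a categorical cross-entropy loss. Implemented with
# plain matrix algebra so training is fully deterministic under a seed.

#' Classifier configuration
#'
#' @param input_dim Number of input features (32 channels x 32 samples).
#' @param hidden Hidden-layer widths.
#' @param l2_penalty L2 regularization coefficient applied to all weights.
#' @param dropout Dropout probability on the first two hidden layers.
#' @param learning_rate Adam step size.
#' @param epochs Number of training passes over the data.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   dropout masks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim = 1024,
                         hidden = c(512, 256, 6),
                         l2_penalty = 1e-4,
                         dropout = 0.10,
                         learning_rate = 0.001,
                         epochs = 150,
                         batch_size = 150,
                         seed = 1L) {
  stopifnot(input_dim >= 1, all(hidden >= 1), l2_penalty >= 0,
            dropout >= 0, dropout < 1, learning_rate > 0,
            epochs >= 1, batch_size >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_classes = 3L, l2_penalty = l2_penalty, dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize an untrained network
#'
#' He-style Gaussian initialization, seeded from the configuration.
#'
#' @param cfg A [model_config()].
#' @return A list of weight matrices `W` and bias vectors `b`, one per layer.
#' @export
build_rotation_net <- function(cfg = model_config()) {
  sizes <- c(cfg$input_dim, cfg$hidden, cfg$n_classes)
  set.seed(cfg$seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

#' Number of trainable parameters
#'
#' @param net A network from [build_rotation_net()] or a fitted
#'   `rotation_model`.
#' @return Integer count of weights plus biases.
#' @export
n_parameters <- function(net) {
  if (inherits(net, "rotation_model")) net <- net$net
  sum(vapply(net$W, length, numeric(1))) +
    sum(vapply(net$b, length, numeric(1)))
}

relu <- function(x) (x + abs(x)) / 2
sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; returns activations of all layers. Dropout masks (inverted
# dropout) are applied to the first two hidden layers only when training.
mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    if (l < L) {
      H <- relu(Z)
      if (train && dropout > 0 && l <= 2) {
        m <- matrix(runif(length(H)) >= dropout, nrow(H), ncol(H)) /
          (1 - dropout)
        H <- H * m
        masks[[l]] <- m
      }
      A[[l + 1]] <- H
    } else {
      A[[l + 1]] <- sigmoid(Z)
    }
  }
  list(A = A, masks = masks)
}

# categorical cross-entropy on sum-normalized sigmoid outputs:
# p_i = s_i / sum(s); L = -mean(log p_true). The raw sigmoids are what the
# model reports at inference; the normalization lives inside the loss only.
cce_loss <- function(S, Y) {
  P <- S / rowSums(S)
  -mean(log(pmax(P[Y], 1e-12)))
}

# gradient of the loss w.r.t. the pre-sigmoid logits; the 1/s singularity of
# dL/ds cancels against the sigmoid derivative: dL/dz = (1-s)(s/sum(s) - y)
cce_grad_logits <- function(S, Ymat) {
  (1 - S) * (S / rowSums(S) - Ymat) / nrow(S)
}

#' Fit the rotation classifier
#'
#' Trains the multi-layer perceptron on balanced, labeled epochs. Features
#' are standardized per feature with training-set statistics (location and
#' scale), which are stored in the model and applied identically at
#' inference. The loss is categorical cross-entropy on sum-normalized
#' sigmoid outputs with an L2 weight penalty; optimization is Adam in
#' mini-batches. Training runs exactly `config$epochs` passes and is
#' deterministic given `config$seed`.
#'
#' @param x Feature matrix, epochs x `input_dim` (from an `epoch_dataset`'s
#'   `features`), or an `epoch_dataset`.
#' @param y Factor of labels with levels `none`, `left`, `right`; ignored
#'   when `x` is an `epoch_dataset`.
#' @param validation Optional list or `epoch_dataset` with held-out `x`/`y`
#'   used to record validation loss and accuracy per epoch (never trained
#'   on).
#' @param config A [model_config()].
#' @param verbose Print progress every 10 epochs.
#' @return An object of class `rotation_model`: the fitted weights, the
#'   configuration, normalization statistics, class levels, and per-epoch
#'   training history.
#' @export
#' @seealso [predict.rotation_model()], [evaluate_model()],
#'   [chance_threshold()]
fit_rotation_model <- function(x, y = NULL, validation = NULL,
                               config = model_config(), verbose = FALSE) {
  if (inherits(x, "epoch_dataset")) { y <- x$label; x <- x$features }
  if (inherits(validation, "epoch_dataset"))
    validation <- list(x = validation$features, y = validation$label)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (ncol(x) != config$input_dim)
    stop(sprintf("feature length %d does not match input_dim %d",
                 ncol(x), config$input_dim))
  levels3 <- c("none", "left", "right")
  y <- factor(y, levels = levels3)
  stopifnot(!anyNA(y))

  # per-feature standardization from the training partition only
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev < 1e-8] <- 1
  X <- sweep(sweep(x, 2, mu), 2, sdev, `/`)
  n <- nrow(X)
  Ymat <- matrix(0, n, 3)
  Ymat[cbind(seq_len(n), as.integer(y))] <- 1

  Xval <- NULL
  if (!is.null(validation)) {
    yval <- factor(validation$y, levels = levels3)
    Xval <- sweep(sweep(validation$x, 2, mu), 2, sdev, `/`)
    Yvalmat <- matrix(0, nrow(Xval), 3)
    Yvalmat[cbind(seq_len(nrow(Xval)), as.integer(yval))] <- 1
  }

  net <- build_rotation_net(config)
  L <- length(net$W)
  adam <- list(mW = lapply(net$W, function(w) w * 0),
               vW = lapply(net$W, function(w) w * 0),
               mb = lapply(net$b, function(b) b * 0),
               vb = lapply(net$b, function(b) b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  hist_train <- numeric(config$epochs)
  hist_val <- rep(NA_real_, config$epochs)
  hist_val_acc <- rep(NA_real_, config$epochs)

  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      Xb <- X[bt, , drop = FALSE]
      Yb <- Ymat[bt, , drop = FALSE]
      fw <- mlp_forward(net, Xb, config$dropout, train = TRUE)
      S <- fw$A[[L + 1]]
      dZ <- cce_grad_logits(S, Yb)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$A[[l]], dZ) + config$l2_penalty * net$W[[l]]
        gb <- colSums(dZ)
        if (l > 1) {
          dA <- tcrossprod(dZ, net$W[[l]])
          H <- fw$A[[l]]
          dZ <- dA * (H > 0)
          if (!is.null(fw$masks[[l - 1]])) dZ <- dZ * fw$masks[[l - 1]]
        }
        step_l <- step + 1
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW^2
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb^2
        mhW <- adam$mW[[l]] / (1 - beta1^step_l)
        vhW <- adam$vW[[l]] / (1 - beta2^step_l)
        mhb <- adam$mb[[l]] / (1 - beta1^step_l)
        vhb <- adam$vb[[l]] / (1 - beta2^step_l)
        net$W[[l]] <- net$W[[l]] - config$learning_rate * mhW / (sqrt(vhW) + eps)
        net$b[[l]] <- net$b[[l]] - config$learning_rate * mhb / (sqrt(vhb) + eps)
      }
      step <- step + 1
    }
    S_tr <- mlp_forward(net, X)$A[[L + 1]]
    hist_train[ep] <- cce_loss(S_tr, cbind(seq_len(n), as.integer(y)))
    if (!is.null(Xval)) {
      S_v <- mlp_forward(net, Xval)$A[[L + 1]]
      hist_val[ep] <- cce_loss(S_v, cbind(seq_len(nrow(Xval)), as.integer(yval)))
      hist_val_acc[ep] <- mean(max.col(S_v) == as.integer(yval))
    }
    if (verbose && ep %% 10 == 0)
      cat(sprintf("epoch %3d  train loss %.4f  val loss %s\n", ep,
                  hist_train[ep],
                  if (is.na(hist_val[ep])) "-" else sprintf("%.4f", hist_val[ep])))
  }

  structure(list(net = net, config = config,
                 normalization = list(center = mu, scale = sdev),
                 levels = levels3,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = hist_train,
                                      val_loss = hist_val,
                                      val_accuracy = hist_val_acc),
                 n_train = n),
            class = "rotation_model")
}

#' Predict class probabilities or classes
#'
#' Applies the stored training-set normalization and a deterministic forward
#' pass (no dropout). Probabilities are the raw sigmoid activations of the
#' three output units, ordered `none`, `left`, `right`; they need not sum
#' to 1 because the outputs are independent sigmoids.
#'
#' @param object A fitted `rotation_model`.
#' @param newdata Feature matrix (epochs x 1024), a single feature vector, or
#'   an `epoch_dataset`.
#' @param type `"prob"` for the probability matrix, `"class"` for the argmax
#'   class factor.
#' @param ... Unused.
#' @return A numeric matrix (epochs x 3) or a factor of predicted classes.
#' @export
predict.rotation_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "epoch_dataset")) newdata <- newdata$features
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$config$input_dim)
    stop(sprintf("feature length %d does not match input_dim %d",
                 ncol(newdata), object$config$input_dim))
  X <- sweep(sweep(newdata, 2, object$normalization$center), 2,
             object$normalization$scale, `/`)
  S <- mlp_forward(object$net, X)$A[[length(object$net$W) + 1]]
  colnames(S) <- object$levels
  if (type == "prob") S else
    factor(object$levels[max.col(S, ties.method = "first")],
           levels = object$levels)
}

#' Evaluate a fitted model on labeled test epochs
#'
#' The predicted class is the argmax of the three output probabilities.
#'
#' @param model A `rotation_model`.
#' @param x Test feature matrix or `epoch_dataset`.
#' @param y Test labels (ignored when `x` is an `epoch_dataset`).
#' @return List with `accuracy` and `confusion` (3 x 3 table, rows = true
#'   class, columns = predicted class).
#' @export
evaluate_model <- function(model, x, y = NULL) {
  if (inherits(x, "epoch_dataset")) { y <- x$label; x <- x$features }
  if (length(y) == 0) stop("empty test set")
  y <- factor(y, levels = model$levels)
  pred <- predict(model, x, type = "class")
  list(accuracy = mean(pred == y),
       confusion = table(true = y, predicted = pred))
}

#' Exact binomial chance-level threshold
#'
#' Upper bound of the accuracy a random classifier reaches with probability
#' `alpha` on `n_trials` test intervals: the smallest `k` such that the
#' Binomial(`n_trials`, `1/n_classes`) CDF at `k` is at least `1 - alpha`,
#' returned as `k / n_trials`.
#'
#' @param n_trials Number of test intervals.
#' @param n_classes Number of balanced classes (chance rate `1/n_classes`).
#' @param alpha Significance level.
#' @return Accuracy bound in \[0, 1\].
#' @export
#' @examples
#' chance_threshold(330, 3)          # ~0.376, i.e., about 38%
#' chance_threshold(100, 2)          # 0.58
chance_threshold <- function(n_trials, n_classes = 3, alpha = 0.05) {
  stopifnot(n_trials >= 1, n_classes >= 2, alpha > 0, alpha < 1)
  k <- qbinom(1 - alpha, n_trials, 1 / n_classes)
  k / n_trials
}

#' @export
print.rotation_model <- function(x, ...) {
  sizes <- x$net$sizes
  cat("<rotation_model> dense MLP", paste(sizes, collapse = " -> "), "\n")
  cat("  parameters:", n_parameters(x), " trained on", x$n_train,
      "epochs for", x$config$epochs, "passes\n")
  cat(sprintf("  final train loss %.4f", tail(x$history$train_loss, 1)))
  if (!is.na(tail(x$history$val_loss, 1)))
    cat(sprintf("  val loss %.4f  val accuracy %.3f",
                tail(x$history$val_loss, 1),
                tail(x$history$val_accuracy, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.rotation_model <- function(object, ...) {
  out <- list(sizes = object$net$sizes,
              n_parameters = n_parameters(object),
              config = object$config,
              history = object$history)
  class(out) <- "summary.rotation_model"
  out
}

#' @export
print.summary.rotation_model <- function(x, ...) {
  cat("Dense MLP", paste(x$sizes, collapse = " -> "),
      "|", x$n_parameters, "parameters\n")
  cat("Training history (last 5 epochs):\n")
  print(tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.rotation_model <- function(object, ...) {
  list(weights = object$net$W, biases = object$net$b)
}

#' Plot training history
#'
#' Training (and, when recorded, validation) loss per epoch.
#'
#' @param x A `rotation_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rotation_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
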