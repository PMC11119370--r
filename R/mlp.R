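## A small fully connected feed-forward network for binary
## classification, trained with Adam on binary cross-entropy. This is
## the evaluation model used for the biomarker features: ReLU hidden
## layers with inverted dropout, a single sigmoid output unit.

#' MLP architecture specification
#'
#' @param n_hidden_layers number of hidden layers (default 6).
#' @param hidden_width units per hidden layer (default 64).
#' @param dropout_rate dropout fraction in `[0, 1)` after every hidden
#'   layer during training (default 0.25).
#' @param epochs,batch_size,learning_rate training schedule.
#' @return an object of class `mlp_architecture`.
#' @export
mlp_architecture <- function(n_hidden_layers = 6L, hidden_width = 64L,
                             dropout_rate = 0.25, epochs = 200L,
                             batch_size = 32L, learning_rate = 1e-3) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must be in [0, 1)")
  structure(list(n_hidden_layers = check_count(n_hidden_layers, "n_hidden_layers"),
                 hidden_width = check_count(hidden_width, "hidden_width"),
                 dropout_rate = dropout_rate,
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = learning_rate),
            class = "mlp_architecture")
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the MLP probability scorer
#'
#' Forward pass: `h_0 = x`, `h_l = max(0, h_{l-1} W_l + b_l)` for each
#' hidden layer (with inverted dropout at rate `arch$dropout_rate`
#' during training only), and `P(y = 1 | x) = sigmoid(h_L w + b)` at the
#' output. Trained by Adam on binary cross-entropy with mini-batches.
#' Features are z-scored with statistics estimated from the training
#' data (stored in the model, applied again at prediction time).
#'
#' @param x_train numeric matrix (subjects x features).
#' @param y_train binary labels (0/1), both classes present.
#' @param arch an [mlp_architecture()].
#' @param seed integer seed; training is deterministic given it.
#' @param standardize z-score features with training statistics.
#' @return an object of class `brainctrl_mlp` with a [predict] method
#'   returning probabilities.
#' @export
train_mlp <- function(x_train, y_train, arch = mlp_architecture(),
                      seed = 1L, standardize = TRUE) {
  x_train <- as.matrix(x_train)
  y_train <- as.numeric(y_train)
  if (nrow(x_train) != length(y_train))
    stop_invalid("x_train rows (%d) must match y_train length (%d)",
                 nrow(x_train), length(y_train))
  if (length(unique(y_train)) < 2 || min(table(y_train)) < 2)
    stop_invalid("training data needs at least 2 subjects in each class")
  center <- rep(0, ncol(x_train)); scale_ <- rep(1, ncol(x_train))
  if (standardize) {
    center <- colMeans(x_train)
    scale_ <- apply(x_train, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x_train <- sweep(sweep(x_train, 2, center), 2, scale_, "/")
  }
  set.seed(seed)
  sizes <- c(ncol(x_train), rep(arch$hidden_width, arch$n_hidden_layers), 1L)
  L <- length(sizes) - 1
  # He initialization for the ReLU stack
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- arch$learning_rate
  n <- nrow(x_train)
  keep <- 1 - arch$dropout_rate
  step <- 0
  for (epoch in seq_len(arch$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = arch$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + arch$batch_size - 1, n)]
      xb <- x_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      m <- length(idx)
      # forward with dropout masks
      h <- vector("list", L + 1); h[[1]] <- xb
      masks <- vector("list", L)
      for (l in seq_len(L - 1)) {
        z <- sweep(h[[l]] %*% W[[l]], 2, b[[l]], "+")
        a <- relu(z)
        if (keep < 1) {
          msk <- matrix(stats::rbinom(length(a), 1, keep), nrow(a)) / keep
          a <- a * msk
          masks[[l]] <- msk
        }
        h[[l + 1]] <- a
      }
      zout <- drop(h[[L]] %*% W[[L]]) + b[[L]]
      p <- sigmoid(zout)
      # backward: d(BCE)/d(zout) = p - y
      delta <- matrix((p - yb) / m, ncol = 1)
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(h[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          back <- delta %*% t(W[[l]])
          act <- h[[l]]
          back <- back * (act > 0)
          if (keep < 1 && !is.null(masks[[l - 1]])) back <- back * masks[[l - 1]]
          delta <- back
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  }
  structure(list(W = W, b = b, arch = arch, center = center,
                 scale = scale_, seed = seed),
            class = "brainctrl_mlp")
}

#' Predict MDD-class probabilities from a trained MLP
#' @param object a `brainctrl_mlp`.
#' @param newdata numeric matrix (subjects x features).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.brainctrl_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  L <- length(object$W)
  h <- x
  for (l in seq_len(L - 1))
    h <- relu(sweep(h %*% object$W[[l]], 2, object$b[[l]], "+"))
  drop(sigmoid(drop(h %*% object$W[[L]]) + object$b[[L]]))
}

#' @export
print.brainctrl_mlp <- function(x, ...) {
  a <- x$arch
  cat(sprintf("MLP scorer: %d hidden layers x %d units, dropout %.2f, %d input features\n",
              a$n_hidden_layers, a$hidden_width, a$dropout_rate, nrow(x$W[[1]])))
  invisible(x)
}
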