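# ---- Lightweight dense ANN: torque/angle/load estimation ----
#
# Two hidden ReLU layers and a task head (softmax classifier or linear
# regressor), trained with Adam. Implemented directly on base matrix algebra;
# all randomness (init, split, shuffling) flows from one seed, so training is
# reproducible on a single thread.

.relu <- function(z) pmax(z, 0)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.mlp_init <- function(d, h1, h2, k) {
  # He-scaled gaussian init for the ReLU stack
  list(W1 = matrix(stats::rnorm(d * h1, 0, sqrt(2 / d)), d, h1),
       b1 = numeric(h1),
       W2 = matrix(stats::rnorm(h1 * h2, 0, sqrt(2 / h1)), h1, h2),
       b2 = numeric(h2),
       W3 = matrix(stats::rnorm(h2 * k, 0, sqrt(2 / h2)), h2, k),
       b3 = numeric(k))
}

.mlp_forward <- function(w, X, task) {
  A1 <- .relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- .relu(sweep(A1 %*% w$W2, 2, w$b2, "+"))
  Z3 <- sweep(A2 %*% w$W3, 2, w$b3, "+")
  out <- if (task == "classification") .softmax(Z3) else Z3
  list(A1 = A1, A2 = A2, out = out)
}

# Mean loss and parameter gradients for one batch.
# Classification: sparse categorical cross-entropy, y = 1-based class index.
# Regression: mean squared error, y numeric.
.mlp_grad <- function(w, X, y, task) {
  n <- nrow(X)
  fw <- .mlp_forward(w, X, task)
  if (task == "classification") {
    P <- fw$out
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
    dZ3 <- P
    dZ3[cbind(seq_len(n), y)] <- dZ3[cbind(seq_len(n), y)] - 1
    dZ3 <- dZ3 / n
  } else {
    err <- fw$out[, 1] - y
    loss <- mean(err^2)
    dZ3 <- matrix(2 * err / n, ncol = 1)
  }
  gW3 <- crossprod(fw$A2, dZ3); gb3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(w$W3); dA2[fw$A2 <= 0] <- 0
  gW2 <- crossprod(fw$A1, dA2); gb2 <- colSums(dA2)
  dA1 <- dA2 %*% t(w$W2); dA1[fw$A1 <= 0] <- 0
  gW1 <- crossprod(X, dA1); gb1 <- colSums(dA1)
  list(loss = loss,
       g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3))
}

.adam_state <- function(w) list(m = lapply(w, function(p) p * 0),
                                v = lapply(w, function(p) p * 0), t = 0)

.adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

.run_epochs <- function(w, st, Xtr, ytr, Xval, yval, task, epochs, lr,
                        batch_size, verbose) {
  n <- nrow(Xtr)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      gr <- .mlp_grad(w, Xtr[b, , drop = FALSE], ytr[b], task)
      up <- .adam_step(w, gr$g, st, lr)
      w <- up$w; st <- up$st
    }
    tr <- .mlp_grad(w, Xtr, ytr, task)$loss
    va <- if (is.null(Xval) || nrow(Xval) == 0) NA_real_
          else .mlp_grad(w, Xval, yval, task)$loss
    row <- data.frame(epoch = ep, train_loss = tr, val_loss = va)
    if (task == "classification") {
      pc <- max.col(.mlp_forward(w, Xtr, task)$out)
      row$train_acc <- mean(pc == ytr)
      row$val_acc <- if (is.null(Xval) || nrow(Xval) == 0) NA_real_
                     else mean(max.col(.mlp_forward(w, Xval, task)$out) == yval)
    }
    hist[[ep]] <- row
    if (verbose) message(sprintf("epoch %3d: train %.4f val %.4f", ep, tr, va))
  }
  list(w = w, st = st, history = do.call(rbind, hist))
}

#' Fit a dense neural network torque/angle/load estimator
#'
#' Fits the two-hidden-layer ReLU network on mean-spectrum feature vectors.
#' For classification the head is a softmax over the distinct label values
#' (sparse categorical cross-entropy loss); for regression it is a single
#' linear output (mean squared error loss). Data are split into
#' training/validation/test sets with a seeded shuffle, features are centred
#' and scaled with training-set statistics, and optimization uses Adam.
#'
#' @param x feature matrix (samples x features).
#' @param y numeric labels: class values (e.g. torque in Nm) for
#'   classification, continuous targets for regression.
#' @param task \code{"classification"} or \code{"regression"}.
#' @param hidden widths of the two hidden layers, default \code{c(256, 64)}.
#' @param epochs training epochs, default 100; 0 returns the initialized
#'   (untrained) network.
#' @param lr Adam learning rate, default 1e-3.
#' @param batch_size minibatch size, default 32.
#' @param split train/validation/test fractions, default \code{c(0.7, 0.1, 0.2)}.
#' @param seed RNG seed controlling init, split and shuffling, default 1.
#' @param standardize centre each feature and scale all features by the
#'   pooled training-set standard deviation, default TRUE.
#' @param verbose print per-epoch losses, default FALSE.
#' @return object of class \code{torque_net}: weights, class-value map,
#'   scaling, per-epoch \code{history}, and the held-out split indices.
#' @examples
#' x <- matrix(rnorm(60), 30, 2); y <- rep(c(1, 2, 3), each = 10)
#' fit <- torque_net(x, y, hidden = c(8, 4), epochs = 2, batch_size = 8)
#' predict(fit, x[1:2, ], type = "prob")
#' @export
torque_net <- function(x, y, task = c("classification", "regression"),
                       hidden = c(256, 64), epochs = 100, lr = 1e-3,
                       batch_size = 32, split = c(0.7, 0.1, 0.2), seed = 1L,
                       standardize = TRUE, verbose = FALSE) {
  task <- match.arg(task)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)),
            length(hidden) == 2, all(hidden >= 1), epochs >= 0,
            length(split) == 3, all(split >= 0))
  if (abs(sum(split) - 1) > 1e-9) stop("split ratios must sum to 1")
  hidden <- as.integer(hidden)

  if (task == "classification") {
    values <- sort(unique(y))
    k <- length(values)
    if (k < 2) stop("classification needs at least two distinct label values")
    yi <- match(y, values)
  } else {
    values <- NULL; k <- 1L; yi <- y
  }

  .with_seed(seed, {
    n <- nrow(x)
    ord <- sample.int(n)
    ntr <- floor(split[1] * n); nva <- floor(split[2] * n)
    idx <- list(train = ord[seq_len(ntr)],
                val = ord[ntr + seq_len(nva)],
                test = ord[setdiff(seq_len(n), seq_len(ntr + nva))])
    if (task == "classification" &&
        length(unique(yi[idx$train])) < k)
      stop("a class is absent from the training split; increase n or adjust split")

    # centre per feature, but use one pooled scale across features: spectra
    # carry class information in their relative bin magnitudes, and per-bin
    # whitening would inflate noise-only bins to the signal's variance
    center <- if (standardize) colMeans(x[idx$train, , drop = FALSE]) else rep(0, ncol(x))
    scl <- rep(1, ncol(x))
    if (standardize) {
      sds <- apply(x[idx$train, , drop = FALSE], 2, stats::sd)
      pooled <- mean(sds[is.finite(sds) & sds > 0])
      if (is.finite(pooled) && pooled > 1e-12) scl <- rep(pooled, ncol(x))
    }
    xs <- sweep(sweep(x, 2, center), 2, scl, "/")

    w <- .mlp_init(ncol(x), hidden[1], hidden[2], k)
    st <- .adam_state(w)
    hist <- NULL
    if (epochs > 0) {
      run <- .run_epochs(w, st, xs[idx$train, , drop = FALSE], yi[idx$train],
                         xs[idx$val, , drop = FALSE], yi[idx$val],
                         task, epochs, lr, batch_size, verbose)
      w <- run$w; st <- run$st; hist <- run$history
    }
    structure(list(weights = w, task = task, class_values = values,
                   hidden = hidden, center = center, scale = scl,
                   history = hist, split_idx = idx,
                   x = x, y = y,
                   config = list(epochs = epochs, lr = lr,
                                 batch_size = batch_size, split = split,
                                 seed = seed, standardize = standardize)),
              class = "torque_net")
  })
}

.net_scale <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$weights$W1))
    stop("feature dimension mismatch: expected ", nrow(object$weights$W1),
         ", got ", ncol(newdata))
  sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
}

#' Predict from a fitted torque network
#'
#' @param object a \code{\link{torque_net}} fit.
#' @param newdata feature matrix.
#' @param type \code{"prob"} (class probabilities), \code{"class"} (the
#'   hard-assigned class value), or \code{"value"} (continuous estimate: the
#'   probability-weighted class value for classifiers, the head output for
#'   regressors). Defaults to \code{"value"}.
#' @param ... unused.
#' @return matrix of probabilities, or a numeric vector.
#' @export
predict.torque_net <- function(object, newdata,
                               type = c("value", "prob", "class"), ...) {
  type <- match.arg(type)
  out <- .mlp_forward(object$weights, .net_scale(object, newdata), object$task)$out
  if (object$task == "regression") {
    if (type != "value") stop("types 'prob' and 'class' require a classifier")
    return(as.numeric(out))
  }
  switch(type,
         prob = { colnames(out) <- format(object$class_values); out },
         class = object$class_values[max.col(out)],
         value = decode_weighted(out, object$class_values))
}

#' Probability-weighted continuous decoding
#'
#' Converts classifier probabilities into a continuous estimate as the
#' probability-weighted sum of the predefined class values,
#' \eqn{\sum_k p_k v_k}.
#'
#' @param probs probability vector, or matrix with one row per sample; rows
#'   must be non-negative and sum to 1 (tolerance 1e-6).
#' @param values numeric class values, one per probability column.
#' @return numeric estimate(s), bounded by \code{range(values)}.
#' @examples
#' decode_weighted(c(0.5, 0.5), c(10, 20))  # 15
#' @export
decode_weighted <- function(probs, values) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != length(values))
    stop("class-value map length does not match the number of classes")
  if (any(!is.finite(values))) stop("class-value map contains missing values")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be non-negative and sum to 1")
  as.numeric(probs %*% values)
}

#' Evaluate an estimator on labelled data
#'
#' @param object fitted model.
#' @param ... passed to methods.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @describeIn evaluate accuracy, confusion matrix, RMSE of the continuous
#'   (probability-weighted or regressed) estimate, and Pearson correlation
#'   between predicted and true values. Defaults to the model's held-out test
#'   split.
#' @param x feature matrix; default: the stored test split.
#' @param y true label values aligned with \code{x}.
#' @export
evaluate.torque_net <- function(object, x = NULL, y = NULL, ...) {
  if (is.null(x)) {
    x <- object$x[object$split_idx$test, , drop = FALSE]
    y <- object$y[object$split_idx$test]
  }
  if (length(y) == 0) stop("empty test set")
  pred_val <- predict(object, x, type = "value")
  out <- list(n = length(y), rmse = sqrt(mean((pred_val - y)^2)))
  if (length(y) < 2 || isTRUE(stats::sd(pred_val) == 0) ||
      isTRUE(stats::sd(y) == 0)) {
    warning("zero-variance predictions or truth: Pearson r undefined")
    out$pearson <- NA_real_
  } else out$pearson <- stats::cor(pred_val, y)
  if (object$task == "classification") {
    pc <- predict(object, x, type = "class")
    out$accuracy <- mean(pc == y)
    lev <- format(object$class_values)
    out$confusion <- table(truth = factor(format(y), levels = lev),
                           predicted = factor(format(pc), levels = lev))
  }
  structure(out, class = "torque_eval")
}

#' @export
print.torque_eval <- function(x, ...) {
  cat("Held-out evaluation (n =", x$n, ")\n")
  if (!is.null(x$accuracy)) cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  RMSE: %.4f\n  Pearson r: %.4f\n", x$rmse, x$pearson))
  invisible(x)
}

#' Fine-tune a fitted network on user-specific data
#'
#' Continues Adam training from the existing weights on a small calibration
#' dataset in the same feature space and with the same label set; the
#' architecture and feature scaling are unchanged.
#'
#' @param object a fitted \code{\link{torque_net}}.
#' @param x,y calibration features and label values.
#' @param epochs additional epochs, default 20; 0 leaves weights unchanged.
#' @param lr fine-tuning learning rate, default 1e-4.
#' @param batch_size minibatch size, default 16.
#' @param seed RNG seed for shuffling, default 1.
#' @return the updated \code{torque_net}.
#' @export
fine_tune <- function(object, x, y, epochs = 20, lr = 1e-4, batch_size = 16,
                      seed = 1L) {
  stopifnot(inherits(object, "torque_net"), epochs >= 0)
  xs <- .net_scale(object, x)
  if (object$task == "classification") {
    if (!all(y %in% object$class_values))
      stop("fine-tuning labels outside the model's class-value map")
    yi <- match(y, object$class_values)
  } else yi <- y
  if (epochs == 0) return(object)
  .with_seed(seed, {
    run <- .run_epochs(object$weights, .adam_state(object$weights),
                       xs, yi, NULL, NULL, object$task, epochs, lr,
                       batch_size, verbose = FALSE)
    object$weights <- run$w
    run$history$phase <- "fine_tune"
    if (!is.null(object$history) && is.null(object$history$phase))
      object$history$phase <- "train"
    object$history <- rbind(object$history, run$history)
    object
  })
}

#' Parameter and FLOP accounting
#'
#' Exact trainable-parameter count and an inference FLOP estimate for the
#' dense stack. Convention: each dense layer costs 2 (multiply + add) per
#' weight plus one add per bias; each ReLU costs one operation per unit;
#' softmax is costed at 3 operations per class. By this convention FLOPs are
#' roughly twice the parameter count.
#'
#' @param object a \code{\link{torque_net}}.
#' @return list with \code{parameters} and \code{flops}.
#' @export
model_footprint <- function(object) {
  stopifnot(inherits(object, "torque_net"))
  w <- object$weights
  nw <- vapply(w[c("W1", "W2", "W3")], length, numeric(1))
  nb <- vapply(w[c("b1", "b2", "b3")], length, numeric(1))
  params <- sum(nw) + sum(nb)
  flops <- 2 * sum(nw) + sum(nb) +               # dense layers
    length(w$b1) + length(w$b2) +                # ReLU
    if (object$task == "classification") 3 * length(w$b3) else 0
  list(parameters = as.integer(params), flops = as.integer(flops))
}

#' @export
print.torque_net <- function(x, ...) {
  fp <- model_footprint(x)
  cat(sprintf(paste0("Dense %s network: %d-%d-%d-%d (%s head)\n",
                     "  %d parameters, ~%d FLOPs per inference\n"),
              x$task, nrow(x$weights$W1), x$hidden[1], x$hidden[2],
              length(x$weights$b3),
              if (x$task == "classification") "softmax" else "linear",
              fp$parameters, fp$flops))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: train %.4f / val %.4f\n",
                last$train_loss, last$val_loss))
  } else cat("  untrained (initialized weights)\n")
  invisible(x)
}

#' @export
summary.torque_net <- function(object, ...) {
  print(object)
  ev <- evaluate(object)
  print(ev)
  invisible(ev)
}

#' @export
plot.torque_net <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ylim = range(c(h$train_loss, h$val_loss),
                                             na.rm = TRUE), ...)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}
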