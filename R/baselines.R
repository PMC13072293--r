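#' Specification of a traditional baseline classifier
#'
#' The three comparison classifiers consume raw RGB triplets in
#' `[0, 255]`: a soft-margin SVM with radial basis kernel
#' `k(u, v) = exp(-||u - v||^2 / s^2)` and kernel scale `s = 5`; a Gaussian
#' naive Bayes classifier with class priors taken from the training data;
#' and a single-hidden-layer neural network (10 ReLU units, softmax
#' output) trained by cross-entropy with an adaptive-moment optimizer.
#'
#' @param kind One of `"svm"`, `"nb"`, `"nn"`.
#' @param kernel_scale SVM kernel scale `s`.
#' @param cost SVM soft-margin cost.
#' @param hidden_units NN hidden-layer width.
#' @param lr,epochs,batch_size NN training configuration.
#' @param seed Integer seed for any stochastic training.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(kind = c("svm", "nb", "nn"),
                          kernel_scale = 5, cost = 1,
                          hidden_units = 10L, lr = 1e-3,
                          epochs = 200L, batch_size = 256L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(kernel_scale > 0, cost > 0, hidden_units >= 1L)
  structure(list(kind = kind, kernel_scale = kernel_scale, cost = cost,
                 hidden_units = as.integer(hidden_units), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

pixel_rgb_matrix <- function(pixels) {
  m <- cbind(r = pixels$r, g = pixels$g, b = pixels$b)
  storage.mode(m) <- "double"
  m
}

# hand-written single-hidden-layer ReLU network (3 -> hidden -> 2 softmax),
# cross-entropy loss, Adam; nnet's hidden units are logistic, hence not used
train_relu_nn <- function(X, y01, spec) {
  set.seed(spec$seed)
  h <- spec$hidden_units
  params <- list(W1 = init_mat(ncol(X), h), b1 = numeric(h),
                 W2 = init_mat(h, 2L), b2 = numeric(2L))
  state <- adam_init(params)
  n <- nrow(X)
  Y <- cbind(1 - y01, y01)  # one-hot: col 2 = positive class
  for (epoch in seq_len(spec$epochs)) {
    perm <- sample.int(n)
    n_batches <- max(1L, n %/% spec$batch_size)
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * spec$batch_size + 1L):min(bi * spec$batch_size, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      B <- nrow(Xb)
      H <- pmax(sweep_add(Xb %*% params$W1, params$b1), 0)
      logits <- sweep_add(H %*% params$W2, params$b2)
      logits <- logits - apply(logits, 1L, max)
      P <- exp(logits) / rowSums(exp(logits))
      G_logits <- (P - Yb) / B
      grads <- list(
        W1 = matrix(0, ncol(X), h), b1 = numeric(h),
        W2 = t(H) %*% G_logits, b2 = colSums(G_logits)
      )
      G_H <- (G_logits %*% t(params$W2)) * (H > 0)
      grads$W1 <- t(Xb) %*% G_H
      grads$b1 <- colSums(G_H)
      st <- adam_step(params, grads, state, spec$lr)
      params <- st$params
      state <- st$state
    }
  }
  params
}

nn_posterior <- function(params, X) {
  H <- pmax(sweep_add(X %*% params$W1, params$b1), 0)
  logits <- sweep_add(H %*% params$W2, params$b2)
  logits <- logits - apply(logits, 1L, max)
  P <- exp(logits) / rowSums(exp(logits))
  P[, 2L]
}

#' Train a baseline classifier
#'
#' @param spec A [baseline_spec()].
#' @param data A labeled pixel set containing both classes (see
#'   [build_balanced_training_set()]); the classifiers are fit on the raw
#'   RGB triplets.
#' @return A `trained_baseline` holding the fitted model.
#' @export
train_baseline <- function(spec, data) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (length(unique(data$label)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  X <- pixel_rgb_matrix(data)
  y <- factor(data$label, levels = c("negative", "positive"))
  fit <- switch(spec$kind,
    svm = {
      set.seed(spec$seed)
      e1071::svm(X, y, kernel = "radial",
                 gamma = 1 / spec$kernel_scale^2, cost = spec$cost,
                 scale = FALSE, probability = FALSE)
    },
    nb = e1071::naiveBayes(X, y),
    nn = train_relu_nn(X, as.numeric(y) - 1, spec)
  )
  structure(list(kind = spec$kind, spec = spec, fit = fit),
            class = "trained_baseline")
}

#' Continuous fluorescence scores from a baseline classifier
#'
#' Higher scores mean "more fluorescent". The SVM returns its signed
#' decision value (oriented toward the positive class); naive Bayes and the
#' neural network return the posterior probability of the positive class.
#'
#' @param model A `trained_baseline`.
#' @param pixels A labeled pixel set, or a 3-column RGB matrix in
#'   `[0, 255]`.
#' @return Numeric score vector, one finite value per pixel.
#' @export
score_pixels <- function(model, pixels) {
  stopifnot(inherits(model, "trained_baseline"))
  X <- if (is.matrix(pixels)) pixels else pixel_rgb_matrix(pixels)
  switch(model$kind,
    svm = {
      dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv)
      # e1071 orients the decision value toward the first class seen in
      # training; flip so that positive-class pixels score high
      if (grepl("^positive/", colnames(dv)[1])) s else -s
    },
    nb = {
      colnames(X) <- c("r", "g", "b")
      as.numeric(stats::predict(model$fit, as.data.frame(X), type = "raw")[, "positive"])
    },
    nn = nn_posterior(model$fit, X)
  )
}
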