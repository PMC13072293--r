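#' Configuration of the contrastive-loss variational autoencoder
#'
#' The anomaly detector is a variational autoencoder with a 10-dimensional
#' input layer (the pixel feature vector), a 3-dimensional Gaussian latent
#' layer and a 10-dimensional sigmoid output layer, trained only on
#' non-fluorescent (normal) pixels. Training minimizes
#' `MSE(reconstruction) + beta(epoch) * KL + lambda * contrastive`, where
#' the KL weight follows a two-phase cyclic annealing schedule (sigmoidal
#' rise to `beta_max` over the first half of each cycle, plateau over the
#' second) and the contrastive term is a squared hinge on the Euclidean
#' distance between the latent means of normal-anomaly pairs. The
#' learning rate decays exponentially from `lr_start` to `lr_end` over the
#' epochs.
#'
#' @param input_dim,latent_dim,output_dim Layer widths (10, 3, 10).
#' @param epochs Training epochs; must be divisible by `2 * cycles` so each
#'   annealing cycle has an integral, even length.
#' @param batch_size Mini-batch size.
#' @param lr_start,lr_end Endpoints of the exponential learning-rate decay.
#' @param beta_max Maximum KL weight (1, 2 and 3 are the settings the package compares).
#' @param cycles Number of annealing cycles.
#' @param margin Contrastive hinge margin, in latent-distance units.
#' @param lambda Weight of the contrastive term.
#' @param hidden_dim Optional width of a ReLU hidden layer inserted in both
#'   encoder and decoder; `NULL` (default) keeps the plain 10-3-10 linear
#'   architecture.
#' @param seed Integer seed governing initialization, batching and the
#'   reparameterization draws.
#' @return A `vae_config` list.
#' @export
vae_config <- function(input_dim = 10L, latent_dim = 3L, output_dim = 10L,
                       epochs = 1000L, batch_size = 256L,
                       lr_start = 0.001, lr_end = 0.0001,
                       beta_max = 1, cycles = 20L,
                       margin = 1, lambda = 1,
                       hidden_dim = NULL, seed = 1L) {
  stopifnot(input_dim >= 1L, latent_dim >= 1L, output_dim >= 1L,
            epochs >= 1L, batch_size >= 1L,
            lr_start > lr_end, lr_end > 0, beta_max > 0,
            cycles >= 1L, margin > 0, lambda >= 0)
  if (epochs %% cycles != 0L)
    stop("epochs must be divisible by cycles", call. = FALSE)
  L <- epochs %/% cycles
  if (L %% 2L != 0L || L < 4L)
    stop("the cycle length epochs/cycles must be even and at least 4",
         call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 output_dim = as.integer(output_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end,
                 beta_max = beta_max, cycles = as.integer(cycles),
                 margin = margin, lambda = lambda,
                 hidden_dim = if (is.null(hidden_dim)) NULL else as.integer(hidden_dim),
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' KL annealing weight at a given epoch
#'
#' Two-phase cyclic schedule: with cycle length `L = epochs/cycles` and
#' in-cycle position `t = epoch mod L`, the first half-cycle rises
#' sigmoidally from 0 to `beta_max` — `beta = beta_max * s(u)` with
#' `u = t/(L/2 - 1)` and the normalized logistic
#' `s(u) = (sigma(12u - 6) - sigma(-6)) / (sigma(6) - sigma(-6))`, so that
#' `s(0) = 0` and `s(1) = 1` exactly — and the second half-cycle holds
#' `beta = beta_max`.
#'
#' @param config A [vae_config()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return The KL weight, in `[0, beta_max]`.
#' @export
beta_at <- function(config, epoch) {
  stopifnot(inherits(config, "vae_config"))
  if (any(epoch < 0L) || any(epoch >= config$epochs))
    stop("epoch out of range", call. = FALSE)
  L <- config$epochs %/% config$cycles
  t <- epoch %% L
  half <- L / 2
  u <- t / (half - 1)
  s <- (stats::plogis(12 * u - 6) - stats::plogis(-6)) /
    (stats::plogis(6) - stats::plogis(-6))
  ifelse(t < half, config$beta_max * s, config$beta_max)
}

#' Learning rate at a given epoch
#'
#' Exponential decay interpolating the configured endpoints:
#' `lr(e) = lr_start * (lr_end/lr_start)^(e/(epochs-1))`, strictly
#' decreasing with `lr(0) = lr_start` and `lr(epochs-1) = lr_end`.
#'
#' @inheritParams beta_at
#' @return The learning rate for that epoch.
#' @export
lr_at <- function(config, epoch) {
  stopifnot(inherits(config, "vae_config"))
  if (any(epoch < 0L) || any(epoch >= config$epochs))
    stop("epoch out of range", call. = FALSE)
  config$lr_start * (config$lr_end / config$lr_start)^(epoch / (config$epochs - 1))
}

#' KL-divergence anomaly score
#'
#' The per-pixel abnormality measure: the closed-form Kullback-Leibler
#' divergence of the encoder's diagonal-Gaussian posterior
#' `N(mu, diag(sigma^2))` from the standard-normal prior,
#' `0.5 * sum_j (mu_j^2 + sigma_j^2 - log sigma_j^2 - 1)`. Zero exactly
#' when the posterior equals the prior; fluorescent (anomalous) pixels map
#' to posteriors far from the prior and score high.
#'
#' @param mu Posterior mean: a length-`d` vector or an `n x d` matrix.
#' @param log_var Posterior log-variance, same shape as `mu`.
#' @return Non-negative score(s), one per row.
#' @examples
#' kl_anomaly_score(c(1, 0, 0), c(0, 0, 0))  # 0.5
#' @export
kl_anomaly_score <- function(mu, log_var) {
  if (!all(is.finite(mu)) || !all(is.finite(log_var)))
    stop("posterior parameters must be finite", call. = FALSE)
  if (is.matrix(mu)) {
    stopifnot(identical(dim(mu), dim(log_var)))
    0.5 * rowSums(mu^2 + exp(log_var) - log_var - 1)
  } else {
    stopifnot(length(mu) == length(log_var))
    0.5 * sum(mu^2 + exp(log_var) - log_var - 1)
  }
}

# ---- small list-of-matrices Adam optimizer (shared with the NN baseline) ----

adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero, v = zero, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (k in names(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_mat <- function(nr, nc, sd = 0.1) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

clvae_params <- function(config) {
  d <- config$input_dim; l <- config$latent_dim; o <- config$output_dim
  hd <- config$hidden_dim
  p <- list()
  if (is.null(hd)) {
    p$W_mu <- init_mat(d, l); p$b_mu <- numeric(l)
    p$W_lv <- init_mat(d, l); p$b_lv <- numeric(l)
    p$W_d <- init_mat(l, o); p$b_d <- numeric(o)
  } else {
    p$W_eh <- init_mat(d, hd); p$b_eh <- numeric(hd)
    p$W_mu <- init_mat(hd, l); p$b_mu <- numeric(l)
    p$W_lv <- init_mat(hd, l); p$b_lv <- numeric(l)
    p$W_dh <- init_mat(l, hd); p$b_dh <- numeric(hd)
    p$W_d <- init_mat(hd, o); p$b_d <- numeric(o)
  }
  p
}

sweep_add <- function(m, v) sweep(m, 2L, v, "+")

# encoder forward; returns mu, log_var (and the hidden activation if any)
clvae_encode_raw <- function(params, X, hidden) {
  if (hidden) {
    He <- pmax(sweep_add(X %*% params$W_eh, params$b_eh), 0)
    list(mu = sweep_add(He %*% params$W_mu, params$b_mu),
         lv = sweep_add(He %*% params$W_lv, params$b_lv),
         He = He)
  } else {
    list(mu = sweep_add(X %*% params$W_mu, params$b_mu),
         lv = sweep_add(X %*% params$W_lv, params$b_lv))
  }
}

clvae_decode_raw <- function(params, Z, hidden) {
  if (hidden) {
    Hd <- pmax(sweep_add(Z %*% params$W_dh, params$b_dh), 0)
    list(Y = sigmoid(sweep_add(Hd %*% params$W_d, params$b_d)), Hd = Hd)
  } else {
    list(Y = sigmoid(sweep_add(Z %*% params$W_d, params$b_d)))
  }
}

# accumulate encoder-parameter gradients for upstream gradients G_mu, G_lv
# arriving at the latent heads, given input X (and hidden activation He)
encoder_backprop <- function(grads, params, X, enc, G_mu, G_lv, hidden) {
  if (hidden) {
    G_He <- G_mu %*% t(params$W_mu) + G_lv %*% t(params$W_lv)
    G_He <- G_He * (enc$He > 0)
    grads$W_mu <- grads$W_mu + t(enc$He) %*% G_mu
    grads$b_mu <- grads$b_mu + colSums(G_mu)
    grads$W_lv <- grads$W_lv + t(enc$He) %*% G_lv
    grads$b_lv <- grads$b_lv + colSums(G_lv)
    grads$W_eh <- grads$W_eh + t(X) %*% G_He
    grads$b_eh <- grads$b_eh + colSums(G_He)
  } else {
    grads$W_mu <- grads$W_mu + t(X) %*% G_mu
    grads$b_mu <- grads$b_mu + colSums(G_mu)
    grads$W_lv <- grads$W_lv + t(X) %*% G_lv
    grads$b_lv <- grads$b_lv + colSums(G_lv)
  }
  grads
}

zero_like <- function(params)
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && all(c("r", "g", "b") %in% names(x)))
    return(pixel_set_features(x))
  stop("expected a feature matrix or a labeled pixel set", call. = FALSE)
}

#' Train the contrastive-loss VAE anomaly detector
#'
#' Trains on normal (non-fluorescent) pixels only. Each epoch iterates
#' seeded mini-batches of the normal set; for every batch the objective is
#' the mean squared reconstruction error plus `beta(epoch)` times the mean
#' posterior KL divergence, plus `lambda` times a contrastive term computed
#' on a same-size batch of normal-anomaly pairs: the squared hinge
#' `mean(max(0, margin - ||mu_normal - mu_anomaly||)^2)` on latent means.
#' Anomaly pixels influence the model only through this term; they are
#' never reconstructed. With no pairs supplied the model degrades to a
#' plain beta-VAE. Training is bit-reproducible for a fixed seed.
#'
#' @param normal Normal-class training data: an `n x 10` feature matrix or
#'   a labeled pixel set (features are then extracted from its RGB values).
#' @param pairs `NULL`, or a list with aligned elements `normal` and
#'   `anomaly` (feature matrices or pixel sets) as produced by
#'   [build_anomaly_training_set()].
#' @param config A [vae_config()].
#' @return A `trained_clvae`: encoder/decoder parameters, the config, and
#'   the per-epoch training-loss trace.
#' @export
train_clvae <- function(normal, pairs = NULL, config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  X_all <- as_feature_matrix(normal)
  if (nrow(X_all) == 0L) stop("normal set is empty", call. = FALSE)
  if (ncol(X_all) != config$input_dim)
    stop("feature dimension does not match config$input_dim", call. = FALSE)
  have_pairs <- !is.null(pairs) && NROW(pairs$normal) > 0L
  if (have_pairs) {
    Pn <- as_feature_matrix(pairs$normal)
    Pa <- as_feature_matrix(pairs$anomaly)
    stopifnot(nrow(Pn) == nrow(Pa), ncol(Pn) == config$input_dim,
              ncol(Pa) == config$input_dim)
  }

  set.seed(config$seed)
  params <- clvae_params(config)
  state <- adam_init(params)
  hidden <- !is.null(config$hidden_dim)
  n <- nrow(X_all)
  bs <- config$batch_size
  D <- config$output_dim
  trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs) - 1L) {
    beta <- beta_at(config, epoch)
    lr <- lr_at(config, epoch)
    perm <- sample.int(n)
    n_batches <- max(1L, n %/% bs)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      X <- X_all[idx, , drop = FALSE]
      B <- nrow(X)

      enc <- clvae_encode_raw(params, X, hidden)
      eps <- matrix(stats::rnorm(B * config$latent_dim), B, config$latent_dim)
      sd_z <- exp(enc$lv / 2)
      Z <- enc$mu + sd_z * eps
      dec <- clvae_decode_raw(params, Z, hidden)

      recon <- mean((dec$Y - X)^2)
      kl <- mean(0.5 * rowSums(enc$mu^2 + exp(enc$lv) - enc$lv - 1))

      grads <- zero_like(params)

      # reconstruction path
      G_logits <- (2 * (dec$Y - X) / (B * D)) * dec$Y * (1 - dec$Y)
      if (hidden) {
        grads$W_d <- grads$W_d + t(dec$Hd) %*% G_logits
        grads$b_d <- grads$b_d + colSums(G_logits)
        G_Hd <- (G_logits %*% t(params$W_d)) * (dec$Hd > 0)
        grads$W_dh <- grads$W_dh + t(Z) %*% G_Hd
        grads$b_dh <- grads$b_dh + colSums(G_Hd)
        G_Z <- G_Hd %*% t(params$W_dh)
      } else {
        grads$W_d <- grads$W_d + t(Z) %*% G_logits
        grads$b_d <- grads$b_d + colSums(G_logits)
        G_Z <- G_logits %*% t(params$W_d)
      }
      G_mu <- G_Z
      G_lv <- G_Z * eps * 0.5 * sd_z

      # KL path
      G_mu <- G_mu + beta * enc$mu / B
      G_lv <- G_lv + beta * 0.5 * (exp(enc$lv) - 1) / B
      grads <- encoder_backprop(grads, params, X, enc, G_mu, G_lv, hidden)

      # contrastive path on latent means of normal-anomaly pairs
      contrast <- 0
      if (have_pairs && config$lambda > 0) {
        pidx <- sample.int(nrow(Pn), B, replace = nrow(Pn) < B)
        Xn <- Pn[pidx, , drop = FALSE]
        Xa <- Pa[pidx, , drop = FALSE]
        en <- clvae_encode_raw(params, Xn, hidden)
        ea <- clvae_encode_raw(params, Xa, hidden)
        diff <- en$mu - ea$mu
        d_pair <- sqrt(rowSums(diff^2))
        hinge <- pmax(0, config$margin - d_pair)
        contrast <- mean(hinge^2)
        active <- hinge > 0 & d_pair > 1e-12
        G_n <- matrix(0, B, config$latent_dim)
        if (any(active)) {
          coef <- numeric(B)
          coef[active] <- config$lambda * (-2 * hinge[active] / B) / d_pair[active]
          G_n <- diff * coef
        }
        Glv0 <- matrix(0, B, config$latent_dim)
        grads <- encoder_backprop(grads, params, Xn, en, G_n, Glv0, hidden)
        grads <- encoder_backprop(grads, params, Xa, ea, -G_n, Glv0, hidden)
      }

      st <- adam_step(params, grads, state, lr)
      params <- st$params
      state <- st$state
      epoch_loss <- epoch_loss + recon + beta * kl + config$lambda * contrast
    }
    trace[epoch + 1L] <- epoch_loss / n_batches
  }

  structure(list(params = params, config = config, loss_trace = trace),
            class = "trained_clvae")
}

#' Encode features with a trained clVAE
#'
#' @param model A `trained_clvae` from [train_clvae()].
#' @param features An `n x 10` feature matrix.
#' @return List with matrices `mu` and `log_var` (`n x latent_dim`).
#' @export
clvae_encode <- function(model, features) {
  stopifnot(inherits(model, "trained_clvae"))
  enc <- clvae_encode_raw(model$params, as_feature_matrix(features),
                          !is.null(model$config$hidden_dim))
  list(mu = enc$mu, log_var = enc$lv)
}

#' Anomaly scores for a feature matrix
#'
#' @inheritParams clvae_encode
#' @return Numeric vector of KL anomaly scores, one per row.
#' @export
score_features <- function(model, features) {
  enc <- clvae_encode(model, features)
  kl_anomaly_score(enc$mu, enc$log_var)
}

#' Per-pixel anomaly score plane for a frame
#'
#' Runs every pixel of the frame through feature extraction, the encoder
#' and the closed-form KL anomaly score.
#'
#' @param model A `trained_clvae`.
#' @param frame An [rgb_frame()].
#' @return A `height x width` numeric matrix of non-negative scores.
#' @export
score_frame <- function(model, frame) {
  stopifnot(is_rgb_frame(frame))
  d <- dim(frame)
  feats <- extract_features(as.vector(frame[, , 1]),
                            as.vector(frame[, , 2]),
                            as.vector(frame[, , 3]))
  matrix(score_features(model, feats), d[1], d[2])
}

#' Calibrate a detection threshold at a target specificity
#'
#' Returns the `ceiling(target * n)`-th ascending order statistic of the
#' negative-class scores. Under the decision rule "flag iff score exceeds
#' the threshold", the achieved specificity on the calibration scores is
#' then always at least the target.
#'
#' @param neg_scores Scores of known-negative pixels.
#' @param target_specificity Fraction in `(0, 1]` (default 0.99, a
#'   conservative operating level for surgical use).
#' @return The threshold.
#' @export
calibrate_threshold <- function(neg_scores, target_specificity = 0.99) {
  if (length(neg_scores) == 0L) stop("neg_scores is empty", call. = FALSE)
  stopifnot(target_specificity > 0, target_specificity <= 1)
  sort(neg_scores)[ceiling(target_specificity * length(neg_scores))]
}
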