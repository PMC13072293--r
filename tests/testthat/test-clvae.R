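test_that("the beta-annealing schedule hits its closed-form identities", {
  cfg <- vae_config()   # 1000 epochs, 20 cycles -> cycle length 50
  expect_equal(beta_at(cfg, 0), 0)
  expect_equal(beta_at(cfg, 24), cfg$beta_max)   # end of the sigmoidal rise
  expect_equal(beta_at(cfg, 25), cfg$beta_max)   # plateau half
  expect_equal(beta_at(cfg, 49), cfg$beta_max)
  expect_identical(beta_at(cfg, 0:49), beta_at(cfg, 50:99))   # periodicity

  b <- beta_at(cfg, 0:(cfg$epochs - 1))
  expect_true(all(b >= 0 & b <= cfg$beta_max))
  # the rise is strictly increasing
  expect_true(all(diff(beta_at(cfg, 0:24)) > 0))

  cfg3 <- vae_config(beta_max = 3)
  expect_equal(beta_at(cfg3, 30), 3)
  expect_error(beta_at(cfg, -1), "range")
  expect_error(beta_at(cfg, 1000), "range")
  expect_error(vae_config(epochs = 1000L, cycles = 30L), "divisible")
  expect_error(vae_config(epochs = 300L, cycles = 20L), "even")
})

test_that("the learning rate decays exponentially between its endpoints", {
  cfg <- vae_config()
  expect_equal(lr_at(cfg, 0), 0.001)
  expect_equal(lr_at(cfg, 999), 0.0001)
  expect_equal(lr_at(cfg, (1000 - 1) / 2), sqrt(0.001 * 0.0001),
               tolerance = 1e-12)   # geometric mean at the midpoint
  lr <- lr_at(cfg, 0:999)
  expect_true(all(diff(lr) < 0))
  expect_error(lr_at(cfg, 1000), "range")
})

test_that("the KL anomaly score evaluates its closed form", {
  expect_equal(kl_anomaly_score(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(kl_anomaly_score(c(1, 0, 0), c(0, 0, 0)), 0.5)
  expect_equal(kl_anomaly_score(c(0, 0, 0), c(1, 0, 0)), 0.5 * (exp(1) - 2))
  # matrix form agrees with row-wise scalar form
  mu <- matrix(rnorm(15), 5, 3)
  lv <- matrix(rnorm(15, 0, 0.5), 5, 3)
  expect_equal(kl_anomaly_score(mu, lv),
               vapply(1:5, function(i) kl_anomaly_score(mu[i, ], lv[i, ]),
                      numeric(1)))
  expect_true(all(kl_anomaly_score(mu, lv) >= 0))
  expect_error(kl_anomaly_score(c(Inf, 0, 0), c(0, 0, 0)), "finite")
})

test_that("training is finite, improving and bit-reproducible", {
  normal <- toy_normal_features(2000, seed = 3)
  set.seed(4)
  anem <- matrix(pmin(pmax(rnorm(3000, 0.8, 0.05), 0), 1), 300, 10)
  pairs <- list(normal = normal[1:300, ], anomaly = anem)
  cfg <- test_vae_config(epochs = 80L, cycles = 10L, seed = 11L)

  m <- train_clvae(normal, pairs, cfg)
  expect_length(m$loss_trace, 80)
  expect_true(all(is.finite(m$loss_trace)))
  # trailing moving average no worse than the leading one
  expect_lte(mean(tail(m$loss_trace, 20)), mean(head(m$loss_trace, 20)))

  m2 <- train_clvae(normal, pairs, cfg)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_identical(m$params, m2$params)

  expect_error(train_clvae(normal[, 1:9], pairs, cfg), "dimension")
  expect_error(train_clvae(normal[0, , drop = FALSE], pairs, cfg), "empty")

  # without pairs the model trains as a plain beta-VAE
  m3 <- train_clvae(normal, NULL, cfg)
  expect_true(all(is.finite(m3$loss_trace)))
})

test_that("anomaly scores separate strong fluorescence from normals", {
  for (seed in 1:3) {
    train_scene <- small_sample_scene(seed = 300 + seed)
    test_scene <- small_sample_scene(seed = 400 + seed)
    trc <- conc_map(train_scene); tec <- conc_map(test_scene)
    neg <- extract_roi_pixels(train_scene$frame, trc == 0, "negative")
    pos <- extract_roi_pixels(train_scene$frame,
                              matrix(trc %in% c(5, 2, 1), nrow(trc)),
                              "positive")
    sets <- build_anomaly_training_set(neg, pos, 6000L, 1000L, seed = seed)
    m <- train_clvae(sets$normal, sets$pairs,
                     test_vae_config(epochs = 100L, cycles = 10L,
                                     seed = seed))
    s_pos <- score_features(m, scene_features(test_scene, tec == 5))
    set.seed(seed)
    neg_idx <- which(tec == 0)[sample.int(sum(tec == 0), 5000L)]
    s_neg <- score_features(m, extract_features(
      test_scene$frame[, , 1][neg_idx], test_scene$frame[, , 2][neg_idx],
      test_scene$frame[, , 3][neg_idx]))
    auc <- roc_curve(c(s_pos, s_neg),
                     rep(c(TRUE, FALSE), c(length(s_pos), length(s_neg))))$auc
    expect_gte(auc, 0.99)

    # vague fluorescence (0.5 ug/mL) scores above the PPIX-free reference
    wells <- test_scene$truth$wells
    ref <- wells[wells$concentration == 0, ]
    ref_mask <- outer(seq_len(nrow(tec)), seq_len(ncol(tec)), function(i, j)
      (i - ref$cx)^2 + (j - ref$cy)^2 <= ref$radius^2)
    s_vague <- score_features(m, scene_features(test_scene, tec == 0.5))
    s_ref <- score_features(m, scene_features(test_scene, ref_mask))
    expect_gt(mean(s_vague), mean(s_ref))
  }
})

test_that("frame scoring agrees with the per-pixel scalar path", {
  m <- train_clvae(toy_normal_features(1500, seed = 5), NULL,
                   test_vae_config(epochs = 40L, cycles = 5L, seed = 6L))
  const <- rgb_frame(array(rep(c(20L, 25L, 60L), each = 12), c(3, 4, 3)))
  plane <- score_frame(m, const)
  expect_equal(dim(plane), c(3, 4))
  expect_equal(length(unique(as.vector(plane))), 1)
  expect_true(all(plane >= 0))

  set.seed(7)
  f <- rgb_frame(array(sample(0:255, 12 * 10 * 3, TRUE), c(12, 10, 3)))
  plane2 <- score_frame(m, f)
  for (k in 1:100) {
    i <- sample(12, 1); j <- sample(10, 1)
    expect_equal(plane2[i, j],
                 score_features(m, extract_features(f[i, j, 1], f[i, j, 2],
                                                    f[i, j, 3])))
  }
})

test_that("threshold calibration is the order-statistic rule", {
  expect_equal(calibrate_threshold(1:100, 0.99), 99)
  expect_equal(sum(1:100 > calibrate_threshold(1:100, 0.99)), 1)
  expect_equal(calibrate_threshold(rep(4.2, 50), 0.99), 4.2)
  expect_equal(calibrate_threshold(c(3, 1, 7, 5), 1.0), 7)
  expect_error(calibrate_threshold(numeric(0)), "empty")

  # achieved specificity always >= target; tau is the smallest candidate
  # score achieving it (brute force over all candidate thresholds)
  set.seed(12)
  for (i in 1:100) {
    s <- round(rexp(sample(5:200, 1)), sample(0:3, 1))
    target <- runif(1, 0.5, 1)
    tau <- calibrate_threshold(s, target)
    expect_gte(mean(s <= tau), target)
    cand <- sort(unique(s))
    ok <- cand[vapply(cand, function(t) mean(s <= t) >= target, logical(1))]
    expect_equal(tau, min(ok))
  }
})
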