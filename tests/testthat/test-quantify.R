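test_that("random-forest permutation importance finds the true predictor", {
  for (seed in 1:3) {
    set.seed(seed + 40)
    n <- 500
    X <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, pixel_feature_names))
    conc <- 5 * X[, "R"] + rnorm(n, 0, 0.1)
    rep <- rank_feature_importance(list(features = X, concentration = conc),
                                   seed = seed)
    expect_equal(rep$feature[rep$rank == 1], "R")
    top <- rep$importance[rep$rank == 1]
    # features independent of the response score at least 10x lower
    expect_true(all(abs(rep$importance[rep$feature != "R"]) < top / 10))
    expect_gt(attr(rep, "oob_r2"), 0.9)
  }
  X <- toy_normal_features(200, seed = 2)
  conc <- 2 * X[, "G"] + rnorm(200, 0, 0.01)
  rep1 <- rank_feature_importance(list(features = X, concentration = conc),
                                  seed = 9)
  rep2 <- rank_feature_importance(list(features = X, concentration = conc),
                                  seed = 9)
  expect_identical(rep1, rep2)
  expect_error(rank_feature_importance(
    list(features = toy_normal_features(20), concentration = runif(20))),
    "50")
})

test_that("polynomial fitters recover generating coefficients exactly", {
  # single predictor quadratic, noise-free regeneration
  x <- seq(0, 1, length.out = 200)
  y <- 2.166 + 7.325 * x - 0.02339 * x^2
  fit <- fit_quadratic_1d(x, y)
  expect_equal(unname(fit$coefficients),
               c(2.166, 7.325, -0.02339), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # degenerate response: zero slope and curvature, R^2 reported as 0
  const <- fit_quadratic_1d(x, rep(2, 200))
  expect_equal(unname(const$coefficients), c(2, 0, 0), tolerance = 1e-9)
  expect_equal(const$r_squared, 0)
  expect_error(fit_quadratic_1d(c(1, 1, 2, 2), c(1, 1, 2, 2)), "distinct")

  # bivariate polynomial on a grid
  g <- expand.grid(x = seq(0, 1, length.out = 20),
                   y = seq(0, 1, length.out = 20))
  z <- 0.0327 - 1.009 * g$x + 0.6343 * g$y + 46.99 * g$x^2 -
    93.46 * g$x * g$y
  fit2 <- fit_poly_2d(g$x, g$y, z)
  expect_equal(unname(fit2$coefficients),
               c(0.0327, -1.009, 0.6343, 46.99, -93.46), tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)

  # response independent of y: its coefficients vanish within noise
  set.seed(3)
  z2 <- 1 + 2 * g$x + 3 * g$x^2 + rnorm(400, 0, 0.01)
  fit3 <- fit_poly_2d(g$x, g$y, z2)
  expect_lt(abs(fit3$coefficients[["p01"]]), 0.02)
  expect_lt(abs(fit3$coefficients[["p11"]]), 0.05)
})

test_that("OLS residuals are orthogonal to every basis column", {
  set.seed(17)
  x <- runif(300); y <- runif(300)
  conc <- 2 + x - 3 * y + rnorm(300)
  f1 <- fit_quadratic_1d(x, conc)
  r1 <- conc - predict_concentration(f1, x, c_max = Inf)
  # clamping would break orthogonality; evaluate the raw polynomial
  co <- f1$coefficients
  r1 <- conc - (co[["p1"]] + co[["p2"]] * x + co[["p3"]] * x^2)
  for (col in list(rep(1, 300), x, x^2))
    expect_lt(abs(sum(r1 * col)), 1e-8)

  f2 <- fit_poly_2d(x, y, conc)
  co <- f2$coefficients
  r2 <- conc - (co[["p00"]] + co[["p10"]] * x + co[["p01"]] * y +
                  co[["p20"]] * x^2 + co[["p11"]] * x * y)
  for (col in list(rep(1, 300), x, y, x^2, x * y))
    expect_lt(abs(sum(r2 * col)), 1e-8)
})

test_that("coefficients are recovered within 3 standard errors under noise", {
  true <- c(1.5, 4, -2)
  n <- 2000
  hits <- 0; total <- 0
  for (rep in 1:20) {
    set.seed(rep + 60)
    x <- runif(n)
    mu <- true[1] + true[2] * x + true[3] * x^2
    conc <- mu + rnorm(n, 0, 0.05 * diff(range(mu)))
    fit <- stats::lm(conc ~ x + I(x^2))
    est <- coef(fit); se <- sqrt(diag(vcov(fit)))
    pkg <- fit_quadratic_1d(x, conc)
    expect_equal(unname(pkg$coefficients), unname(est), tolerance = 1e-10)
    hits <- hits + sum(abs(est - true) <= 3 * se)
    total <- total + 3
  }
  expect_gte(hits / total, 0.95)
})

test_that("the published reference models evaluate and round-trip", {
  quad <- reference_quant_model("quadratic1d")
  expect_equal(predict_concentration(quad, 0), 2.166)
  biv <- reference_quant_model("poly2d")
  expect_equal(predict_concentration(biv, 0, pg = 0), 0.0327)
  # a strongly negative raw value clamps to zero
  expect_equal(predict_concentration(biv, 0.3, pg = 1), 0)
  # and nothing exceeds the clamp ceiling
  expect_true(all(predict_concentration(biv, runif(50), pg = runif(50)) <= 5))

  path <- withr::local_tempfile(fileext = ".json")
  save_quant_model(biv, path)
  back <- load_quant_model(path)
  r <- runif(100); pg <- runif(100)
  expect_identical(predict_concentration(back, r, pg = pg),
                   predict_concentration(biv, r, pg = pg))
})

test_that("concentration maps are clamped, masked and ladder-monotone", {
  scene <- small_sample_scene(seed = 8)
  conc <- conc_map(scene)
  px <- extract_roi_pixels(scene$frame, conc > 0, "positive")
  px$concentration <- conc[conc > 0]
  ft <- extract_features(px$r, px$g, px$b)
  model <- fit_poly_2d(ft[, "R"], ft[, "pG"], px$concentration)

  empty <- render_concentration_map(scene$frame, model,
                                    matrix(FALSE, nrow(conc), ncol(conc)))
  expect_true(all(empty$map == 0))

  out <- render_concentration_map(scene$frame, model, conc > 0)
  expect_true(all(out$map >= 0 & out$map <= model$c_max))
  expect_true(is_rgb_frame(out$overlay))
  med <- vapply(sort(unique(px$concentration)), function(cc)
    median(out$map[conc == cc]), numeric(1))
  expect_true(all(diff(med) > 0))
  expect_error(render_concentration_map(scene$frame, model,
                                        matrix(FALSE, 2, 2)), "dimensions")
})
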