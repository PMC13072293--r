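test_that("ROC curves and AUC match the pairwise-comparison oracle", {
  # perfectly separated scores
  expect_equal(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # all scores tied: chance-level by the tie convention
  expect_equal(roc_curve(rep(3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")

  set.seed(51)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    scores <- sample(1:6, n, TRUE)           # heavy ties on purpose
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    rc <- roc_curve(scores, labels)
    expect_equal(rc$auc, pairwise_auc(scores, labels))
    expect_true(all(rc$sensitivity >= 0 & rc$sensitivity <= 1))
    expect_true(all(rc$specificity >= 0 & rc$specificity <= 1))
    # curve endpoints: nothing flagged -> all flagged
    expect_equal(rc$sensitivity[1], 0)
    expect_equal(rc$specificity[1], 1)
    expect_equal(rc$sensitivity[length(rc$sensitivity)], 1)
    expect_equal(rc$specificity[length(rc$specificity)], 0)
  }

  # independent library cross-check on a continuous-score case
  set.seed(52)
  s <- rnorm(200); l <- rbinom(200, 1, 0.4) == 1
  s[l] <- s[l] + 1
  expect_equal(roc_curve(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the operating point maximizes Youden's J, ties to specificity", {
  perfect <- roc_curve(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  oop <- optimal_operating_point(perfect)
  expect_equal(oop$sensitivity, 1)
  expect_equal(oop$specificity, 1)
  expect_equal(oop$j, 1)
  expect_equal(oop$accuracy, 1)

  # hand-enumerated tie: scores 1..4, labels F,T,F,T; J = 0.5 at both
  # tau = 3 (spec 1) and tau = 1 (spec 0.5) -> the conservative point wins
  tie <- roc_curve(1:4, c(FALSE, TRUE, FALSE, TRUE))
  oop2 <- optimal_operating_point(tie)
  expect_equal(oop2$threshold, 3)
  expect_equal(oop2$specificity, 1)
  expect_equal(oop2$sensitivity, 0.5)

  # label-free scores carry no signal: J stays near zero
  set.seed(53)
  rnd <- roc_curve(rnorm(1000), sample(c(TRUE, FALSE), 1000, TRUE))
  expect_lte(optimal_operating_point(rnd)$j, 0.15)
})

test_that("detection-rate tables count threshold exceedances per level", {
  rates <- detection_rate_table(c(1, 2, 3, 4), rep(5, 4), 2.5)
  expect_equal(rates$detection_rate, 50)

  scores <- c(0.1, 0.9, 0.5, 0.7, 0.2, 0.8)
  concs <- c(5, 5, 1, 1, 0, 0)
  low <- detection_rate_table(scores, concs, min(scores) - 1)
  expect_true(all(low$detection_rate == 100))
  high <- detection_rate_table(scores, concs, max(scores))
  expect_true(all(high$detection_rate == 0))
  expect_equal(low$concentration, c(5, 1, 0))   # descending ladder order

  # invariance under a joint strictly monotone transform of scores and tau
  set.seed(54)
  s <- rnorm(500); cc <- sample(c(5, 1, 0.1), 500, TRUE); tau <- 0.3
  expect_equal(detection_rate_table(exp(s), cc, exp(tau))$detection_rate,
               detection_rate_table(s, cc, tau)$detection_rate)
  expect_error(detection_rate_table(1:3, 1:2, 0), "length")
})

test_that("negative-frame specificity handles black pixels and pooling", {
  f1 <- rgb_frame(array(30L, c(20, 24, 3)))
  m_empty <- matrix(FALSE, 20, 24)
  rep0 <- negative_frame_specificity(list(m_empty), list(f1))
  expect_equal(rep0$specificity_all, 1)
  expect_equal(attr(rep0, "pooled"), 1)

  # frame with 80 black pixels and 12 false positives among 480
  arr <- array(30L, c(20, 24, 3))
  arr[1:4, 1:20, ] <- 0L
  f2 <- rgb_frame(arr)
  m <- matrix(FALSE, 20, 24)
  m[10:12, 1:4] <- TRUE
  rep1 <- negative_frame_specificity(list(m), list(f2))
  expect_equal(rep1$fp, 12)
  expect_equal(rep1$black, 80)
  expect_equal(rep1$specificity_all, 1 - 12 / 480)
  expect_equal(rep1$specificity_excl_black, 1 - 12 / 400)

  # pooled value equals the FP-weighted combination of per-frame values
  m2 <- matrix(FALSE, 20, 24); m2[1, 21:24] <- TRUE
  rep2 <- negative_frame_specificity(list(m, m2), list(f2, f1))
  expect_equal(attr(rep2, "pooled"), 1 - (12 + 4) / 960)
  expect_equal(attr(rep2, "pooled"),
               sum(rep2$total * rep2$specificity_all) / sum(rep2$total))

  all_black <- rgb_frame(array(0L, c(4, 4, 3)))
  expect_error(negative_frame_specificity(list(matrix(FALSE, 4, 4)),
                                          list(all_black)), "undefined")
})

test_that("black pixels are never flagged in detection masks", {
  arr <- array(10L, c(5, 5, 3))
  arr[2, 3, ] <- 0L
  f <- rgb_frame(arr)
  scores <- matrix(100, 5, 5)
  mask <- detection_mask(scores, f, tau = 1)
  expect_false(mask[2, 3])
  expect_equal(sum(mask), 24)
})

test_that("annotation overlap reports areas, ratio and coverage", {
  a <- matrix(FALSE, 10, 10); a[1:2, 1:5] <- TRUE      # 10 px annotation
  m <- a; m[3:4, 1:7] <- TRUE                          # 24 px model mask
  ov <- annotation_overlap(m, a)
  expect_equal(ov$ratio, 2.4)
  expect_equal(ov$coverage, 1)

  same <- annotation_overlap(a, a)
  expect_equal(same$ratio, 1)
  expect_equal(same$coverage, 1)

  disj <- matrix(FALSE, 10, 10); disj[9:10, 9:10] <- TRUE
  expect_equal(annotation_overlap(disj, a)$coverage, 0)
  expect_true(is.na(annotation_overlap(m, matrix(FALSE, 10, 10))$ratio))
  expect_error(annotation_overlap(m, matrix(FALSE, 3, 3)), "differ")
})

test_that("the qualitative embedding separates distant clusters", {
  set.seed(55)
  X <- rbind(matrix(rnorm(250 * 10, 0, 1), 250, 10),
             matrix(rnorm(250 * 10, 10, 1), 250, 10))
  lab <- rep(c(0, 1), each = 250)
  emb <- embed_qualitative(X, perplexity = 40, seed = 3, max_iter = 300)
  expect_equal(nrow(emb), 500)
  expect_identical(emb, embed_qualitative(X, perplexity = 40, seed = 3,
                                          max_iter = 300))
  # nearest-centroid rule on the embedding recovers the clusters
  cent <- rbind(colMeans(emb[lab == 0, ]), colMeans(emb[lab == 1, ]))
  assign <- apply(emb, 1, function(p)
    which.min(colSums((t(cent) - p)^2)) - 1)
  expect_gte(max(mean(assign == lab), mean(assign != lab)), 0.9)
  expect_error(embed_qualitative(X[1:50, ], perplexity = 40), "perplexity")
})
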