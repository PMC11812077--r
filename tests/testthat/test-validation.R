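test_that("pair metrics match hand arithmetic and brute force", {
  m <- pair_metrics(c(5, 4), c(5, 6))
  expect_equal(m$pe_mean, 1)
  expect_equal(m$ape_mean, 1)
  expect_equal(m$rmse, sqrt(2), tolerance = 1e-12)

  m2 <- pair_metrics(1:5, 1:5)
  expect_equal(m2$pe_mean, 0)
  expect_equal(m2$rmse, 0)
  expect_equal(m2$r, 1)

  set.seed(9)
  obs <- rnorm(50, 5); prd <- obs + rnorm(50, 0, 0.5)
  m3 <- pair_metrics(obs, prd)
  expect_equal(m3$rmse, sqrt(mean((prd - obs)^2)), tolerance = 1e-12)
  expect_equal(m3$pe_sd, sd(prd - obs), tolerance = 1e-12)
  # Fisher-z interval contains r and is ordered
  expect_true(m3$r_ci[1] < m3$r && m3$r < m3$r_ci[2])
  # n < 2: correlation unavailable, the rest computed
  m4 <- pair_metrics(5, 6)
  expect_true(is.na(m4$r))
  expect_equal(m4$ape_mean, 1)
})

test_that("confusion matrix counts and marginals reproduce the published table", {
  cm1 <- build_confusion(5, 5)
  expect_identical(sum(cm1), 1L)
  expect_identical(cm1[5, 5], 1L)
  expect_error(build_confusion(0, 5), "1..9")

  cm <- read_confusion(table3_path())
  expect_identical(sum(cm), 5819L)
  expect_identical(sum(cm[5, ]), 2731L) # observed class 5 row total
  expect_identical(sum(cm[, 5]), 2772L) # predicted class 5 column total
  ag <- agreement_counts(cm)
  expect_identical(ag$identical, 3582L)
  expect_identical(ag$within_one, 1917L)
  expect_equal(100 * ag$identical_frac, 61.56, tolerance = 0.005)
  # fractions of all deviation bands sum to one
  d <- abs(row(cm) - col(cm))
  fr <- vapply(0:8, function(k) sum(cm[d == k]) / sum(cm), numeric(1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # diagonal-only matrix has nothing within one
  diagcm <- build_confusion(rep(1:9, 2), rep(1:9, 2))
  expect_identical(agreement_counts(diagcm)$within_one, 0L)
})

test_that("Cohen's kappa matches a direct-formula oracle on the published table", {
  cm <- read_confusion(table3_path())
  k0 <- cohen_kappa(cm, "none")
  kl <- cohen_kappa(cm, "linear")
  kq <- cohen_kappa(cm, "quadratic")
  # frozen values from an independent direct evaluation of
  # kappa = (po - pe)/(1 - pe) on the printed counts
  expect_equal(k0$po, 3582 / 5819, tolerance = 1e-12)
  expect_equal(k0$kappa, 0.4388397503, tolerance = 1e-9)
  expect_equal(kl$kappa, 0.5582507762, tolerance = 1e-9)
  expect_equal(kq$kappa, 0.6820287087, tolerance = 1e-9)
  # weighting order on this tri-diagonally dominant ordinal table
  expect_true(kq$kappa >= kl$kappa && kl$kappa >= k0$kappa)
  # CIs are ordered and finite
  for (k in list(k0, kl, kq)) {
    expect_true(k$ci[1] < k$kappa && k$kappa < k$ci[2])
  }
})

test_that("kappa has known values on canonical tables", {
  perfect <- build_confusion(rep(1:9, 3), rep(1:9, 3))
  for (wt in c("none", "linear", "quadratic")) {
    expect_equal(cohen_kappa(perfect, wt)$kappa, 1)
  }
  # independence: 2x2-style balanced table embedded in 9 classes
  obs <- rep(c(4L, 4L, 5L, 5L), each = 25)
  prd <- rep(c(4L, 5L, 4L, 5L), each = 25)
  expect_equal(cohen_kappa(build_confusion(obs, prd), "none")$kappa, 0)
  # degenerate single-category table is flagged
  one <- build_confusion(rep(5L, 10), rep(5L, 10))
  expect_true(cohen_kappa(one, "none")$degenerate)
})

test_that("unweighted kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  obs <- sample(1:9, 300, replace = TRUE, prob = c(1, 2, 6, 20, 45, 20, 4, 1, 1))
  prd <- pmin(9L, pmax(1L, obs + sample(-2:2, 300, TRUE,
                                        prob = c(1, 3, 10, 3, 1))))
  cm <- build_confusion(obs, prd)
  ours <- cohen_kappa(cm, "none")$kappa
  theirs <- e1071::classAgreement(unclass(cm))$kappa
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Landis-Koch labels follow the printed bands", {
  expect_identical(landis_koch(0.67), "substantial")
  expect_identical(landis_koch(0.15), "slight")
  expect_identical(landis_koch(-0.1), "poor")
  expect_identical(landis_koch(c(0, 0.20, 0.21, 0.405, 0.605, 0.81, 1)),
                   c("slight", "slight", "fair", "moderate", "substantial",
                     "almost perfect", "almost perfect"))
})

test_that("per-DIM summaries equal brute-force group means", {
  prd <- data.frame(animal_id = "a", test_date = Sys.Date(),
                    dim = c(10L, 10L, 40L),
                    y_hat_model = 0, e_hat_bcs = 0,
                    y_hat_continuous = c(5.2, 4.8, 6.5),
                    y_hat_rounded = c(5L, 5L, 7L), obs_bcs = c(5L, 4L, 6L))
  s <- per_dim_summary(prd)
  expect_identical(s$dim, c(10L, 40L))
  expect_equal(s$obs_mean, c(4.5, 6))
  expect_equal(s$pe_mean, c(mean(c(0.2, 0.8)), 0.5))
  expect_equal(s$ape_mean, c(0.5, 0.5))
  # random data: grouped means equal split-apply recomputation
  set.seed(3)
  n <- 200
  prd2 <- data.frame(animal_id = "a", test_date = Sys.Date(),
                     dim = sample(5:20, n, TRUE), y_hat_model = 0,
                     e_hat_bcs = 0, y_hat_continuous = runif(n, 3, 7),
                     y_hat_rounded = 5L, obs_bcs = sample(3:7, n, TRUE))
  s2 <- per_dim_summary(prd2)
  ref <- tapply(prd2$y_hat_continuous - prd2$obs_bcs, prd2$dim, mean)
  expect_equal(s2$pe_mean, as.numeric(ref[as.character(s2$dim)]),
               tolerance = 1e-12)
  # metrics are invariant to pair order
  pm_a <- pair_metrics(prd2$obs_bcs, prd2$y_hat_continuous)
  idx <- sample(n)
  pm_b <- pair_metrics(prd2$obs_bcs[idx], prd2$y_hat_continuous[idx])
  expect_equal(pm_a, pm_b, tolerance = 1e-12)
})
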