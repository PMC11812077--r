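# Unit tests of the EM-REML machinery on small systems. The 10-seed
# parameter-recovery demonstration lives in the acceptance suite.

test_that("balanced repeated records match the closed-form ANOVA-REML", {
  # n cows x m shared visits, one herd, unrelated animals, only MY
  # observed. D and HY are pinned at a negligible value; the regression
  # coefficients beyond the intercept carry a negligible prior variance, so
  # the cow effect is a constant; the minor-stage classes absorb the four
  # visit means. The model then collapses to the balanced two-way design
  # y_ij = mu + visit_j + cow_i + e_ij (visit fixed, cow random), whose
  # REML solution is the ANOVA estimator:
  #   sigma_e^2 = MSE (interaction),  sigma_cow^2 = (MSA - MSE)/m.
  n <- 24; m <- 4
  cows <- sprintf("C%02d", seq_len(n))
  set.seed(31)
  a <- rnorm(n, 0, 2)
  beta <- c(0, 1.5, -1, 0.5) # visit effects
  y <- rep(a, each = m) + rep(beta, times = n) + rnorm(n * m, 0, 1.5) + 30
  visits <- as.Date("2015-05-01") + rep(seq_len(m) * 31, times = n)
  rec <- data.frame(animal_id = rep(cows, each = m), herd_id = "H1",
                    test_date = visits,
                    calving_date = as.Date("2015-03-01"),
                    birth_date = as.Date("2015-03-01") - 800,
                    dim = as.integer(visits - as.Date("2015-03-01")),
                    my = y, fp = NA_real_, pp = NA_real_,
                    bcs = NA_integer_)
  coding <- build_coding(rec)
  Ainv <- build_A_inverse(sort_pedigree(ped_df(cows)))
  tiny <- 1e-6
  intercept_only <- function(M) {
    # small but numerically benign variance for the higher coefficients:
    # the absorbed curve variance is ~1e-5 of the cow variance, far below
    # the comparison tolerance
    out <- diag(1e-5 * mean(diag(M)), 12)
    for (t in 1:4) out[(t - 1) * 3 + 1, (t - 1) * 3 + 1] <- M[(t - 1) * 3 +
                                                              1, (t - 1) *
                                                              3 + 1]
    out
  }
  base <- init_components(rec)
  init <- cov_components(D = diag(tiny, 4), HY = diag(tiny, 12),
                         P = intercept_only(base$P),
                         G = intercept_only(base$G), R = base$R)
  est <- suppressWarnings(
    estimate_components(rec, coding, legendre_basis(), Ainv, init = init,
                        settings = list(max_iter = 500, tol = 1e-10,
                                        fix = c("D", "HY"))))
  # with A = I the cow variance is identified as the G + P daily total,
  # constant over DIM because only the intercept coefficient is loaded
  phi <- as.numeric(legendre_covariates(rec$dim[1]))
  GP <- est$components$G[1:3, 1:3] + est$components$P[1:3, 1:3]
  va_hat <- drop(phi %*% GP %*% phi)
  # balanced two-way ANOVA oracle
  ybar_i <- tapply(y, rec$animal_id, mean)
  ybar_j <- tapply(y, rec$dim, mean)
  ybar <- mean(y)
  MSA <- m * sum((ybar_i - ybar)^2) / (n - 1)
  fit2 <- y - ybar_i[rec$animal_id] - ybar_j[as.character(rec$dim)] + ybar
  MSE <- sum(fit2^2) / ((n - 1) * (m - 1))
  expect_equal(va_hat, (MSA - MSE) / m, tolerance = 1e-4)
  expect_equal(est$components$R[1, 1], MSE, tolerance = 1e-4)
  # EM never decreased the restricted log-likelihood
  expect_true(all(diff(est$trace$loglik) > -1e-8))
})

test_that("zero simulated genetic variance drives G toward the boundary", {
  # EM approaches a zero-variance boundary sublinearly, so full collapse of
  # G is not reachable in a test-sized iteration budget; boundary
  # attraction is asserted instead: the genetic fraction shrinks from its
  # starting value, and the restricted likelihood of the boundary model
  # (G pinned near zero) dominates the free fit.
  truth <- default_truth()
  truth0 <- cov_components(truth$D, truth$HY, truth$P, 1e-8 * truth$G,
                           truth$R)
  cfg <- sim_config(n_herds = 6, cows_per_herd = c(12, 15), seed = 17,
                    n_males = 5,
                    calving_window = c("2014-01-01", "2015-06-30"),
                    test_years = 2014:2016, truth = truth0, bcs_prob = 1)
  s <- simulate_records(cfg)
  rec <- apply_edits(s$records)$records
  coding <- build_coding(rec)
  Ainv <- build_A_inverse(s$pedigree)
  est <- suppressWarnings(
    estimate_components(rec, coding, legendre_basis(), Ainv,
                        settings = list(max_iter = 50, tol = 1e-6)))
  expect_true(all(diff(est$trace$loglik) > -1e-8))
  # every trait's mean daily heritability fell from the 0.10 start
  h2 <- daily_parameters(est$components)$h2_mean
  expect_true(all(h2 < 0.095))
  # and the likelihood prefers the boundary over the free fit
  base <- init_components(rec)
  bdry <- suppressWarnings(estimate_components(
    rec, coding, legendre_basis(), Ainv,
    init = cov_components(base$D, base$HY, base$P, 1e-4 * base$G, base$R),
    settings = list(max_iter = 25, tol = 1e-8, fix = "G")))
  expect_gt(utils::tail(bdry$trace$loglik, 1),
            utils::tail(est$trace$loglik, 1))
})

test_that("estimates are invariant to record order", {
  d <- small_fit_data(seed = 23, n_herds = 2, cows = c(10, 11))
  rec <- d$records
  coding <- build_coding(rec)
  Ainv <- build_A_inverse(d$sim$pedigree)
  run <- function(r) {
    estimate_components(r, build_coding(r), legendre_basis(), Ainv,
                        settings = list(max_iter = 4, tol = 1e-8))$components
  }
  set.seed(99)
  perm <- sample(nrow(rec))
  c1 <- suppressWarnings(run(rec))
  c2 <- suppressWarnings(run(rec[perm, ]))
  for (nm in c("D", "HY", "P", "G", "R")) {
    expect_lt(max(abs(c1[[nm]] - c2[[nm]])), 1e-8)
  }
})

test_that("daily parameters follow the covariance functions", {
  truth <- default_truth()
  dp <- daily_parameters(truth)
  # G = 0 gives h2 = 0 everywhere
  z <- cov_components(truth$D, truth$HY, truth$P, 1e-12 * truth$G, truth$R)
  expect_lt(max(daily_parameters(z)$h2), 1e-6)
  # only-phi0-loaded diagonal components give a flat h2 curve
  flat <- local({
    m <- matrix(0, 12, 12)
    diag(m)[c(1, 4, 7, 10)] <- 1
    cov_components(diag(4), m, m, m, diag(4))
  })
  h2f <- daily_parameters(flat)$h2
  expect_lt(max(apply(h2f, 2, sd)), 1e-12)
  # components constructed so that v_g/(total) = 0.11 at every DIM
  m11 <- local({
    m <- matrix(0, 12, 12)
    diag(m)[c(1, 4, 7, 10)] <- 2 * 0.11 # phi0^2 = 1/2, so daily v_g = 0.11
    m
  })
  prop <- cov_components(diag(0.20, 4), 1e-12 * diag(12),
                         (0.30 / 0.11) * m11, m11, diag(0.39, 4))
  expect_equal(unname(daily_parameters(prop)$h2_mean), rep(0.11, 4),
               tolerance = 1e-10)
})

test_that("default truth implies the intended daily parameters", {
  dp <- daily_parameters(default_truth())
  expect_equal(unname(dp$h2_mean),
               c(0.16, 0.22, 0.25, 0.11), tolerance = 0.02)
  expect_gt(dp$h2_mean[4], 0.09)
  expect_lt(dp$h2_mean[4], 0.13)
  expect_lt(dp$rg_mean["MY", "BCS"], 0) # negative yield-condition correlation
  expect_lt(dp$rg_mean["MY", "FP"], 0)
  expect_gt(dp$rg_mean["FP", "PP"], 0)
})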