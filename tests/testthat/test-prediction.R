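test_that("rounding to the 9-point scale is away-from-zero with clamping", {
  expect_identical(round_bcs(c(4.4, 4.5, 9.7, 0.2)), c(4L, 5L, 9L, 1L))
  expect_identical(round_bcs(c(1.49, 8.5)), c(1L, 9L))
  expect_error(round_bcs(c(3, NA)), "non-finite")
  expect_error(round_bcs(Inf), "non-finite")
  set.seed(1)
  expect_true(all(round_bcs(rnorm(500, 5, 4)) %in% 1:9))
})

test_that("calibration split keeps exactly one BCS per cow", {
  d <- small_fit_data(seed = 6)
  sp <- split_calibration_validation(d$records, seed = 42)
  n_cal <- tapply(!is.na(sp$calibration$bcs), sp$calibration$animal_id, sum)
  expect_true(all(n_cal == 1L))
  # validation count = total BCS - number of cows
  total_bcs <- sum(!is.na(d$records$bcs))
  n_cows <- length(unique(d$records$animal_id))
  expect_identical(nrow(sp$validation), total_bcs - n_cows)
  # milk records are untouched
  expect_identical(sp$calibration$my, d$records$my)
  # same seed -> identical split; different seed -> different (generically)
  sp2 <- split_calibration_validation(d$records, seed = 42)
  expect_identical(sp, sp2)
  # a cow with fewer than two BCS is an error
  bad <- d$records
  first_cow <- bad$animal_id[1]
  drop <- which(bad$animal_id == first_cow & !is.na(bad$bcs))[-1]
  bad$bcs[drop] <- NA
  expect_error(split_calibration_validation(bad), "fewer than two")
})

test_that("residual imputation equals multivariate-normal conditioning", {
  # analytic case: BCS residual loads only on MY
  R <- diag(4)
  R[4, 1] <- R[1, 4] <- 0.5
  expect_equal(impute_residual(2, -1, 3, R), 0.5 * 2)
  expect_equal(impute_residual(0, 0, 0, R), 0)
  # random PD R: compare with conditioning through the precision matrix
  set.seed(8)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4)
    R <- crossprod(A) + diag(4)
    e <- rnorm(3)
    ours <- impute_residual(e[1], e[2], e[3], R)
    K <- solve(R) # precision route: E[e4|e_o] = -K[4,o]/K[4,4] e_o
    oracle <- -sum(K[4, 1:3] * e) / K[4, 4]
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
  expect_error(impute_residual(1, 1, 1, matrix(1, 4, 4)), "singular")
})

test_that("model-part prediction equals the dense conditional mean", {
  # mask one BCS observation; the package's model part + imputed residual
  # must equal the dense multivariate-normal conditional mean of that
  # observation given all others, computed from the full joint covariance
  d <- small_fit_data(seed = 9)
  rec <- d$records
  basis <- legendre_basis()
  Ainv <- build_A_inverse(d$sim$pedigree)
  comp <- d$sim$truth$components
  has_bcs <- which(!is.na(rec$bcs))
  mask <- has_bcs[5]
  obs_bcs <- rec$bcs[mask]
  rec_m <- rec
  rec_m$bcs[mask] <- NA
  coding <- build_coding(rec_m)
  sys <- assemble_mme(rec_m, coding, basis, comp, Ainv)
  sol <- solve_mme(sys)
  target <- rec[mask, ]
  target$obs_bcs <- obs_bcs
  pb <- predict_bcs(sol, target)

  # dense oracle: y* | y_obs under the full joint normal (fixed effects at
  # their GLS estimates), via the augmented-V regression identity
  oracle <- local({
    str0 <- build_mme_structure(rec, build_coding(rec), basis, Ainv)
    M <- as.matrix(str0$M)
    n_eq <- str0$n_eq
    A <- solve(as.matrix(Ainv))
    Gfull <- matrix(0, n_eq, n_eq)
    blk <- list(htd = kronecker(diag(str0$counts$htd), comp$D),
                hy = kronecker(diag(str0$counts$hy), comp$HY),
                pe = kronecker(diag(str0$counts$cow), comp$P),
                gen = kronecker(A, comp$G))
    for (e in names(blk)) {
      r <- as.vector(t(bcsrr:::.effect_rows(str0, e)))
      Gfull[r, r] <- blk[[e]]
    }
    Rbig <- matrix(0, nrow(M), nrow(M))
    for (rr in unique(str0$row_rec)) {
      sel <- which(str0$row_rec == rr)
      Rbig[sel, sel] <- comp$R[str0$row_trait[sel], str0$row_trait[sel]]
    }
    V <- M %*% Gfull %*% t(M) + Rbig
    star <- which(str0$row_rec == mask & str0$row_trait == 4L)
    obs <- setdiff(seq_len(nrow(M)), star)
    X <- M[, seq_len(str0$offsets$htd), drop = FALSE]
    Vi <- solve(V[obs, obs])
    b <- MASS::ginv(t(X[obs, ]) %*% Vi %*% X[obs, ]) %*%
      t(X[obs, ]) %*% Vi %*% str0$y[obs]
    drop(X[star, ] %*% b +
         V[star, obs] %*% Vi %*% (str0$y[obs] - X[obs, ] %*% b))
  })
  expect_equal(pb$y_hat_continuous, oracle, tolerance = 1e-6)
})

test_that("prediction inputs are validated", {
  d <- small_fit_data(seed = 9)
  sp <- split_calibration_validation(d$records, seed = 2)
  coding <- build_coding(sp$calibration)
  sys <- assemble_mme(sp$calibration, coding, legendre_basis(),
                      d$sim$truth$components,
                      build_A_inverse(d$sim$pedigree))
  sol <- solve_mme(sys)
  # unseen herd-test date errors, naming the level
  tgt <- sp$validation[1, ]
  tgt$test_date <- tgt$test_date + 1
  expect_error(predict_bcs(sol, tgt), "herd-test")
  # but the model part alone can be evaluated off test dates
  expect_silent(predict_model_part(sol, tgt, require_htd = FALSE))
  # all-zero solutions predict zero before rounding
  sol0 <- sol
  sol0$theta <- rep(0, length(sol$theta))
  expect_equal(predict_model_part(sol0, sp$validation[1:3, ]), rep(0, 3))
})
test_that("the imputation weights are MSE-optimal among linear predictors", {
  set.seed(14)
  R <- default_truth()$R
  L <- t(chol(R))
  E <- matrix(rnorm(5000 * 4), 5000) %*% t(L)
  b_opt <- solve(R[1:3, 1:3], R[1:3, 4])
  mse <- function(b) mean((E[, 4] - E[, 1:3] %*% b)^2)
  m0 <- mse(b_opt)
  expect_equal(m0, mean((E[, 4] - impute_residual(E[, 1], E[, 2], E[, 3],
                                                  R))^2))
  for (k in 1:25) {
    expect_gte(mse(b_opt + rnorm(3, 0, 0.15)), m0)
  }
})

test_that("prediction accuracy grows with the residual cross-correlation", {
  # fully-scored BCS, standard one-record-per-cow masking; as the residual
  # BCS-milk correlation rises from 0 to 0.5 the held-out correlation
  # improves on average, and is positive in every run
  base <- default_truth()
  with_bcs_corr <- function(c) {
    R <- base$R
    sgn <- c(-1, 1, 1)
    R[4, 1:3] <- R[1:3, 4] <- c * sgn * sqrt(R[4, 4] * diag(R)[1:3])
    cov_components(base$D, base$HY, base$P, base$G, R)
  }
  levels <- c(0, 0.25, 0.5)
  rbar <- numeric(length(levels))
  for (li in seq_along(levels)) {
    rs <- numeric(5)
    for (k in 1:5) {
      cfg <- sim_config(n_herds = 10, cows_per_herd = c(15, 20),
                        seed = 40 + k, bcs_prob = 1,
                        calving_window = c("2014-01-01", "2015-06-30"),
                        test_years = 2014:2016,
                        truth = with_bcs_corr(levels[li]))
      s <- simulate_records(cfg)
      rec <- apply_edits(s$records)$records
      sp <- split_calibration_validation(rec, seed = 70 + k)
      sys <- assemble_mme(sp$calibration, build_coding(sp$calibration),
                          legendre_basis(), s$truth$components,
                          build_A_inverse(s$pedigree))
      pb <- predict_bcs(solve_mme(sys), sp$validation)
      rs[k] <- cor(pb$obs_bcs, pb$y_hat_continuous)
    }
    expect_true(all(rs > 0))
    rbar[li] <- mean(rs)
  }
  expect_true(all(diff(rbar) > 0))
})
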