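test_that("assembled equations match a hand-built Henderson system", {
  # a single record: data block must be M' R_ooo^{-1} M and the rhs
  # M' R_oo^{-1} y for its observed pattern, on top of the prior blocks
  rec <- make_records(n = 1, bcs = NA_integer_) # milk-only record
  coding <- build_coding(rec)
  basis <- legendre_basis()
  Ainv <- build_A_inverse(sort_pedigree(ped_df("A1")))
  comp <- default_truth()
  sys <- assemble_mme(rec, coding, basis, comp, Ainv)
  str <- sys$structure
  M <- as.matrix(str$M)
  Rinv <- solve(comp$R[1:3, 1:3])
  expect_equal(as.matrix(sys$C - bcsrr:::.prior_matrix(str, comp)),
               t(M) %*% Rinv %*% M, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sys$rhs, as.numeric(t(M) %*% Rinv %*% str$y),
               tolerance = 1e-12)
})

test_that("sparse MME solutions equal dense GLS/BLUP on small instances", {
  for (seed in c(3, 8)) {
    d <- small_fit_data(seed = seed)
    basis <- legendre_basis()
    coding <- build_coding(d$records)
    Ainv <- build_A_inverse(d$sim$pedigree)
    comp <- d$sim$truth$components
    sys <- assemble_mme(d$records, coding, basis, comp, Ainv)
    # symmetry is exact
    expect_identical(Matrix::isSymmetric(sys$C), TRUE)
    sol <- solve_mme(sys)
    oracle <- dense_blup_oracle(sys)
    str <- sys$structure
    fit_mme <- as.numeric(str$M %*% sol$theta)
    expect_lt(max(abs(fit_mme - oracle$fitted)), 1e-7)
    rnd <- setdiff(seq_len(str$n_eq), oracle$fix_cols)
    expect_lt(max(abs(sol$theta[rnd] - oracle$theta[rnd])), 1e-7)
    # residuals agree with y - yhat from the oracle
    res <- compute_residuals(sol)
    expect_lt(max(abs(res$residual - (str$y - oracle$fitted))), 1e-7)
  }
})

test_that("records with missing BCS contribute no BCS data rows", {
  d <- small_fit_data(seed = 5)
  rec <- d$records
  rec$bcs <- NA_integer_ # all BCS missing
  basis <- legendre_basis()
  coding <- build_coding(rec)
  Ainv <- build_A_inverse(d$sim$pedigree)
  comp <- d$sim$truth$components
  sys <- assemble_mme(rec, coding, basis, comp, Ainv)
  str <- sys$structure
  expect_identical(sort(unique(str$row_trait)), 1:3)
  # BCS equations still exist (covariance links), rhs for pure-BCS fixed
  # equations is zero
  em <- equation_map(sys)
  bcs_mu <- em$row[em$effect == "mu" & em$trait == "BCS"]
  expect_equal(sys$rhs[bcs_mu], 0)
  # but solving still yields finite BCS genetic solutions through G
  sol <- solve_mme(sys)
  gen <- solution_block(sol, "gen")
  expect_true(all(is.finite(gen)))
  # doubling R halves every data block exactly
  comp2 <- cov_components(comp$D, comp$HY, comp$P, comp$G, 2 * comp$R)
  sys2 <- assemble_mme(rec, coding, basis, comp2, Ainv)
  data1 <- sys$C - bcsrr:::.prior_matrix(str, comp)
  data2 <- sys2$C - bcsrr:::.prior_matrix(sys2$structure, comp2)
  expect_lt(max(abs(data2 - data1 / 2)), 1e-12)
})

test_that("a record with no observed trait is rejected", {
  d <- small_fit_data(seed = 5)
  rec <- d$records
  rec$my[1] <- NA; rec$fp[1] <- NA; rec$pp[1] <- NA; rec$bcs[1] <- NA
  expect_error(build_mme_structure(rec, build_coding(rec), legendre_basis(),
                                   build_A_inverse(d$sim$pedigree)),
               "no observed trait")
})

test_that("random-effect solutions shrink to zero as their variances do", {
  d <- small_fit_data(seed = 13)
  basis <- legendre_basis()
  coding <- build_coding(d$records)
  Ainv <- build_A_inverse(d$sim$pedigree)
  comp <- d$sim$truth$components
  norms <- sapply(c(1, 1e-2, 1e-4), function(sc) {
    compsc <- cov_components(sc * comp$D, sc * comp$HY, sc * comp$P,
                             sc * comp$G, comp$R)
    sol <- solve_mme(assemble_mme(d$records, coding, basis, compsc, Ainv))
    sqrt(sum(solution_block(sol, "gen")^2) + sum(solution_block(sol, "pe")^2) +
         sum(solution_block(sol, "htd")^2) + sum(solution_block(sol, "hy")^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 0.05 * norms[1])
})

test_that("levels without data shrink exactly to zero for random effects", {
  d <- small_fit_data(seed = 3)
  basis <- legendre_basis()
  coding <- build_coding(d$records)
  # append an unrelated founder animal to the pedigree: no data, no links
  ids <- d$sim$pedigree$id
  df <- data.frame(animal_id = c(ids, "lone_founder"),
                   sire_id = c(ifelse(is.na(d$sim$pedigree$sire), NA,
                                      ids[d$sim$pedigree$sire]), NA),
                   dam_id = c(ifelse(is.na(d$sim$pedigree$dam), NA,
                                     ids[d$sim$pedigree$dam]), NA))
  Ainv <- build_A_inverse(sort_pedigree(df))
  comp <- d$sim$truth$components
  sol <- solve_mme(assemble_mme(d$records, coding, basis, comp, Ainv))
  gen <- solution_block(sol, "gen")
  expect_equal(unname(gen["lone_founder", ]), rep(0, 12))
})
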