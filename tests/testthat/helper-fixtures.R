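# Shared fixtures: small record sets, pedigrees and a dense mixed-model
# oracle, all built in code.

# a minimal valid record data frame; missing traits as NA
make_records <- function(n = 3, animal = paste0("A", seq_len(n)),
                         herd = "H1", dim = rep(100L, n),
                         my = rep(25, n), fp = rep(4, n), pp = rep(3.3, n),
                         bcs = rep(5L, n),
                         calving = as.Date("2015-03-01"),
                         birth = calving - 750) {
  data.frame(animal_id = animal, herd_id = herd,
             test_date = calving + dim, calving_date = calving,
             birth_date = birth, dim = as.integer(dim),
             my = my, fp = fp, pp = pp, bcs = bcs)
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write_records(records, path)
  path
}

# pedigree data frame helper
ped_df <- function(animal, sire = NA, dam = NA) {
  data.frame(animal_id = animal, sire_id = sire, dam_id = dam)
}

# dense GLS/BLUP oracle for an assembled system: builds V = W G W' + R_big
# by brute force and solves the generalized-least-squares problem; fixed
# effects via a pseudo-inverse so rank deficiency matches any constraint.
dense_blup_oracle <- function(sys) {
  str <- sys$structure
  comp <- sys$components
  M <- as.matrix(str$M)
  y <- str$y
  n_eq <- str$n_eq
  A <- solve(as.matrix(str$A_inverse))
  Gfull <- matrix(0, n_eq, n_eq)
  blk <- list(htd = kronecker(diag(str$counts$htd), comp$D),
              hy = kronecker(diag(str$counts$hy), comp$HY),
              pe = kronecker(diag(str$counts$cow), comp$P),
              gen = kronecker(A, comp$G))
  for (e in names(blk)) {
    r <- as.vector(t(bcsrr:::.effect_rows(str, e)))
    Gfull[r, r] <- blk[[e]]
  }
  Rbig <- matrix(0, length(y), length(y))
  for (rec in unique(str$row_rec)) {
    sel <- which(str$row_rec == rec)
    Rbig[sel, sel] <- comp$R[str$row_trait[sel], str$row_trait[sel]]
  }
  V <- M %*% Gfull %*% t(M) + Rbig
  fix_cols <- seq_len(str$offsets$htd)
  X <- M[, fix_cols, drop = FALSE]
  Vi <- solve(V)
  b <- MASS::ginv(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  u <- Gfull %*% t(M) %*% Vi %*% (y - X %*% b)
  theta <- as.numeric(u)
  theta[fix_cols] <- b
  list(theta = theta, fitted = as.numeric(M %*% theta),
       fix_cols = fix_cols)
}

# small synthetic dataset ready for model fitting
small_fit_data <- function(seed = 3, n_herds = 2, cows = c(11, 12), ...) {
  cfg <- sim_config(n_herds = n_herds, cows_per_herd = cows, seed = seed, ...)
  s <- simulate_records(cfg)
  rec <- apply_edits(s$records)$records
  list(sim = s, records = rec)
}

table3_path <- function() {
  system.file("extdata", "confusion_published.csv", package = "bcsrr")
}

# random tiny fitting instance (<= ~30 records) with jittered components;
# bypasses the herd-size edits so the dense oracle stays cheap
random_tiny_instance <- function(seed) {
  set.seed(seed)
  n_cows <- sample(3:6, 1)
  ped <- ped_df(paste0("S", 1:2))
  ped <- rbind(ped, data.frame(animal_id = paste0("C", seq_len(n_cows)),
                               sire_id = sample(paste0("S", 1:2), n_cows,
                                                TRUE),
                               dam_id = NA))
  sp <- sort_pedigree(ped)
  herd <- sample(c("H1", "H2"), n_cows, TRUE)
  calving <- as.Date("2015-01-01") + sample(0:400, n_cows, TRUE)
  recs <- do.call(rbind, lapply(seq_len(n_cows), function(i) {
    k <- sample(2:5, 1)
    dims <- sort(sample(5:365, k))
    data.frame(animal_id = paste0("C", i), herd_id = herd[i],
               test_date = calving[i] + dims, calving_date = calving[i],
               birth_date = calving[i] - sample(640:1100, 1),
               dim = dims,
               my = round(rnorm(k, 23, 4), 3),
               fp = round(rnorm(k, 4, 0.5), 3),
               pp = round(rnorm(k, 3.4, 0.3), 3),
               bcs = ifelse(runif(k) < 0.5, sample(3:7, k, TRUE),
                            NA_integer_))
  }))
  jitter_spd <- function(M) {
    n <- nrow(M)
    E <- matrix(rnorm(n * n, 0, 0.05), n)
    sc <- runif(1, 0.5, 1.5)
    sc * (M + mean(diag(M)) * crossprod(E) / n)
  }
  tr <- default_truth()
  comp <- cov_components(jitter_spd(tr$D), jitter_spd(tr$HY),
                         jitter_spd(tr$P), jitter_spd(tr$G),
                         jitter_spd(tr$R))
  list(records = recs, ped = sp, components = comp)
}
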