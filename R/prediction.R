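#' Round a continuous BCS prediction to the 9-point scale
#'
#' Nearest integer, ties (x.5) rounded away from zero, then clamped to
#' `[1, 9]`.
#'
#' @param y numeric vector of continuous BCS values.
#' @return integer vector in `{1..9}`.
#' @export
round_bcs <- function(y) {
  if (any(!is.finite(y))) stop("non-finite BCS value")
  r <- as.integer(sign(y) * floor(abs(y) + 0.5))
  pmin(9L, pmax(1L, r))
}

#' Split records into calibration and validation sets
#'
#' Keeps exactly one BCS record per cow (chosen uniformly at random under
#' `seed`) for calibration; every other observed BCS becomes a validation
#' target. All milk records stay in calibration unchanged, including at the
#' validation test dates, which is what makes cross-trait residual
#' imputation possible there.
#'
#' @param records filtered records in which every cow has at least two BCS.
#' @param seed integer seed for the per-cow selection.
#' @return list with `calibration` (records, BCS masked except the selected
#'   one) and `validation` (data frame of held-out BCS targets:
#'   `animal_id, herd_id, test_date, calving_date, birth_date, dim,
#'   obs_bcs`).
#' @export
split_calibration_validation <- function(records, seed = 1L) {
  has_bcs <- !is.na(records$bcs)
  n_bcs <- table(records$animal_id[has_bcs])
  all_cows <- unique(records$animal_id)
  short <- setdiff(all_cows, names(n_bcs)[n_bcs >= 2L])
  if (length(short)) {
    stop("cow(s) with fewer than two BCS records (filter first): ",
         paste(utils::head(short, 5), collapse = ", "))
  }
  set.seed(seed)
  idx_bcs <- which(has_bcs)
  # deterministic order: sort cows, then sample one index per cow
  cows <- sort(unique(records$animal_id))
  keep_idx <- vapply(cows, function(cw) {
    i <- idx_bcs[records$animal_id[idx_bcs] == cw]
    i[sample.int(length(i), 1L)]
  }, integer(1))
  mask <- setdiff(idx_bcs, keep_idx)
  calibration <- records
  calibration$bcs[mask] <- NA_integer_
  validation <- records[mask, c("animal_id", "herd_id", "test_date",
                                "calving_date", "birth_date", "dim")]
  validation$obs_bcs <- records$bcs[mask]
  rownames(validation) <- NULL
  list(calibration = calibration, validation = validation)
}

#' Model part of a BCS prediction
#'
#' \eqn{X^*\hat b + U^*\hat t + W_1^*\hat h + W_2^*\hat p + Z^*\hat a} for
#' the BCS trait at the target records' herd-test dates, with the Legendre
#' covariates applied to the herd-year, permanent-environment and genetic
#' regressions exactly as in fitting. Every target must resolve to levels
#' seen in calibration; an unseen herd-test date is an error unless
#' `require_htd = FALSE`, in which case the herd-test-day term (unavailable
#' off test dates) is dropped.
#'
#' @param solutions a [solve_mme()] result.
#' @param targets data frame with `animal_id, herd_id, test_date,
#'   calving_date, birth_date, dim`.
#' @param require_htd drop or require the random herd-test-day contribution.
#' @return numeric vector of continuous model-part predictions (BCS units).
#' @export
predict_model_part <- function(solutions, targets, require_htd = TRUE) {
  str <- solutions$structure
  cd <- str$coding
  lookup <- function(keys, table, what) {
    i <- match(keys, table)
    if (anyNA(i)) {
      stop("unresolvable ", what, " level(s): ",
           paste(utils::head(unique(keys[is.na(i)]), 5), collapse = ", "))
    }
    i
  }
  typ <- assign_test_year_period(targets$test_date, cd$ty_breaks)
  season <- assign_season(targets$test_date)
  cseason <- assign_season(targets$calving_date)
  mstage <- assign_major_stage(targets$dim)
  lstage <- assign_minor_stage(targets$dim)
  cyp <- assign_calving_year_period(targets$calving_date, cd$cy_breaks)
  age <- as.integer(as.Date(targets$calving_date) -
                    as.Date(targets$birth_date))
  age_class <- findInterval(age, cd$age_cutpoints) + 1L

  i_hty <- lookup(paste(targets$herd_id, typ, sep = "|"), cd$hty$levels, "HTY")
  i_htmp <- lookup(paste(targets$herd_id, season, sep = "|"),
                   cd$htmp$levels, "HTMp")
  i_as <- lookup(paste(age_class, cseason, mstage, sep = "|"),
                 cd$as$levels, "AS")
  i_ls <- lookup(sprintf("LS%02d", lstage), cd$ls$levels, "LS")
  i_hy <- lookup(paste(targets$herd_id, cyp, sep = "|"), cd$hy$levels, "HY")
  i_pe <- lookup(as.character(targets$animal_id), cd$cow$levels,
                 "permanent-environment (cow)")
  i_gen <- lookup(as.character(targets$animal_id), str$gen_ids, "animal")

  bt <- 4L # BCS trait slot
  mu <- solution_block(solutions, "mu")[1, bt]
  hty <- solution_block(solutions, "hty")[i_hty, bt]
  htmp <- solution_block(solutions, "htmp")[i_htmp, bt]
  as_ <- solution_block(solutions, "as")[i_as, bt]
  ls_ <- solution_block(solutions, "ls")[i_ls, bt]
  phi <- basis_eval(str$basis, targets$dim)
  bcs_cols <- (bt - 1L) * N_COEF + 1:3
  hy <- rowSums(phi * solution_block(solutions, "hy")[i_hy, bcs_cols,
                                                      drop = FALSE])
  pe <- rowSums(phi * solution_block(solutions, "pe")[i_pe, bcs_cols,
                                                      drop = FALSE])
  gen <- rowSums(phi * solution_block(solutions, "gen")[i_gen, bcs_cols,
                                                        drop = FALSE])
  out <- mu + hty + htmp + as_ + ls_ + hy + pe + gen
  if (require_htd) {
    i_htd <- lookup(paste(targets$herd_id, targets$test_date, sep = "|"),
                    cd$htd$levels, "herd-test-date")
    out <- out + solution_block(solutions, "htd")[i_htd, bt]
  }
  as.numeric(out)
}

#' Impute the BCS residual from milk-trait residuals
#'
#' Multiple-linear-regression imputation from the residual covariance
#' structure:
#' \deqn{\hat e_{BCS} = R_{BCS,(MY,FP,PP)}\,R_{(MY,FP,PP)}^{-1}
#'   (\hat e_{MY}, \hat e_{FP}, \hat e_{PP})',}
#' the conditional expectation of the BCS residual given the observed milk
#' residuals under the multivariate-normal residual model.
#'
#' @param e_my,e_fp,e_pp numeric vectors of milk-trait residuals.
#' @param R the 4 x 4 residual covariance (trait order MY, FP, PP, BCS).
#' @return numeric vector of imputed BCS residuals.
#' @export
impute_residual <- function(e_my, e_fp, e_pp, R) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == 4))
  Roo <- R[1:3, 1:3]
  if (abs(det(Roo)) < .Machine$double.eps * max(abs(Roo))^3) {
    stop("singular milk-trait residual covariance block")
  }
  b <- solve(Roo, R[1:3, 4])
  as.numeric(cbind(e_my, e_fp, e_pp) %*% b)
}

#' Predict BCS at held-out herd-test dates
#'
#' Combines the model part with the imputed residual from the cow's milk
#' residuals at the same herd-test date, then rounds to the 9-point scale.
#'
#' @param solutions a [solve_mme()] result fitted to the calibration data.
#' @param targets validation targets (see
#'   [split_calibration_validation()]); may carry `obs_bcs`.
#' @param use_residual include the imputed residual term (`FALSE`
#'   corresponds to predicting off test dates where milk residuals do not
#'   exist).
#' @return data frame of prediction records: `animal_id, test_date, dim,
#'   y_hat_model, e_hat_bcs, y_hat_continuous, y_hat_rounded, obs_bcs`.
#' @export
predict_bcs <- function(solutions, targets, use_residual = TRUE) {
  model_part <- predict_model_part(solutions, targets,
                                   require_htd = use_residual)
  e_hat <- rep(0, nrow(targets))
  if (use_residual) {
    res <- compute_residuals(solutions)
    str <- solutions$structure
    rec_key <- paste(str$records$animal_id, str$records$test_date)
    res$key <- rec_key[res$record]
    tkey <- paste(targets$animal_id, targets$test_date)
    getr <- function(trait) {
      sub <- res[res$trait == trait, ]
      v <- sub$residual[match(tkey, sub$key)]
      if (anyNA(v)) {
        stop("no calibration ", trait, " residual at target herd-test ",
             "date(s): ", paste(utils::head(tkey[is.na(v)], 5),
                                collapse = ", "))
      }
      v
    }
    e_hat <- impute_residual(getr("MY"), getr("FP"), getr("PP"),
                             solutions$components$R)
  }
  y_cont <- model_part + e_hat
  data.frame(animal_id = targets$animal_id, test_date = targets$test_date,
             dim = targets$dim, y_hat_model = model_part, e_hat_bcs = e_hat,
             y_hat_continuous = y_cont, y_hat_rounded = round_bcs(y_cont),
             obs_bcs = if ("obs_bcs" %in% names(targets)) {
               targets$obs_bcs
             } else NA_integer_)
}
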