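# Validation statistics for predicted vs observed BCS: prediction error,
# absolute prediction error, RMSE, Pearson correlation, the 9x9 confusion
# matrix, Cohen's kappa under three weightings, agreement bands and per-DIM
# summaries.

#' Prediction-error metrics for paired observations
#'
#' PE = predicted - observed, APE = |PE|, RMSE = sqrt(mean(PE^2)), Pearson r
#' with a Fisher-z 95\% confidence interval. SDs are sample SDs (n-1).
#'
#' @param obs observed values.
#' @param prd predicted values (continuous).
#' @return list with `n`, `pe_mean`, `pe_sd`, `ape_mean`, `ape_sd`, `rmse`,
#'   `r`, `r_ci` (NA when n < 2 or a vector is constant).
#' @export
pair_metrics <- function(obs, prd) {
  stopifnot(length(obs) == length(prd))
  ok <- is.finite(obs) & is.finite(prd)
  obs <- obs[ok]; prd <- prd[ok]
  n <- length(obs)
  pe <- prd - obs
  ape <- abs(pe)
  out <- list(n = n, pe_mean = mean(pe), pe_sd = sd(pe),
              ape_mean = mean(ape), ape_sd = sd(ape),
              rmse = sqrt(mean(pe^2)), r = NA_real_,
              r_ci = c(NA_real_, NA_real_))
  if (n >= 2 && sd(obs) > 0 && sd(prd) > 0) {
    r <- cor(obs, prd)
    out$r <- r
    if (n > 3) {
      z <- atanh(r)
      hw <- qnorm(0.975) / sqrt(n - 3)
      out$r_ci <- tanh(c(z - hw, z + hw))
    }
  }
  out
}

#' Build the 9 x 9 BCS confusion matrix
#'
#' Rows are observed classes, columns predicted classes, both on the 1-9
#' scale.
#'
#' @param obs observed integer classes.
#' @param prd predicted (rounded) integer classes.
#' @return object of class `confusion9`: integer matrix with dimnames 1..9.
#' @export
build_confusion <- function(obs, prd) {
  obs <- as.integer(obs); prd <- as.integer(prd)
  if (any(obs < 1L | obs > 9L | prd < 1L | prd > 9L, na.rm = TRUE) ||
      anyNA(obs) || anyNA(prd)) {
    stop("classes must be integers in 1..9")
  }
  cm <- table(factor(obs, levels = 1:9), factor(prd, levels = 1:9))
  cm <- matrix(as.integer(cm), 9, 9, dimnames = list(observed = 1:9,
                                                     predicted = 1:9))
  structure(cm, class = c("confusion9", class(cm)))
}

#' Read a 9 x 9 confusion matrix from CSV
#'
#' Plain count table: 9 rows x 9 columns with a header `c1..c9` or `1..9`;
#' rows are observed classes in order.
#'
#' @param path CSV path.
#' @return a `confusion9` matrix.
#' @export
read_confusion <- function(path) {
  m <- as.matrix(read.csv(path, header = TRUE))
  if (!all(dim(m) == c(9, 9))) stop("confusion matrix must be 9 x 9")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(observed = 1:9, predicted = 1:9)
  structure(m, class = c("confusion9", "matrix", "array"))
}

#' Agreement counts from a confusion matrix
#'
#' @param cm a `confusion9`.
#' @return list with `identical` (trace), `within_one` (cells at
#'   |observed - predicted| = 1), the corresponding fractions and the grand
#'   total.
#' @export
agreement_counts <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  d <- abs(row(cm) - col(cm))
  list(identical = sum(diag(cm)), within_one = sum(cm[d == 1]),
       identical_frac = sum(diag(cm)) / n, within_one_frac = sum(cm[d == 1]) / n,
       n = n)
}

#' Cohen's kappa with optional linear or quadratic weights
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with weighted observed and expected
#' agreement; weights are \eqn{1 - d/(k-1)} (linear) or
#' \eqn{1 - (d/(k-1))^2} (quadratic) with \eqn{d = |i - j|}, and identity
#' weights for the unweighted coefficient. The 95\% CI uses the
#' large-sample variance of the weighted kappa (Fleiss-Cohen-Everitt).
#'
#' @param cm a `confusion9` (or any square count matrix).
#' @param weighting one of `"none"`, `"linear"`, `"quadratic"`.
#' @return list with `kappa`, `se`, `ci` (95\%), `po`, `pe`, `weighting`.
#' @export
cohen_kappa <- function(cm, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  cm <- unclass(cm)
  k <- nrow(cm)
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  p <- cm / n
  d <- abs(row(p) - col(p))
  w <- switch(weighting,
              none = (d == 0) * 1,
              linear = 1 - d / (k - 1),
              quadratic = 1 - (d / (k - 1))^2)
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < .Machine$double.eps) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                po = po, pe = pe, weighting = weighting,
                degenerate = TRUE))
  }
  kap <- (po - pe) / (1 - pe)
  wr <- as.numeric(w %*% pc)   # row-weighted marginal means
  wc <- as.numeric(t(w) %*% pr)
  # large-sample variance (Fleiss, Cohen & Everitt):
  # var = [ sum_ij p_ij (w_ij(1-pe) - (wbar_i. + wbar_.j)(1-po))^2
  #         - (po*pe - 2*pe + po)^2 ] / (n (1-pe)^4)
  term <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      term[i, j] <- (w[i, j] * (1 - pe) - (wr[i] + wc[j]) * (1 - po))^2
    }
  }
  v <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  list(kappa = kap, se = se,
       ci = c(kap - qnorm(0.975) * se, kap + qnorm(0.975) * se),
       po = po, pe = pe, weighting = weighting, degenerate = FALSE)
}

#' Landis-Koch agreement label for a kappa value
#'
#' Bands: below 0 poor, 0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect. Boundaries
#' belong to the band whose printed range contains them.
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return character label.
#' @export
landis_koch <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  lab <- c("poor", "slight", "fair", "moderate", "substantial",
           "almost perfect")
  # printed bands are two-decimal: 0.21 starts "fair", 0.20 is still "slight"
  idx2 <- ifelse(kappa < 0, 1L,
                 ifelse(kappa <= 0.20, 2L,
                        ifelse(kappa <= 0.40, 3L,
                               ifelse(kappa <= 0.60, 4L,
                                      ifelse(kappa <= 0.80, 5L, 6L)))))
  lab[idx2]
}

#' Per-DIM summaries of prediction records
#'
#' Group means by integer DIM of observed BCS, predicted BCS, PE and APE;
#' DIMs without records are omitted.
#'
#' @param predictions a [predict_bcs()] data frame with `obs_bcs`.
#' @param use one of `"continuous"` or `"rounded"`: which prediction to
#'   summarize.
#' @return data frame: `dim, n, obs_mean, prd_mean, pe_mean, ape_mean`.
#' @export
per_dim_summary <- function(predictions, use = c("continuous", "rounded")) {
  use <- match.arg(use)
  prd <- if (use == "continuous") {
    predictions$y_hat_continuous
  } else predictions$y_hat_rounded
  pe <- prd - predictions$obs_bcs
  df <- data.frame(dim = predictions$dim, obs = predictions$obs_bcs,
                   prd = prd, pe = pe, ape = abs(pe))
  agg <- aggregate(cbind(obs, prd, pe, ape) ~ dim, data = df, FUN = mean)
  cnt <- aggregate(cbind(n = obs) ~ dim, data = df, FUN = length)
  out <- merge(cnt, agg, by = "dim")
  names(out) <- c("dim", "n", "obs_mean", "prd_mean", "pe_mean", "ape_mean")
  out[order(out$dim), ]
}

#' Full validation report
#'
#' Combines [pair_metrics()] (on the continuous predictions),
#' [build_confusion()] and [cohen_kappa()] (on the rounded ones),
#' [agreement_counts()], the Landis-Koch label of each kappa, and the
#' per-DIM summary.
#'
#' @param predictions a [predict_bcs()] data frame with `obs_bcs`.
#' @return object of class `validation_report`.
#' @export
validation_report <- function(predictions) {
  stopifnot(all(c("obs_bcs", "y_hat_continuous", "y_hat_rounded") %in%
                names(predictions)))
  pm <- pair_metrics(predictions$obs_bcs, predictions$y_hat_continuous)
  cm <- build_confusion(predictions$obs_bcs, predictions$y_hat_rounded)
  ag <- agreement_counts(cm)
  kap <- lapply(c("none", "linear", "quadratic"), function(wt) {
    k <- cohen_kappa(cm, wt)
    k$landis_koch <- if (is.na(k$kappa)) NA_character_ else landis_koch(k$kappa)
    k
  })
  names(kap) <- c("none", "linear", "quadratic")
  structure(list(metrics = pm, confusion = cm, agreement = ag, kappa = kap,
                 per_dim = per_dim_summary(predictions)),
            class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Validation over %d predicted-observed BCS pairs\n", m$n))
  cat(sprintf("  mean PE  %6.3f (SD %.3f)\n", m$pe_mean, m$pe_sd))
  cat(sprintf("  mean APE %6.3f (SD %.3f)\n", m$ape_mean, m$ape_sd))
  cat(sprintf("  RMSE     %6.3f\n", m$rmse))
  if (!is.na(m$r)) {
    cat(sprintf("  Pearson r %.3f (95%% CI %.3f-%.3f)\n", m$r,
                m$r_ci[1], m$r_ci[2]))
  }
  cat(sprintf("  identical %d (%.2f%%), within +/-1 %d (%.2f%%)\n",
              x$agreement$identical, 100 * x$agreement$identical_frac,
              x$agreement$within_one, 100 * x$agreement$within_one_frac))
  for (wt in names(x$kappa)) {
    k <- x$kappa[[wt]]
    cat(sprintf("  kappa (%s) %.3f (95%% CI %.3f-%.3f), %s\n", wt, k$kappa,
                k$ci[1], k$ci[2], k$landis_koch))
  }
  invisible(x)
}
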