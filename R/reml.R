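# EM-REML for the multi-trait random-regression test-day model.
#
# Each iteration solves the mixed-model equations at the current components,
# computes the inverse-subset (Takahashi) elements of the coefficient-matrix
# inverse, and applies the classical expectation-maximization updates:
#   D    <- (1/q) sum_lev ( t_hat t_hat' + C^{lev,lev} )
#   HY,P <- analogous 12x12 updates over their levels
#   G    <- (1/n) sum_ij Ainv_ij ( a_i a_j' + C^{a_i a_j} )
#   R    <- (1/N) sum_rec E[ e e' | y ]  with missing traits imputed from
#           the conditional normal given the observed residuals.
# EM keeps every component positive semi-definite by construction and never
# decreases the restricted log-likelihood.

# permuted 0-based equation positions for a matrix of original indices
.perm_rows <- function(rows, pos0) {
  matrix(pos0[rows], nrow = nrow(rows))
}

# equation rows (original, 1-based) per level of a random effect
.effect_rows <- function(str, effect) {
  off <- str$offsets[[effect]]
  nlev <- switch(effect, htd = str$counts$htd, hy = str$counts$hy,
                 pe = str$counts$cow, gen = str$counts$gen)
  wid <- if (effect == "htd") N_TRAITS else 12L
  matrix(off + seq_len(nlev * wid), nrow = nlev, byrow = TRUE)
}

# log|R_oo| summed over records, by observation pattern
.logdet_R_obs <- function(str, R) {
  s <- 0
  for (p in unique(str$pat_id)) {
    traits <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
    s <- s + sum(str$pat_id == p) *
      determinant(R[traits, traits, drop = FALSE], logarithm = TRUE)$modulus
  }
  as.numeric(s)
}

#' Restricted log-likelihood of a component set
#'
#' Evaluated through the mixed-model equations:
#' \deqn{-2\,\ell_R = \sum_r \log|R_{o_r}| + q_t\log|D| + q_h\log|HY| +
#'   q_p\log|P| + 12\log|A| + n_a\log|G| + \log|C| + y'Py + const,}
#' with \eqn{\log|C|} the sum of log pivots of the sparse factorization
#' (redundant equations excluded) and \eqn{y'Py = y'R^{-1}_\ast y -
#' \hat\theta' \mathrm{rhs}}. The additive constant is omitted.
#'
#' @keywords internal
.restricted_loglik <- function(sys, theta, fac, logdetA) {
  str <- sys$structure
  comp <- sys$components
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  yPy <- sys$yBy - sum(theta * sys$rhs)
  logC <- sum(log(fac$D[fac$D > 0]))
  m2 <- .logdet_R_obs(str, comp$R) +
    str$counts$htd * ld(comp$D) + str$counts$hy * ld(comp$HY) +
    str$counts$cow * ld(comp$P) + str$counts$gen * ld(comp$G) +
    12 * logdetA + logC + yPy
  -0.5 * m2
}

# one EM step; returns updated components plus diagnostics. `fix` names
# components held at their current value (config switch, e.g. fix = "D").
.em_step <- function(str, comp, perm, Ainv_trip, logdetA, fix = character(0),
                     ldl_tol = 1e-9) {
  sys <- assemble_mme(structure = str, components = comp,
                      records = NULL, coding = NULL, basis = NULL,
                      A_inverse = NULL)
  fac <- .factor_system(sys$C, perm = perm, tol = ldl_tol)
  theta <- as.numeric(.factor_solve(fac, sys$rhs))
  llik <- .restricted_loglik(sys, theta, fac, logdetA)
  tk <- .takahashi_cpp(fac$Lp, fac$Li, fac$Lx, fac$D)
  pos0 <- integer(fac$n)
  pos0[fac$perm] <- seq_len(fac$n) - 1L

  blocks <- list()
  for (e in c("htd", "hy", "pe")) {
    rows <- .effect_rows(str, e)
    rp <- .perm_rows(rows, pos0)
    tr <- .z_block_sum_cpp(fac$Lp, fac$Li, tk$Zx, tk$Zdiag, rp, rp,
                           rep(1, nrow(rp)))
    U <- matrix(theta[t(rows)], ncol = ncol(rows), byrow = TRUE)
    blocks[[e]] <- (crossprod(U) + tr) / nrow(rows)
  }
  # genetic: weighted over the A-inverse pattern
  rows_g <- .effect_rows(str, "gen")
  rpg <- .perm_rows(rows_g, pos0)
  tr_g <- .z_block_sum_cpp(fac$Lp, fac$Li, tk$Zx, tk$Zdiag,
                           rpg[Ainv_trip$i, , drop = FALSE],
                           rpg[Ainv_trip$j, , drop = FALSE], Ainv_trip$x)
  Ahat <- matrix(theta[t(rows_g)], ncol = 12L, byrow = TRUE)
  G_new <- (crossprod(Ahat, as.matrix(str$A_inverse %*% Ahat)) + tr_g) /
    str$counts$gen
  G_new <- (G_new + t(G_new)) / 2

  # residual: per-record E[e e' | y] with conditional imputation of
  # unobserved traits
  Mt <- methods::as(Matrix::t(str$M), "CsparseMatrix")
  qf <- .record_quad_forms_cpp(fac$Lp, fac$Li, tk$Zx, tk$Zdiag,
                               Mt@p, pos0[Mt@i + 1L], Mt@x,
                               str$row_rec - 1L, str$row_trait - 1L,
                               str$n_rec, N_TRAITS)
  ehat <- str$y - as.numeric(str$M %*% theta)
  Rsum <- matrix(0, N_TRAITS, N_TRAITS)
  for (p in unique(str$pat_id)) {
    o <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
    m <- setdiff(seq_len(N_TRAITS), o)
    recs <- which(str$pat_id == p)
    sel <- str$row_rec %in% recs
    E <- matrix(ehat[sel], ncol = length(o), byrow = TRUE) # recs x |o|
    Eoo <- crossprod(E) +
      apply(qf[o, o, recs, drop = FALSE], c(1, 2), sum)
    Efull <- matrix(0, N_TRAITS, N_TRAITS)
    Efull[o, o] <- Eoo
    if (length(m)) {
      S <- comp$R[m, o, drop = FALSE] %*%
        solve(comp$R[o, o, drop = FALSE])
      Emo <- S %*% Eoo
      Emm <- length(recs) *
        (comp$R[m, m, drop = FALSE] - S %*% comp$R[o, m, drop = FALSE]) +
        S %*% Eoo %*% t(S)
      Efull[m, o] <- Emo
      Efull[o, m] <- t(Emo)
      Efull[m, m] <- Emm
    }
    Rsum <- Rsum + Efull
  }
  R_new <- (Rsum + t(Rsum)) / (2 * str$n_rec)

  upd <- list(D = blocks$htd, HY = blocks$hy, P = blocks$pe, G = G_new,
              R = R_new)
  for (nm in fix) upd[[nm]] <- comp[[nm]]
  list(components = cov_components(D = upd$D, HY = upd$HY, P = upd$P,
                                   G = upd$G, R = upd$R),
       llik = llik, theta = theta, n_constrained = fac$n_zero_pivots)
}

#' Default starting values for EM-REML
#'
#' Splits the observed phenotypic (co)variance into 10\% genetic, 10\%
#' permanent environment, 5\% herd-year, 5\% herd-test-day and 70\%
#' residual. Regression-coefficient matrices put most weight on the
#' intercept coefficient so that the implied mean daily variance equals the
#' intended share; cross-trait starting covariances use the damped (halved)
#' phenotypic correlations, the usual multi-trait starting point, which also
#' spares the slowly-converging correlation components many early EM steps.
#'
#' @param records test-day records.
#' @return a [cov_components()].
#' @export
init_components <- function(records) {
  Y <- cbind(records$my, records$fp, records$pp, records$bcs)
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1 # traits never observed: unit placeholder
  Cm <- suppressWarnings(cor(Y, use = "pairwise.complete.obs"))
  Cm[!is.finite(Cm)] <- 0
  diag(Cm) <- 1
  Cd <- 0.5 * Cm + 0.5 * diag(4) # damped, safely positive definite
  ev <- eigen(Cd, symmetric = TRUE)
  if (min(ev$values) < 1e-6) { # clip in the rare ill-conditioned case
    Cd <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
  }
  w <- c(0.85, 0.10, 0.05)
  coefmat <- function(share) {
    M <- matrix(0, 12, 12)
    for (k in 1:3) {
      sdv <- sqrt(2 * share * v * w[k])
      idx <- (0:3) * 3 + k
      M[idx, idx] <- Cd * tcrossprod(sdv)
    }
    M
  }
  Dh <- diag(sqrt(0.70 * v))
  R0 <- Dh %*% Cd %*% Dh
  cov_components(D = diag(0.05 * v), HY = coefmat(0.05), P = coefmat(0.10),
                 G = coefmat(0.10), R = R0)
}

#' Estimate covariance components by EM-REML
#'
#' Iterates expectation-maximization updates of all five component matrices
#' until the largest relative Frobenius change falls below `tol` or the
#' iteration cap is hit. The restricted log-likelihood is tracked per
#' iteration and is non-decreasing.
#'
#' @param records filtered (calibration) test-day records.
#' @param coding effect coding covering the records.
#' @param basis a [legendre_basis()].
#' @param A_inverse sparse A-inverse with animal-id dimnames.
#' @param init starting [cov_components()]; `NULL` uses
#'   [init_components()].
#' @param settings list with `max_iter` (default 100), `tol` (relative
#'   parameter change, default 1e-6), `fix` (character vector of component
#'   names in `c("D","HY","P","G","R")` to hold at their starting value),
#'   `verbose`, and `error_on_cap`
#'   (default `FALSE`: return the current estimate with a warning when the
#'   cap is reached; `TRUE` raises instead).
#' @return list with `components` (the estimate), `trace` (a `reml_trace`
#'   data frame: iteration, restricted log-likelihood, update norm, step
#'   type) and `converged`.
#' @export
estimate_components <- function(records, coding, basis, A_inverse,
                                init = NULL, settings = list()) {
  set <- utils::modifyList(list(max_iter = 100L, tol = 1e-6,
                                fix = character(0), verbose = FALSE,
                                error_on_cap = FALSE),
                           settings)
  str <- build_mme_structure(records, coding, basis, A_inverse)
  comp <- init %||% init_components(records)
  stopifnot(inherits(comp, "cov_components"))
  logdetA <- -as.numeric(Matrix::determinant(str$A_inverse,
                                             logarithm = TRUE)$modulus)
  Ag <- methods::as(methods::as(str$A_inverse, "generalMatrix"),
                    "TsparseMatrix")
  Ainv_trip <- list(i = Ag@i + 1L, j = Ag@j + 1L, x = Ag@x)
  # the fill-reducing ordering must reflect the pattern EM will produce:
  # after one update every coefficient block is dense, so analyse a
  # densified copy of the starting components (values are irrelevant)
  densify <- function(M) {
    s <- mean(diag(M))
    M + 0.05 * s * matrix(1, nrow(M), ncol(M)) + 0.2 * s * diag(nrow(M))
  }
  comp_dense <- cov_components(densify(comp$D), densify(comp$HY),
                               densify(comp$P), densify(comp$G),
                               densify(comp$R))
  sys0 <- assemble_mme(structure = str, components = comp_dense,
                       records = NULL, coding = NULL, basis = NULL,
                       A_inverse = NULL)
  perm <- .factor_system(sys0$C)$perm

  trace <- data.frame(iteration = integer(0), loglik = numeric(0),
                      delta = numeric(0), step = character(0))
  converged <- FALSE
  for (it in seq_len(set$max_iter)) {
    stp <- .em_step(str, comp, perm, Ainv_trip, logdetA,
                    fix = set$fix)
    new <- stp$components
    rel <- function(a, b) {
      norm(as.matrix(a - b), "F") / max(norm(as.matrix(b), "F"),
                                        .Machine$double.eps)
    }
    delta <- max(rel(new$D, comp$D), rel(new$HY, comp$HY),
                 rel(new$P, comp$P), rel(new$G, comp$G), rel(new$R, comp$R))
    trace <- rbind(trace, data.frame(iteration = it, loglik = stp$llik,
                                     delta = delta, step = "EM"))
    if (set$verbose) {
      message(sprintf("EM iter %3d  logL_R = %.6f  delta = %.3e",
                      it, stp$llik, delta))
    }
    comp <- new
    if (delta < set$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- sprintf(
      "EM-REML reached the iteration cap (%d) at relative change %.2e",
      set$max_iter, trace$delta[nrow(trace)])
    if (isTRUE(set$error_on_cap)) stop(msg) else warning(msg)
  }
  class(trace) <- c("reml_trace", class(trace))
  list(components = comp, trace = trace, converged = converged)
}

#' Daily genetic parameters implied by a component set
#'
#' Evaluates, on a DIM grid, the daily variances
#' \eqn{v_g(d) = q(d)' G_t q(d)} (and analogously for permanent environment
#' and herd-year), the daily heritability
#' \eqn{h^2(d) = v_g / (v_g + v_p + v_{hy} + v_{htd} + v_r)}, and daily
#' genetic and permanent-environment correlations between traits.
#'
#' @param components a [cov_components()].
#' @param basis a [legendre_basis()].
#' @param dim_grid integer DIM grid (default every day 5..365).
#' @return list with per-DIM curves (`h2`, `rg`, `rp`) and their means and
#'   SDs over the grid (`h2_mean`, `h2_sd`, `rg_mean`, `rg_sd`, `rp_mean`,
#'   `rp_sd`).
#' @export
daily_parameters <- function(components, basis = legendre_basis(),
                             dim_grid = 5:365) {
  if (!inherits(components, "cov_components")) {
    components <- do.call(cov_components, components[c("D", "HY", "P",
                                                       "G", "R")])
  }
  comp <- components
  Q <- basis_eval(basis, dim_grid) # n x 3
  nd <- length(dim_grid)
  vg <- vp <- vhy <- matrix(0, nd, N_TRAITS)
  cg <- cp <- array(0, c(N_TRAITS, N_TRAITS, nd))
  for (s in 1:4) {
    for (t in 1:4) {
      is <- (s - 1) * 3 + 1:3
      it <- (t - 1) * 3 + 1:3
      cg[s, t, ] <- rowSums((Q %*% comp$G[is, it]) * Q)
      cp[s, t, ] <- rowSums((Q %*% comp$P[is, it]) * Q)
    }
    vg[, s] <- cg[s, s, ]
    vp[, s] <- cp[s, s, ]
    vhy[, s] <- rowSums((Q %*% comp$HY[(s - 1) * 3 + 1:3,
                                       (s - 1) * 3 + 1:3]) * Q)
  }
  vtot <- vg + vp + vhy +
    matrix(diag(comp$D), nd, 4, byrow = TRUE) +
    matrix(diag(comp$R), nd, 4, byrow = TRUE)
  h2 <- vg / vtot
  corr_of <- function(cc) {
    out <- array(NA_real_, c(4, 4, nd))
    for (s in 1:4) for (t in 1:4) {
      den <- sqrt(cc[s, s, ] * cc[t, t, ])
      out[s, t, ] <- ifelse(den > 0, cc[s, t, ] / den, NA_real_)
    }
    out
  }
  rg <- corr_of(cg)
  rp <- corr_of(cp)
  dimnames(rg) <- dimnames(rp) <- list(TRAITS, TRAITS, NULL)
  colnames(h2) <- TRAITS
  list(dim = dim_grid, h2 = h2, rg = rg, rp = rp,
       h2_mean = colMeans(h2), h2_sd = apply(h2, 2, sd),
       rg_mean = apply(rg, c(1, 2), mean), rg_sd = apply(rg, c(1, 2), sd),
       rp_mean = apply(rp, c(1, 2), mean), rp_sd = apply(rp, c(1, 2), sd))
}
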