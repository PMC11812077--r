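#' Covariance components of the multi-trait random-regression model
#'
#' Bundles the five covariance matrices of the model
#' \deqn{y = Xb + Ut + QW_1h + W_2p + Za + e:}
#' `D` (4 x 4, herd-test-day effects, trait intercepts), `HY` (12 x 12,
#' herd-calving-year-period random-regression coefficients), `P` (12 x 12,
#' permanent environment), `G` (12 x 12, additive genetic, expanded over the
#' pedigree as `G` Kronecker `A`) and `R` (4 x 4 residual). The 12-dimensional
#' matrices use trait-major ordering: (MY.phi0, MY.phi1, MY.phi2, FP.phi0,
#' ..., BCS.phi2).
#'
#' @param D,HY,P,G,R the component matrices.
#' @return object of class `cov_components`.
#' @export
cov_components <- function(D, HY, P, G, R) {
  chk <- function(M, d, name, pd = FALSE) {
    M <- as.matrix(M)
    if (!all(dim(M) == d)) stop(name, " must be ", d, " x ", d)
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      stop(name, " must be symmetric")
    }
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (pd && min(ev) <= 0) stop(name, " must be positive definite")
    if (!pd && min(ev) < -1e-8 * max(abs(ev))) {
      stop(name, " must be positive semi-definite")
    }
    M
  }
  out <- list(D = chk(D, 4, "D"), HY = chk(HY, 12, "HY"),
              P = chk(P, 12, "P"), G = chk(G, 12, "G"),
              R = chk(R, 4, "R", pd = TRUE))
  structure(out, class = "cov_components")
}

#' @exportS3Method base::print
print.cov_components <- function(x, ...) {
  cat("cov_components: D 4x4, HY 12x12, P 12x12, G 12x12, R 4x4",
      "(traits MY, FP, PP, BCS; coefficients phi0..phi2, trait-major)\n")
  invisible(x)
}

# Row index of the trait-major 12-dim coefficient vector
.tm_index <- function(trait, coef) (trait - 1L) * N_COEF + coef + 1L

#' Build the record-side structure of the mixed-model equations
#'
#' Constructs, once per dataset, everything that does not depend on the
#' covariance components: the equation index map, the sparse design matrix
#' with one row per record x observed trait, and the per-record observation
#' patterns. The components only enter through the data weights and the
#' random-effect priors, so REML can re-weight this structure cheaply.
#'
#' @param records filtered test-day records.
#' @param coding an [build_coding()] result covering the records.
#' @param basis a [legendre_basis()].
#' @param A_inverse sparse inverse numerator relationship matrix with animal
#'   ids as dimnames; every record's animal must appear.
#' @return an object of class `mme_structure`.
#' @export
build_mme_structure <- function(records, coding, basis, A_inverse) {
  stopifnot(inherits(coding, "effect_coding"),
            inherits(basis, "legendre_basis"))
  n_rec <- nrow(records)
  if (coding$n_records != n_rec) stop("coding does not cover the records")
  gen_ids <- rownames(A_inverse)
  if (is.null(gen_ids)) stop("A_inverse must carry animal ids as dimnames")
  anim <- match(as.character(records$animal_id), gen_ids)
  if (anyNA(anim)) {
    stop("record animal(s) missing from A_inverse: ",
         paste(unique(records$animal_id[is.na(anim)]), collapse = ", "))
  }

  nl <- list(hty = length(coding$hty$levels), htmp = length(coding$htmp$levels),
             as = length(coding$as$levels), ls = length(coding$ls$levels),
             htd = length(coding$htd$levels), hy = length(coding$hy$levels),
             cow = length(coding$cow$levels), gen = length(gen_ids))
  off <- list()
  cur <- 0L
  for (e in c("mu", "hty", "htmp", "as", "ls", "htd")) {
    off[[e]] <- cur
    cur <- cur + N_TRAITS * switch(e, mu = 1L, nl[[e]])
  }
  for (e in c("hy", "pe", "gen")) {
    off[[e]] <- cur
    cur <- cur + 12L * switch(e, hy = nl$hy, pe = nl$cow, gen = nl$gen)
  }
  n_eq <- cur

  # observation rows: record-major, observed traits in MY,FP,PP,BCS order
  ymat <- cbind(records$my, records$fp, records$pp, records$bcs)
  obs <- !is.na(ymat)
  if (any(rowSums(obs) == 0)) {
    stop("record(s) with no observed trait: ",
         paste(which(rowSums(obs) == 0), collapse = ", "))
  }
  row_rec <- rep(seq_len(n_rec), times = rowSums(obs))
  row_trait <- unlist(lapply(seq_len(n_rec), function(r) which(obs[r, ])),
                      use.names = FALSE)
  n_rows <- length(row_rec)
  y <- ymat[cbind(row_rec, row_trait)]

  phi <- basis_eval(basis, records$dim) # n_rec x 3
  t_ <- row_trait
  r_ <- row_rec
  # intercept-type entries (one equation each)
  eq_fix <- cbind(
    off$mu + t_,
    off$hty + (coding$hty$index[r_] - 1L) * N_TRAITS + t_,
    off$htmp + (coding$htmp$index[r_] - 1L) * N_TRAITS + t_,
    off$as + (coding$as$index[r_] - 1L) * N_TRAITS + t_,
    off$ls + (coding$ls$index[r_] - 1L) * N_TRAITS + t_,
    off$htd + (coding$htd$index[r_] - 1L) * N_TRAITS + t_
  )
  # regression entries (three equations each)
  reg_eq <- function(offset, level) {
    base <- offset + (level[r_] - 1L) * 12L + (t_ - 1L) * N_COEF
    cbind(base + 1L, base + 2L, base + 3L)
  }
  eq_hy <- reg_eq(off$hy, coding$hy$index)
  eq_pe <- reg_eq(off$pe, coding$cow$index)
  eq_gen <- reg_eq(off$gen, anim)
  phir <- phi[r_, , drop = FALSE]

  j_all <- cbind(eq_fix, eq_hy, eq_pe, eq_gen)
  x_all <- cbind(matrix(1, n_rows, 6), phir, phir, phir)
  i_all <- matrix(seq_len(n_rows), n_rows, ncol(j_all))
  M <- Matrix::sparseMatrix(i = as.vector(i_all), j = as.vector(j_all),
                            x = as.vector(x_all), dims = c(n_rows, n_eq))

  # per-record observation pattern id (bitmask over traits)
  pat_id <- as.integer(obs %*% c(1L, 2L, 4L, 8L))

  structure(list(
    M = M, y = y, row_rec = row_rec, row_trait = row_trait,
    pat_id = pat_id, obs = obs, n_rec = n_rec, n_eq = n_eq,
    offsets = off, counts = nl, gen_ids = gen_ids, anim = anim,
    coding = coding, basis = basis, A_inverse = A_inverse,
    records = records
  ), class = "mme_structure")
}

# residual weight matrix B (n_rows x n_rows, block per record) and y'By pieces
.residual_weights <- function(str, R) {
  pats <- sort(unique(str$pat_id))
  ii <- list(); jj <- list(); xx <- list(); k <- 1L
  # rows are record-major and contiguous; compute first row per record
  first_row <- c(1L, 1L + cumsum(rowSums(str$obs)))[seq_len(str$n_rec)]
  for (p in pats) {
    traits <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
    m <- length(traits)
    Rinv <- tryCatch(solve(R[traits, traits, drop = FALSE]),
                     error = function(e) stop(
                       "singular residual sub-matrix for pattern {",
                       paste(TRAITS[traits], collapse = ","), "}"))
    recs <- which(str$pat_id == p)
    fr <- first_row[recs]
    a <- rep(rep(seq_len(m), each = m), times = length(recs))
    b <- rep(rep(seq_len(m), times = m), times = length(recs))
    base <- rep(fr - 1L, each = m * m)
    ii[[k]] <- base + a
    jj[[k]] <- base + b
    xx[[k]] <- rep(as.vector(Rinv), times = length(recs))
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(length(str$y), length(str$y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# prior (random-effect) precision block of the coefficient matrix; the
# inversion carries a 1e-12-relative ridge so that components driven onto
# the PSD boundary (e.g. by EM) stay invertible without affecting any
# quantity at working precision
.prior_inv <- function(M) {
  solve(M + 1e-12 * mean(diag(M)) * diag(nrow(M)))
}

.prior_matrix <- function(str, comp) {
  n_fix <- str$offsets$htd # all equations before HTD are fixed
  blocks <- list(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n_fix, n_fix)),
    Matrix::kronecker(Matrix::Diagonal(str$counts$htd), .prior_inv(comp$D)),
    Matrix::kronecker(Matrix::Diagonal(str$counts$hy), .prior_inv(comp$HY)),
    Matrix::kronecker(Matrix::Diagonal(str$counts$cow), .prior_inv(comp$P)),
    Matrix::kronecker(str$A_inverse, .prior_inv(comp$G))
  )
  Matrix::bdiag(blocks)
}

#' Assemble the mixed-model equations
#'
#' Henderson-form normal equations for the multi-trait random-regression
#' test-day model. Each record contributes through the inverse of the
#' residual sub-matrix for its observed-trait pattern (3 x 3 for records
#' without BCS, 4 x 4 with BCS), so BCS missingness is handled exactly.
#' Random-effect priors add \eqn{D^{-1} \otimes I} (herd-test-day),
#' \eqn{HY^{-1} \otimes I}, \eqn{P^{-1} \otimes I} and
#' \eqn{G^{-1} \otimes A^{-1}} (stored animal-major as
#' \eqn{A^{-1} \otimes G^{-1}}).
#'
#' @param records filtered test-day records.
#' @param coding effect coding from [build_coding()].
#' @param basis a [legendre_basis()].
#' @param components a [cov_components()].
#' @param A_inverse sparse A-inverse with animal-id dimnames.
#' @param structure optionally, a prebuilt [build_mme_structure()] result
#'   (the other data arguments are then ignored).
#' @return object of class `mme_system` with the sparse symmetric coefficient
#'   matrix `C`, right-hand side `rhs`, and the equation map.
#' @export
assemble_mme <- function(records, coding, basis, components, A_inverse,
                         structure = NULL) {
  str <- structure %||% build_mme_structure(records, coding, basis, A_inverse)
  stopifnot(inherits(components, "cov_components"))
  B <- .residual_weights(str, components$R)
  C <- Matrix::forceSymmetric(
    Matrix::crossprod(str$M, B %*% str$M) + .prior_matrix(str, components))
  rhs <- as.numeric(Matrix::crossprod(str$M, B %*% str$y))
  out <- list(C = C, rhs = rhs, structure = str, components = components,
              yBy = as.numeric(str$y %*% (B %*% str$y)))
  class(out) <- "mme_system"
  out
}

#' Equation map of an assembled system
#'
#' @param system an `mme_system` or `mme_structure`.
#' @return data frame with one row per equation: effect, level key, trait,
#'   Legendre coefficient and equation row.
#' @export
equation_map <- function(system) {
  str <- if (inherits(system, "mme_system")) system$structure else system
  off <- str$offsets
  cd <- str$coding
  lev <- list(mu = "mu", hty = cd$hty$levels, htmp = cd$htmp$levels,
              as = cd$as$levels, ls = cd$ls$levels, htd = cd$htd$levels,
              hy = cd$hy$levels, pe = cd$cow$levels, gen = str$gen_ids)
  pieces <- lapply(names(lev), function(e) {
    L <- lev[[e]]
    if (e %in% c("hy", "pe", "gen")) {
      data.frame(effect = e,
                 level = rep(L, each = 12L),
                 trait = rep(rep(TRAITS, each = N_COEF), times = length(L)),
                 coef = rep(0:2, times = 4L * length(L)))
    } else {
      data.frame(effect = e,
                 level = rep(L, each = N_TRAITS),
                 trait = rep(TRAITS, times = length(L)),
                 coef = 0L)
    }
  })
  out <- do.call(rbind, pieces)
  out$row <- seq_len(nrow(out))
  out
}

# fill-reducing permutation + sparse LDL' factorization of C (generalized
# inverse treatment of redundant equations via zero pivots)
.factor_system <- function(C, perm = NULL, tol = 1e-9) {
  n <- nrow(C)
  if (is.null(perm)) {
    shift <- mean(Matrix::diag(C))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), perm = TRUE,
                           LDL = TRUE, super = FALSE, Imult = shift)
    perm <- ch@perm + 1L
  }
  Cg <- methods::as(C, "generalMatrix")
  Cp <- Cg[perm, perm, drop = FALSE]
  Cu <- Matrix::triu(Cp)
  Cu <- methods::as(methods::as(Cu, "CsparseMatrix"), "generalMatrix")
  fac <- .ldl_factor_cpp(n, Cu@p, Cu@i, Cu@x, tol)
  fac$perm <- perm
  fac$n <- n
  fac
}

.factor_solve <- function(fac, b) {
  b <- as.matrix(b)
  xp <- .ldl_solve_cpp(fac$Lp, fac$Li, fac$Lx, fac$D, b[fac$perm, ,
                                                        drop = FALSE])
  x <- xp
  x[fac$perm, ] <- xp
  x
}

# redundant fixed-effect equations, found once per structure: zero pivots of
# the fixed-block Gram matrix X'X (rank deficiency lives entirely in the
# fixed part; every random effect carries a positive-definite prior)
.redundant_fixed <- function(str) {
  if (is.null(str$redundant_cache)) {
    fix_cols <- seq_len(str$offsets$htd)
    X <- str$M[, fix_cols, drop = FALSE]
    G <- Matrix::forceSymmetric(Matrix::crossprod(X))
    fac <- .factor_system(G, tol = 1e-9)
    which(fac$D[order(fac$perm)] == 0)
  } else {
    str$redundant_cache
  }
}

#' Solve assembled mixed-model equations
#'
#' Direct sparse factorization. Fixed-effect rank deficiency is resolved by
#' a deterministic constraint: redundant fixed-effect equations (zero pivots
#' of the fixed-block Gram matrix under a fill-reducing ordering) are
#' constrained to zero, and the remaining positive-definite system is
#' factored by sparse supernodal Cholesky. The relative residual norm of the
#' returned solution is checked against `tol`.
#'
#' @param system an `mme_system` from [assemble_mme()].
#' @param tol relative residual tolerance (default 1e-8).
#' @return object of class `model_solutions`: full solution vector `theta`,
#'   per-effect accessors via [solution_block()], and the equation map.
#' @export
solve_mme <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "mme_system"))
  drop_eq <- .redundant_fixed(system$structure)
  n <- nrow(system$C)
  keep <- setdiff(seq_len(n), drop_eq)
  Ck <- system$C[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ck), perm = TRUE,
                         LDL = FALSE, super = TRUE)
  theta <- numeric(n)
  theta[keep] <- as.numeric(Matrix::solve(ch, system$rhs[keep],
                                          system = "A"))
  resid <- as.numeric(system$C %*% theta - system$rhs)
  relres <- sqrt(sum(resid^2)) / max(sqrt(sum(system$rhs^2)),
                                     .Machine$double.eps)
  if (relres > tol) {
    stop(sprintf("MME solve did not reach tolerance: relative residual %.3e",
                 relres))
  }
  out <- list(theta = theta, relres = relres,
              n_constrained = length(drop_eq),
              structure = system$structure, components = system$components)
  class(out) <- "model_solutions"
  out
}

#' @exportS3Method base::print
print.model_solutions <- function(x, ...) {
  cat(sprintf(
    "model_solutions: %d equations, relative residual %.2e, %d constrained\n",
    length(x$theta), x$relres, x$n_constrained))
  invisible(x)
}

#' Extract a block of solutions
#'
#' @param solutions a `model_solutions`.
#' @param effect one of `"mu","hty","htmp","as","ls","htd","hy","pe","gen"`.
#' @return for intercept-type effects a `levels x 4` matrix (traits in
#'   columns); for regression effects a `levels x 12` matrix (trait-major
#'   coefficient columns).
#' @export
solution_block <- function(solutions, effect) {
  str <- solutions$structure
  off <- str$offsets[[effect]]
  nlev <- switch(effect, mu = 1L, hty = str$counts$hty,
                 htmp = str$counts$htmp, as = str$counts$as,
                 ls = str$counts$ls, htd = str$counts$htd,
                 hy = str$counts$hy, pe = str$counts$cow,
                 gen = str$counts$gen)
  wid <- if (effect %in% c("hy", "pe", "gen")) 12L else N_TRAITS
  m <- matrix(solutions$theta[off + seq_len(nlev * wid)], nrow = nlev,
              byrow = TRUE)
  rn <- switch(effect, mu = "mu", hty = str$coding$hty$levels,
               htmp = str$coding$htmp$levels, as = str$coding$as$levels,
               ls = str$coding$ls$levels, htd = str$coding$htd$levels,
               hy = str$coding$hy$levels, pe = str$coding$cow$levels,
               gen = str$gen_ids)
  cn <- if (wid == 12L) {
    paste(rep(TRAITS, each = N_COEF), rep(paste0("phi", 0:2), 4), sep = ".")
  } else TRAITS
  dimnames(m) <- list(rn, cn)
  m
}

#' Residuals of a solved system
#'
#' \eqn{\hat e = y - \hat y} for observed traits only, where the fitted value
#' sums the fixed-effect, herd-test-day, herd-year, permanent-environment and
#' genetic contributions of the record.
#'
#' @param solutions a `model_solutions`.
#' @return data frame with `record` (row index into the fitted records),
#'   `trait` and `residual`.
#' @export
compute_residuals <- function(solutions) {
  str <- solutions$structure
  fit <- as.numeric(str$M %*% solutions$theta)
  data.frame(record = str$row_rec, trait = TRAITS[str$row_trait],
             residual = str$y - fit, fitted = fit, observed = str$y)
}
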