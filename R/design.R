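#' @useDynLib bcsrr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Matrix
#' @importFrom methods as new is
#' @importFrom stats rnorm quantile var sd cor qnorm pnorm setNames aggregate
#' @importFrom utils read.csv write.csv
NULL

# Trait order is fixed throughout the package: milk yield (kg), fat %,
# protein %, body condition score (1-9).
TRAITS <- c("MY", "FP", "PP", "BCS")
N_TRAITS <- 4L
N_COEF <- 3L # second-order Legendre polynomial: intercept, linear, quadratic

#' Legendre polynomial covariates for days in milk
#'
#' Standardizes days in milk (DIM) onto \eqn{[-1, 1]} over the data window and
#' evaluates the second-order Legendre polynomials there. Random-regression
#' herd-year, permanent-environment and additive-genetic effects all load on
#' these three covariates, so each effect level is a curve over the lactation.
#'
#' @param dim integer vector of days in milk.
#' @param dim_min,dim_max the DIM window the basis is standardized to;
#'   defaults match the data edits (5 and 365 days).
#' @param normalized if `TRUE` (default) the orthonormal scaling
#'   \eqn{\phi_k = \sqrt{(2k+1)/2}\,P_k} is used, so that
#'   \eqn{\int_{-1}^{1}\phi_i\phi_j\,dx = \delta_{ij}}; if `FALSE` the raw
#'   polynomials \eqn{P_k} are returned. Variance components are
#'   basis-dependent, so the flag in use is recorded by the pipeline log.
#' @return a `length(dim) x 3` matrix of covariates.
#' @export
legendre_covariates <- function(dim, dim_min = 5L, dim_max = 365L,
                                normalized = TRUE) {
  dim <- as.numeric(dim)
  if (any(!is.finite(dim)) || any(dim < dim_min) || any(dim > dim_max)) {
    stop("dim outside the basis window [", dim_min, ", ", dim_max, "]")
  }
  x <- 2 * (dim - dim_min) / (dim_max - dim_min) - 1
  p0 <- rep(1, length(x))
  p1 <- x
  p2 <- (3 * x^2 - 1) / 2
  out <- cbind(p0, p1, p2)
  if (normalized) {
    out <- sweep(out, 2, sqrt((2 * (0:2) + 1) / 2), `*`)
  }
  colnames(out) <- paste0("phi", 0:2)
  out
}

#' A Legendre basis description
#'
#' Bundles the DIM window and normalization choice so that fitting and
#' prediction always evaluate the same covariates.
#'
#' @inheritParams legendre_covariates
#' @return an object of class `legendre_basis`.
#' @export
legendre_basis <- function(dim_min = 5L, dim_max = 365L, normalized = TRUE) {
  structure(list(dim_min = as.integer(dim_min), dim_max = as.integer(dim_max),
                 normalized = isTRUE(normalized), order = 2L),
            class = "legendre_basis")
}

#' Evaluate a Legendre basis at given DIM
#' @param basis a [legendre_basis()].
#' @param dim integer vector of days in milk.
#' @return matrix of covariates, one row per element of `dim`.
#' @export
basis_eval <- function(basis, dim) {
  stopifnot(inherits(basis, "legendre_basis"))
  legendre_covariates(dim, basis$dim_min, basis$dim_max, basis$normalized)
}

#' Test-year period of a test date
#'
#' Herd-test-year-period (HTY) uses two test-year classes: 2014-2016 and
#' 2017-2022. The map is configurable so that synthetic calendars outside the
#' study window can reuse the machinery.
#'
#' @param test_date a `Date` vector.
#' @param breaks named list mapping period index to an inclusive year range
#'   `c(from, to)`.
#' @return integer period per date.
#' @export
assign_test_year_period <- function(test_date,
                                    breaks = list(`1` = c(2014, 2016),
                                                  `2` = c(2017, 2022))) {
  yr <- as.integer(format(as.Date(test_date), "%Y"))
  out <- rep(NA_integer_, length(yr))
  for (k in names(breaks)) {
    rg <- breaks[[k]]
    out[yr >= rg[1] & yr <= rg[2]] <- as.integer(k)
  }
  if (anyNA(out)) {
    stop("test year(s) outside the configured test-year-period map: ",
         paste(unique(yr[is.na(out)]), collapse = ", "))
  }
  out
}

#' Season of a date
#'
#' Winter is January-March, spring April-June, summer July-September and
#' autumn October-December.
#'
#' @param date a `Date` vector.
#' @return character vector in `{"winter","spring","summer","autumn"}`.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "spring", "summer", "autumn")[(m - 1L) %/% 3L + 1L]
}

#' Major lactation stage
#'
#' Three classes: DIM 5-50, 51-200 and 201-365 (bounds inclusive).
#'
#' @param dim integer days in milk in `[5, 365]`.
#' @return integer stage in `{1, 2, 3}`.
#' @export
assign_major_stage <- function(dim) {
  dim <- as.integer(dim)
  if (any(dim < 5L | dim > 365L)) stop("dim outside [5, 365]")
  ifelse(dim <= 50L, 1L, ifelse(dim <= 200L, 2L, 3L))
}

#' Minor lactation stage
#'
#' 32 classes modelling the average lactation curve: DIM 5-15, then 29
#' ten-day classes covering DIM 16-305, then two 30-day classes for
#' DIM 306-335 and 336-365. The classes partition `[5, 365]` exactly.
#'
#' @param dim integer days in milk in `[5, 365]`.
#' @return integer class in `{1..32}`.
#' @export
assign_minor_stage <- function(dim) {
  dim <- as.integer(dim)
  if (any(dim < 5L | dim > 365L)) stop("dim outside [5, 365]")
  ifelse(dim <= 15L, 1L,
         ifelse(dim <= 305L, (dim - 16L) %/% 10L + 2L,
                ifelse(dim <= 335L, 31L, 32L)))
}

#' Calving-year period
#'
#' Three herd-calving-year (HY) classes: calving year 2014, 2015-2017 and
#' 2018-2022; configurable like the test-year map.
#'
#' @param calving_date a `Date` vector.
#' @param breaks named list of inclusive year ranges per period.
#' @return integer period per date.
#' @export
assign_calving_year_period <- function(calving_date,
                                       breaks = list(`1` = c(2014, 2014),
                                                     `2` = c(2015, 2017),
                                                     `3` = c(2018, 2022))) {
  yr <- as.integer(format(as.Date(calving_date), "%Y"))
  out <- rep(NA_integer_, length(yr))
  for (k in names(breaks)) {
    rg <- breaks[[k]]
    out[yr >= rg[1] & yr <= rg[2]] <- as.integer(k)
  }
  if (anyNA(out)) {
    stop("calving year(s) outside the configured calving-year-period map: ",
         paste(unique(yr[is.na(out)]), collapse = ", "))
  }
  out
}

# Dense, order-stable level index for a character key vector: levels sorted
# lexicographically so that permuting records never changes the coding.
.dense_levels <- function(key) {
  lev <- sort(unique(key))
  list(index = match(key, lev), levels = lev)
}

#' Assign every record to its fixed- and random-effect classes
#'
#' Builds the level codings for the model effects:
#' \describe{
#'   \item{HTY}{fixed herd x test-year-period,}
#'   \item{HTMp}{fixed herd x test season,}
#'   \item{AS}{fixed age-at-calving class x calving season x major lactation
#'     stage,}
#'   \item{LS}{fixed minor lactation stage (32 DIM classes),}
#'   \item{HTD}{random herd x test date (contemporary group),}
#'   \item{HY}{random-regression herd x calving-year-period,}
#'   \item{cow}{permanent environment (one level per cow with records).}
#' }
#' Age-at-calving classes default to terciles of the observed age-at-first-
#' calving distribution; explicit cut-points can be supplied instead. Level
#' indices are dense and stable under permutation of the records.
#'
#' @param records a test-day record data frame (see [read_records()]).
#' @param age_cutpoints optional numeric vector of two interior cut-points
#'   (days) separating the three age classes; `NULL` means terciles.
#' @param ty_breaks,cy_breaks year-period maps passed to
#'   [assign_test_year_period()] and [assign_calving_year_period()].
#' @return an object of class `effect_coding`: per-record integer indices and
#'   the level tables they refer to.
#' @export
build_coding <- function(records, age_cutpoints = NULL,
                         ty_breaks = list(`1` = c(2014, 2016),
                                          `2` = c(2017, 2022)),
                         cy_breaks = list(`1` = c(2014, 2014),
                                          `2` = c(2015, 2017),
                                          `3` = c(2018, 2022))) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  age_days <- as.integer(as.Date(records$calving_date) -
                         as.Date(records$birth_date))
  if (is.null(age_cutpoints)) {
    per_cow <- tapply(age_days, records$animal_id, `[`, 1L)
    age_cutpoints <- unname(quantile(per_cow, c(1 / 3, 2 / 3), type = 1))
  }
  age_class <- findInterval(age_days, age_cutpoints) + 1L
  typ <- assign_test_year_period(records$test_date, ty_breaks)
  season <- assign_season(records$test_date)
  cseason <- assign_season(records$calving_date)
  mstage <- assign_major_stage(records$dim)
  lstage <- assign_minor_stage(records$dim)
  cyp <- assign_calving_year_period(records$calving_date, cy_breaks)

  hty <- .dense_levels(paste(records$herd_id, typ, sep = "|"))
  htmp <- .dense_levels(paste(records$herd_id, season, sep = "|"))
  as_ <- .dense_levels(paste(age_class, cseason, mstage, sep = "|"))
  ls_ <- .dense_levels(sprintf("LS%02d", lstage))
  htd <- .dense_levels(paste(records$herd_id, records$test_date, sep = "|"))
  hy <- .dense_levels(paste(records$herd_id, cyp, sep = "|"))
  cow <- .dense_levels(as.character(records$animal_id))

  structure(list(
    hty = hty, htmp = htmp, as = as_, ls = ls_, htd = htd, hy = hy, cow = cow,
    age_cutpoints = age_cutpoints, ty_breaks = ty_breaks,
    cy_breaks = cy_breaks, n_records = nrow(records)
  ), class = "effect_coding")
}

#' Decode a dense level index back to its key
#' @param coding an `effect_coding`.
#' @param effect one of `"hty","htmp","as","ls","htd","hy","cow"`.
#' @param index integer level index.
#' @return the level key string(s).
#' @export
decode_level <- function(coding, effect, index) {
  stopifnot(inherits(coding, "effect_coding"))
  coding[[effect]]$levels[index]
}
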