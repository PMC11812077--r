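#' Read a pedigree file
#'
#' Columns `animal_id,sire_id,dam_id`; `0` (or empty) codes an unknown parent.
#'
#' @param path CSV file path.
#' @return data frame with character ids, `NA` for unknown parents.
#' @export
read_pedigree <- function(path) {
  ped <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("animal_id", "sire_id", "dam_id")
  if (!all(need %in% names(ped))) {
    stop("pedigree file must have columns ", paste(need, collapse = ", "))
  }
  ped$sire_id[ped$sire_id %in% c("0", "", "NA")] <- NA_character_
  ped$dam_id[ped$dam_id %in% c("0", "", "NA")] <- NA_character_
  ped[need]
}

#' Topologically sort a pedigree
#'
#' Orders animals so that parents precede offspring; unknown parents are
#' treated as unrelated founders. Animals appearing only as parents are added
#' as founders. A cycle (an animal its own ancestor) is an error naming the
#' animals involved.
#'
#' @param ped data frame with `animal_id`, `sire_id`, `dam_id` (NA = unknown).
#' @return an object of class `pedigree`: ordered ids, integer sire/dam
#'   indices (`NA` = unknown) and inbreeding coefficients `f`.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  ped$animal_id <- as.character(ped$animal_id)
  ped$sire_id <- as.character(ped$sire_id)
  ped$dam_id <- as.character(ped$dam_id)
  if (anyDuplicated(ped$animal_id)) {
    stop("duplicate animal_id in pedigree: ",
         paste(unique(ped$animal_id[duplicated(ped$animal_id)]), collapse = ", "))
  }
  parents_only <- setdiff(c(ped$sire_id, ped$dam_id), c(ped$animal_id, NA))
  if (length(parents_only)) {
    ped <- rbind(ped[, c("animal_id", "sire_id", "dam_id")],
                 data.frame(animal_id = sort(parents_only),
                            sire_id = NA_character_, dam_id = NA_character_))
  }
  n <- nrow(ped)
  id <- ped$animal_id
  si <- match(ped$sire_id, id)
  di <- match(ped$dam_id, id)
  # Kahn topological sort, stable in input order
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), order_out)], collapse = ", "))
  }
  id2 <- id[order_out]
  pos <- match(seq_len(n), order_out) # old index -> new position
  si2 <- pos[si[order_out]]
  di2 <- pos[di[order_out]]
  out <- structure(list(id = id2, sire = si2, dam = di2), class = "pedigree")
  out$f <- inbreeding(out)
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding F (and, as an attribute, the Mendelian
#' sampling variances \eqn{d_i} of the \eqn{A = T D T'} decomposition)
#' without forming the dense relationship matrix.
#'
#' @param ped a sorted `pedigree`.
#' @return numeric vector `F` with attribute `"mendelian"`.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  f <- numeric(n)
  dii <- numeric(n)
  if (n == 0L) {
    attr(f, "mendelian") <- dii
    return(f)
  }
  s <- ifelse(is.na(ped$sire), 0L, ped$sire)
  d <- ifelse(is.na(ped$dam), 0L, ped$dam)
  w <- numeric(n)      # ancestor contribution weights T_ij
  nxt <- integer(n)    # linked list over ancestor indices, descending
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    dii[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L || d[i] == 0L) next # F = 0 with an unknown parent
    # A_ii = sum_j w_j^2 d_j over ancestors j (including i, w_i = 1)
    aii <- 0
    w[i] <- 1
    nxt[i] <- 0L
    j <- i
    while (j > 0L) {
      wj <- w[j]
      aii <- aii + wj * wj * dii[j]
      for (par in c(s[j], d[j])) {
        if (par > 0L) {
          if (w[par] == 0) { # not yet in the list; insert behind j
            k <- j
            while (nxt[k] > par) k <- nxt[k]
            nxt[par] <- nxt[k]
            nxt[k] <- par
          }
          w[par] <- w[par] + 0.5 * wj
        }
      }
      jn <- nxt[j]
      w[j] <- 0
      nxt[j] <- 0L
      j <- jn
    }
    f[i] <- aii - 1
  }
  attr(f, "mendelian") <- dii
  f
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense recursion \eqn{a_{ij} = (a_{j,s(i)} + a_{j,d(i)})/2} for \eqn{j<i},
#' \eqn{a_{ii} = 1 + a_{s(i),d(i)}/2}. Intended for moderate pedigrees; the
#' mixed-model equations only ever use the sparse inverse.
#'
#' @param ped a sorted `pedigree`.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{\alpha_i = 1/d_i} (the inverse Mendelian sampling variance, computed
#' from parental inbreeding via [inbreeding()]) to at most 9 cells of
#' \eqn{A^{-1}}.
#'
#' @param ped a sorted `pedigree`.
#' @return a symmetric sparse `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  f <- ped$f
  dii <- attr(f, "mendelian")
  if (is.null(dii)) {
    f <- inbreeding(ped)
    dii <- attr(f, "mendelian")
  }
  if (any(dii <= 0)) {
    stop("non-positive Mendelian sampling variance for animal(s): ",
         paste(ped$id[dii <= 0], collapse = ", "), " (corrupt pedigree)")
  }
  # vectorized triplet construction; sparseMatrix sums duplicate cells
  s <- ped$sire; d <- ped$dam
  alpha <- 1 / dii
  tr_i <- list(); tr_j <- list(); tr_x <- list(); k <- 1L
  push <- function(i, j, x) {
    tr_i[[k]] <<- i; tr_j[[k]] <<- j; tr_x[[k]] <<- x; k <<- k + 1L
  }
  idx <- seq_len(n)
  push(idx, idx, alpha)
  hs <- !is.na(s)
  push(idx[hs], s[hs], -0.5 * alpha[hs])
  push(s[hs], idx[hs], -0.5 * alpha[hs])
  push(s[hs], s[hs], 0.25 * alpha[hs])
  hd <- !is.na(d)
  push(idx[hd], d[hd], -0.5 * alpha[hd])
  push(d[hd], idx[hd], -0.5 * alpha[hd])
  push(d[hd], d[hd], 0.25 * alpha[hd])
  hb <- hs & hd
  push(s[hb], d[hb], 0.25 * alpha[hb])
  push(d[hb], s[hb], 0.25 * alpha[hb])
  Ainv <- Matrix::sparseMatrix(i = unlist(tr_i), j = unlist(tr_j),
                               x = unlist(tr_x), dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
}

#' Log-determinant of A from the pedigree
#'
#' \eqn{\log|A| = \sum_i \log d_i} with \eqn{d_i} the Mendelian sampling
#' variances; used by the restricted likelihood.
#'
#' @param ped a sorted `pedigree`.
#' @return scalar log-determinant.
#' @export
logdet_A <- function(ped) {
  f <- ped$f
  dii <- attr(f, "mendelian")
  if (is.null(dii)) dii <- attr(inbreeding(ped), "mendelian")
  sum(log(dii))
}
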