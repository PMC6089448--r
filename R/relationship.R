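#' Numerator relationship matrix by the tabular method
#'
#' Builds the pedigree-expected additive relationship matrix A: processing
#' animals parents-first, `A[i, j] = (A[j, sire(i)] + A[j, dam(i)]) / 2` for
#' previously processed j, and `A[i, i] = 1 + A[sire(i), dam(i)] / 2`
#' (diagonal = 1 + inbreeding coefficient). Unknown parents contribute zero
#' relationship and no inbreeding. Positive semi-definiteness is checked by
#' attempted Cholesky factorization on every build.
#'
#' @param ped pedigree `data.frame` (see [validate_pedigree()]).
#' @return symmetric matrix with animal ids as dimnames and attribute
#'   `inbreeding` (named vector F_i = diag - 1).
#' @export
build_numerator_relationship <- function(ped) {
  ped <- validate_pedigree(ped)
  ord <- pedigree_order(ped)
  id <- ped$animal_id
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  sire <- idx[as.character(ped$sire_id)]
  dam <- idx[as.character(ped$dam_id)]
  A <- matrix(0, n, n, dimnames = list(id, id))
  pos <- integer(0) # already-processed indices
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    rs <- if (!is.na(s)) A[s, pos] else rep(0, length(pos))
    rd <- if (!is.na(d)) A[d, pos] else rep(0, length(pos))
    if (length(pos)) {
      A[i, pos] <- (rs + rd) / 2
      A[pos, i] <- A[i, pos]
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    pos <- c(pos, i)
  }
  # PSD check: A + tiny jitter must factorize (A is PD in exact arithmetic)
  ok <- tryCatch({ chol(A + diag(1e-10, n)); TRUE }, error = function(e) FALSE)
  if (!ok) stop("matrix error: relationship matrix is not positive semi-definite",
                call. = FALSE)
  attr(A, "inbreeding") <- setNames(diag(A) - 1, id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Meuwissen-Luo-style inbreeding adjustment: for
#' animal i with Mendelian sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (terms adapted for unknown parents),
#' add `1/d_i` at (i,i), `-1/(2 d_i)` at (i, parent) and `1/(4 d_i)` between
#' parents. Inbreeding coefficients are taken from the tabular A (the
#' pedigrees used here are small enough that this costs nothing and keeps a
#' single source of truth for F).
#'
#' @param ped pedigree `data.frame`.
#' @return a sparse symmetric `Matrix::dsCMatrix`, ordered as the pedigree.
#' @export
relationship_inverse <- function(ped) {
  A <- build_numerator_relationship(ped)
  Fi <- attr(A, "inbreeding")
  id <- rownames(A)
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  sire <- idx[as.character(ped$sire_id)]
  dam <- idx[as.character(ped$dam_id)]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    ns <- !is.na(s); nd <- !is.na(d)
    di <- 1 - (if (ns) 0.25 * (1 + Fi[s]) else 0) - (if (nd) 0.25 * (1 + Fi[d]) else 0)
    w <- 1 / di
    add(i, i, w)
    if (ns) { add(i, s, -w / 2); add(s, i, -w / 2); add(s, s, w / 4) }
    if (nd) { add(i, d, -w / 2); add(d, i, -w / 2); add(d, d, w / 4) }
    if (ns && nd) { add(s, d, w / 4); add(d, s, w / 4) }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(id, id))
  Matrix::forceSymmetric(Ainv)
}
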