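#' Closure: project a positive vector onto the unit simplex
#'
#' Divides a vector of positive abundances by its sum so that the result is a
#' composition (a vector of proportions summing to one).  Closure is the basic
#' operation of Aitchison geometry: it discards overall scale while preserving
#' all ratios between parts.
#'
#' @param m Numeric vector (or a matrix whose columns are vectors) of strictly
#'   positive abundances; length (or row count) at least 2.
#' @return A composition (vector summing to 1), or a matrix whose columns are
#'   compositions.  Names/dimnames are preserved.
#' @examples
#' closure(c(2, 3, 5))
#' @export
closure <- function(m) {
  if (is.matrix(m)) {
    if (nrow(m) < 2L) stop("closure() needs at least 2 parts", call. = FALSE)
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("closure() requires strictly positive finite entries", call. = FALSE)
    }
    return(sweep(m, 2L, colSums(m), "/"))
  }
  if (length(m) < 2L) stop("closure() needs at least 2 parts", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("closure() requires strictly positive finite entries", call. = FALSE)
  }
  m / sum(m)
}

check_composition <- function(p, tol = 1e-6) {
  if (is.matrix(p)) {
    if (nrow(p) < 2L) stop("a composition needs D >= 2 parts", call. = FALSE)
    if (any(!is.finite(p)) || any(p <= 0)) {
      stop("composition parts must be strictly positive", call. = FALSE)
    }
    if (any(abs(colSums(p) - 1) > tol)) {
      stop("composition columns must sum to 1", call. = FALSE)
    }
  } else {
    if (length(p) < 2L) stop("a composition needs D >= 2 parts", call. = FALSE)
    if (any(!is.finite(p)) || any(p <= 0)) {
      stop("composition parts must be strictly positive", call. = FALSE)
    }
    if (abs(sum(p) - 1) > tol) stop("composition must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Contrast bases for log-ratio coordinates
#'
#' A contrast basis is a \eqn{(D-1) \times D} matrix \eqn{\Psi} whose rows sum
#' to zero and have rank \eqn{D-1}, together with a right inverse
#' \eqn{\Psi^\dagger} (a \eqn{D \times (D-1)} matrix with
#' \eqn{\Psi \Psi^\dagger = I_{D-1}}).  Log-ratio coordinates of a composition
#' are \eqn{\eta = \Psi \log p}; the inverse map is
#' \eqn{p = C[\exp(\Psi^\dagger \eta)]} where \eqn{C} is [closure()].  Because
#' the kernel of \eqn{\Psi} is spanned by the ones vector, the inverse map does
#' not depend on which right inverse is used.
#'
#' `alr_basis()` builds the additive log-ratio (ALR) basis with reference part
#' `ref`: row \eqn{j} contrasts part \eqn{j} against the reference.
#'
#' @param D Number of parts (taxa), at least 2.
#' @param ref Index of the reference part, in `1..D`.  Defaults to the last
#'   part, the usual ALR convention.
#' @return An object of class `contrast_basis`: a list with elements `psi`
#'   ((D-1) x D), `psi_rinv` (D x (D-1)), `kind`, `D`, and `ref` (`NA` for
#'   non-ALR bases).
#' @examples
#' b <- alr_basis(3)
#' b$psi %*% b$psi_rinv  # identity
#' @export
alr_basis <- function(D, ref = D) {
  if (D < 2L) stop("D must be >= 2", call. = FALSE)
  if (length(ref) != 1L || is.na(ref) || ref < 1L || ref > D) {
    stop("ref must be an index in 1..D", call. = FALSE)
  }
  keep <- setdiff(seq_len(D), ref)
  psi <- matrix(0, D - 1L, D)
  psi[cbind(seq_len(D - 1L), keep)] <- 1
  psi[, ref] <- -1
  rinv <- matrix(0, D, D - 1L)
  rinv[cbind(keep, seq_len(D - 1L))] <- 1
  structure(
    list(psi = psi, psi_rinv = rinv, kind = "alr", D = as.integer(D),
         ref = as.integer(ref)),
    class = "contrast_basis"
  )
}

#' @rdname alr_basis
#' @param psi A (D-1) x D contrast matrix: rows sum to zero, rank D-1.
#' @param psi_rinv Optional right inverse; computed by pseudo-inversion when
#'   omitted.
#' @param kind Tag describing the basis.
#' @export
contrast_basis <- function(psi, psi_rinv = NULL, kind = "custom") {
  psi <- as.matrix(psi)
  D <- ncol(psi)
  if (nrow(psi) != D - 1L) stop("psi must be (D-1) x D", call. = FALSE)
  if (any(abs(rowSums(psi)) > 1e-9)) {
    stop("contrast rows must sum to zero", call. = FALSE)
  }
  if (qr(psi)$rank != D - 1L) stop("psi must have rank D-1", call. = FALSE)
  if (is.null(psi_rinv)) {
    # Moore-Penrose right inverse via SVD
    sv <- svd(psi)
    psi_rinv <- sv$v %*% (t(sv$u) / sv$d)
  }
  psi_rinv <- as.matrix(psi_rinv)
  if (max(abs(psi %*% psi_rinv - diag(D - 1L))) > 1e-9) {
    stop("psi_rinv is not a right inverse of psi", call. = FALSE)
  }
  structure(
    list(psi = psi, psi_rinv = psi_rinv, kind = kind, D = as.integer(D),
         ref = NA_integer_),
    class = "contrast_basis"
  )
}

#' @export
print.contrast_basis <- function(x, ...) {
  cat(sprintf("<contrast_basis> kind=%s D=%d%s\n", x$kind, x$D,
              if (!is.na(x$ref)) sprintf(" ref=%d", x$ref) else ""))
  invisible(x)
}

#' Log-ratio transform and its inverse
#'
#' `to_logratio()` maps compositions to log-ratio coordinates
#' \eqn{\eta = \Psi \log p}; `from_logratio()` maps coordinates back to the
#' simplex via \eqn{C[\exp(\Psi^\dagger \eta)]}.  Both accept a single vector
#' or a matrix whose columns are compositions / coordinate vectors (e.g.
#' posterior draws).
#'
#' @param p Composition vector of length D, or D x M matrix of compositions.
#' @param basis A [contrast_basis].
#' @return `to_logratio()`: a (D-1)-vector or (D-1) x M matrix.
#'   `from_logratio()`: a D-vector or D x M matrix of compositions.
#' @examples
#' b <- alr_basis(3)
#' to_logratio(c(0.4, 0.4, 0.2), b)        # (log 2, log 2)
#' from_logratio(c(log(2), log(2)), b)     # (0.4, 0.4, 0.2)
#' @export
to_logratio <- function(p, basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  vec <- !is.matrix(p)
  pm <- if (vec) matrix(p, ncol = 1L) else p
  if (nrow(pm) != basis$D) {
    stop(sprintf("composition has %d parts but basis expects %d",
                 nrow(pm), basis$D), call. = FALSE)
  }
  if (any(!is.finite(pm)) || any(pm <= 0)) {
    stop("log-ratio transform requires strictly positive parts", call. = FALSE)
  }
  eta <- basis$psi %*% log(pm)
  if (vec) drop(eta) else eta
}

#' @rdname to_logratio
#' @param eta (D-1)-vector or (D-1) x M matrix of log-ratio coordinates.
#' @export
from_logratio <- function(eta, basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  vec <- !is.matrix(eta)
  em <- if (vec) matrix(eta, ncol = 1L) else eta
  if (nrow(em) != basis$D - 1L) {
    stop(sprintf("eta has %d coordinates but basis expects %d",
                 nrow(em), basis$D - 1L), call. = FALSE)
  }
  if (any(!is.finite(em))) stop("eta must be finite", call. = FALSE)
  o <- basis$psi_rinv %*% em
  # stabilised closure of exp()
  o <- sweep(o, 2L, apply(o, 2L, max), "-")
  p <- exp(o)
  p <- sweep(p, 2L, colSums(p), "/")
  if (vec) drop(p) else p
}

#' Centred log-ratio transform
#'
#' \eqn{clr(p) = \log p - mean(\log p)}.  CLR coordinates sum to zero across
#' parts; the Euclidean distance between CLR vectors is the Aitchison
#' distance.
#'
#' @inheritParams to_logratio
#' @return A D-vector or D x M matrix with zero column sums.
#' @export
clr <- function(p) {
  vec <- !is.matrix(p)
  pm <- if (vec) matrix(p, ncol = 1L) else p
  if (any(!is.finite(pm)) || any(pm <= 0)) {
    stop("clr requires strictly positive parts", call. = FALSE)
  }
  lp <- log(pm)
  out <- sweep(lp, 2L, colMeans(lp), "-")
  if (vec) drop(out) else out
}

#' Convert log-ratio coordinates between an ALR-style basis and CLR
#'
#' Maps coordinates (columns of `eta`) expressed in `basis` to centred
#' log-ratio coordinates of the same underlying compositions.  Used to report
#' posterior draws fitted in ALR coordinates on the CLR scale.
#'
#' @param eta (D-1)-vector or (D-1) x M matrix of coordinates in `basis`.
#' @param basis The [contrast_basis] in which `eta` is expressed.
#' @return D-vector or D x M matrix of CLR coordinates (zero column sums).
#' @export
alr_to_clr <- function(eta, basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  vec <- !is.matrix(eta)
  em <- if (vec) matrix(eta, ncol = 1L) else eta
  if (nrow(em) != basis$D - 1L) {
    stop("coordinate dimension does not match basis", call. = FALSE)
  }
  o <- basis$psi_rinv %*% em          # log-parts up to an additive constant
  out <- sweep(o, 2L, colMeans(o), "-")
  if (vec) drop(out) else out
}

#' Compositional perturbation
#'
#' Elementwise multiplication followed by closure: the group operation of
#' Aitchison geometry.  PCR amplification bias acts as a cycle-indexed
#' perturbation of the template composition.
#'
#' @param p Composition (vector or D x M matrix of compositions).
#' @param q Strictly positive perturbation vector of the same dimension D.
#' @return Perturbed composition(s).
#' @examples
#' perturb(c(0.5, 0.5), c(4, 1))  # (0.8, 0.2)
#' @export
perturb <- function(p, q) {
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("perturbation must be strictly positive", call. = FALSE)
  }
  if (is.matrix(p)) {
    if (length(q) != nrow(p)) stop("dimension mismatch", call. = FALSE)
    check_composition(p)
    closure(p * q)
  } else {
    if (length(q) != length(p)) stop("dimension mismatch", call. = FALSE)
    check_composition(p)
    closure(p * q)
  }
}

#' Aitchison distance between compositions
#'
#' The Euclidean norm of the difference of CLR representations.  It is a
#' metric on the simplex and is invariant under compositional perturbation,
#' which makes it the natural yardstick for how far PCR bias moves a sample.
#'
#' @param x,y Compositions of the same dimension.
#' @return Nonnegative scalar.
#' @examples
#' aitchison_distance(c(0.5, 0.5), c(0.8, 0.2))  # sqrt(2) * log(2)
#' @export
aitchison_distance <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  check_composition(x)
  check_composition(y)
  sqrt(sum((clr(x) - clr(y))^2))
}
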