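# Spin-3/2 operator algebra on the irreducible spherical tensor basis.
#
# The density operator of an isolated spin-3/2 nucleus is expanded on the 15
# normalized tensor operators T_{l,m} (l = 1..3, m = -l..l; the identity is
# dropped since it is invariant under all dynamics considered).  All dynamics
# (RF nutation, residual quadrupole splitting, Redfield quadrupolar
# relaxation) are 15 x 15 complex linear maps on the coefficient vector.

.spin32_cache <- new.env(parent = emptyenv())

#' Angular momentum matrices for spin 3/2
#'
#' @return list with `Iz`, `Ip` (raising), `Im` (lowering), `Ix`, `Iy`
#'   as 4 x 4 complex matrices in the m = 3/2 .. -3/2 basis.
#' @keywords internal
spin32_operators <- function() {
  if (!is.null(.spin32_cache$ops)) return(.spin32_cache$ops)
  m <- c(3 / 2, 1 / 2, -1 / 2, -3 / 2)
  Iz <- diag(m) + 0i
  Ip <- matrix(0i, 4, 4)
  for (k in 2:4) {
    mm <- m[k]
    Ip[k - 1, k] <- sqrt(15 / 4 - mm * (mm + 1))
  }
  Im <- Conj(t(Ip))
  ops <- list(Iz = Iz, Ip = Ip, Im = Im,
              Ix = (Ip + Im) / 2, Iy = (Ip - Im) / (2i))
  .spin32_cache$ops <- ops
  ops
}

.comm <- function(a, b) a %*% b - b %*% a

#' Orthonormal irreducible tensor operator basis for spin 3/2
#'
#' Operators are normalized to unit Frobenius norm, Tr(T_lm^H T_l'm') =
#' delta_ll' delta_mm', with the phase convention T_lm^H = (-1)^m T_l,-m
#' (so T_10 is +Iz/sqrt(5) and T_11 is -Ip/sqrt(10)).
#'
#' @return list with `ops` (list of 15 4x4 matrices), `lm` (data.frame of l
#'   and m per slot), and `index(l, m)` lookup.
#' @keywords internal
tensor_basis <- function() {
  if (!is.null(.spin32_cache$basis)) return(.spin32_cache$basis)
  sp <- spin32_operators()
  lm <- do.call(rbind, lapply(1:3, function(l) data.frame(l = l, m = -l:l)))
  ops <- vector("list", nrow(lm))
  for (l in 1:3) {
    # top of the ladder: T_ll proportional to (-1)^l Ip^l, unit norm
    top <- (-1)^l * Reduce(`%*%`, rep(list(sp$Ip), l))
    top <- top / sqrt(Re(sum(diag(Conj(t(top)) %*% top))))
    cur <- top
    ops[[which(lm$l == l & lm$m == l)]] <- cur
    for (mm in l:(-l + 1)) {
      cur <- .comm(sp$Im, cur) / sqrt(l * (l + 1) - mm * (mm - 1))
      ops[[which(lm$l == l & lm$m == mm - 1)]] <- cur
    }
  }
  basis <- list(
    ops = ops, lm = lm,
    index = function(l, m) which(lm$l == l & lm$m == m)
  )
  .spin32_cache$basis <- basis
  basis
}

# Project a 4x4 operator X onto the tensor basis: c_j = Tr(T_j^H X)
.project <- function(X, basis = tensor_basis()) {
  vapply(basis$ops, function(Tj) sum(diag(Conj(t(Tj)) %*% X)), complex(1))
}

# Superoperator of a linear map f on 4x4 operators, expressed on the basis
.superop <- function(f, basis = tensor_basis()) {
  n <- length(basis$ops)
  L <- matrix(0i, n, n)
  for (k in seq_len(n)) L[, k] <- .project(f(basis$ops[[k]]), basis)
  L
}

#' Matrix exponential of a complex square matrix
#'
#' Scaling-and-squaring with a diagonal Pade approximant; used for
#' propagators of the (generally non-Hermitian) evolution generators.
#'
#' @param A complex square matrix
#' @return expm(A)
#' @keywords internal
expm_complex <- function(A) {
  n <- nrow(A)
  nrm <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin)) + 1))
  As <- A / 2^s
  # Pade(6,6)
  c6 <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n) + 0i
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A4 %*% A2
  U <- As %*% (c6[2] * I + c6[4] * A2 + c6[6] * A4)
  V <- c6[1] * I + c6[3] * A2 + c6[5] * A4 + c6[7] * A6
  E <- solve(V - U, V + U)
  if (s > 0) for (k in seq_len(s)) E <- E %*% E
  E
}
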