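# Redfield quadrupolar relaxation and evolution generators for spin-3/2 Na.

#' Describe the relaxation of one sodium environment
#'
#' A sodium environment (intracellular, extracellular, myelin water, edema,
#' CSF, agar reference gel) is characterized by the spectral densities of the
#' fluctuating quadrupolar interaction at zero, one, and two times the Larmor
#' frequency, plus an optional residual (time-averaged) quadrupole splitting
#' that survives motional averaging in ordered environments such as the
#' myelin water layers.
#'
#' @param name environment label (e.g. "intra", "extra", "myelin", "edema",
#'   "csf", "agar")
#' @param J0,J1,J2 spectral densities at 0, w0 and 2*w0 in s^-1; must satisfy
#'   `J0 >= J1 >= J2 >= 0`
#' @param fQ_hz residual quadrupole splitting in Hz (0 for isotropic
#'   environments)
#' @param fQ_model `"single-value"` (one effective splitting) or
#'   `"powder-average"` (splitting scaled by the second Legendre polynomial
#'   of a uniformly distributed orientation, averaged by Gauss-Legendre
#'   quadrature)
#' @param fQ_n_orient number of quadrature points for the powder average
#' @return object of class `na_environment`
#' @export
#' @examples
#' env <- na_environment("intra", J0 = 250, J1 = 20, J2 = 12)
#' redfield_rates(env)
na_environment <- function(name, J0, J1, J2, fQ_hz = 0,
                           fQ_model = c("single-value", "powder-average"),
                           fQ_n_orient = 64L) {
  fQ_model <- match.arg(fQ_model)
  stopifnot(is.numeric(J0), is.numeric(J1), is.numeric(J2),
            length(J0) == 1, length(J1) == 1, length(J2) == 1)
  if (J2 < 0 || J1 < J2 || J0 < J1)
    stop("spectral densities must satisfy J0 >= J1 >= J2 >= 0")
  if (fQ_hz < 0) stop("fQ_hz must be >= 0")
  structure(
    list(name = name, J0 = J0, J1 = J1, J2 = J2, fQ_hz = fQ_hz,
         fQ_model = fQ_model, fQ_n_orient = as.integer(fQ_n_orient)),
    class = "na_environment"
  )
}

#' @export
print.na_environment <- function(x, ...) {
  r <- redfield_rates(x)
  cat(sprintf(
    "<na_environment '%s'>  J0=%g J1=%g J2=%g s^-1, fQ=%g Hz (%s)\n",
    x$name, x$J0, x$J1, x$J2, x$fQ_hz, x$fQ_model))
  cat(sprintf(
    "  T2fast=%.2f ms (60%%)  T2slow=%.2f ms (40%%)  T1fast=%.2f ms (20%%)  T1slow=%.2f ms (80%%)\n",
    1000 / r$R2f, 1000 / r$R2s, 1000 / r$R1f, 1000 / r$R1s))
  invisible(x)
}

#' Relaxation rates of a spin-3/2 environment
#'
#' Standard Redfield result for quadrupolar relaxation of spin 3/2: the
#' transverse decay is biexponential with rates `R2f = J0 + J1` (satellite
#' transitions, amplitude 0.6) and `R2s = J1 + J2` (central transition,
#' amplitude 0.4); the longitudinal recovery is biexponential with rates
#' `R1f = 2*J1` (amplitude 0.2) and `R1s = 2*J2` (amplitude 0.8).
#'
#' @param env an [na_environment()]
#' @return list with `R2f`, `R2s`, `R1f`, `R1s` (s^-1) and the fixed
#'   component fractions `a2f = 0.6`, `a2s = 0.4`, `a1f = 0.2`, `a1s = 0.8`
#' @export
redfield_rates <- function(env) {
  stopifnot(inherits(env, "na_environment"))
  list(R2f = env$J0 + env$J1, R2s = env$J1 + env$J2,
       R1f = 2 * env$J1, R1s = 2 * env$J2,
       a2f = 0.6, a2s = 0.4, a1f = 0.2, a1s = 0.8)
}

# Redfield relaxation superoperator: sum over m of J_|m| [T2m, [T2m^H, . ]]
# With unit-norm tensor operators this convention reproduces the rates of
# redfield_rates() exactly (verified by the biexponential-fraction tests).
.redfield_superop <- function(J0, J1, J2) {
  basis <- tensor_basis()
  key <- paste0("redfield_unit")
  if (is.null(.spin32_cache[[key]])) {
    parts <- lapply(0:2, function(am) {
      idx <- which(basis$lm$l == 2 & abs(basis$lm$m) == am)
      Reduce(`+`, lapply(idx, function(j) {
        A <- basis$ops[[j]]
        Ah <- Conj(t(A))
        .superop(function(X) A %*% (Ah %*% X - X %*% Ah) -
                   (Ah %*% X - X %*% Ah) %*% A, basis)
      }))
    })
    .spin32_cache[[key]] <- parts
  }
  parts <- .spin32_cache[[key]]
  J0 * parts[[1]] + J1 * parts[[2]] + J2 * parts[[3]]
}

# Hamiltonian superoperators (commutator maps), cached as unit templates.
.hamiltonian_superops <- function() {
  if (!is.null(.spin32_cache$hsup)) return(.spin32_cache$hsup)
  sp <- spin32_operators()
  basis <- tensor_basis()
  HQ <- (3 * sp$Iz %*% sp$Iz - (15 / 4) * diag(4)) / 6  # unit-splitting form
  hsup <- list(
    Lx = .superop(function(X) -1i * .comm(sp$Ix, X), basis),
    Ly = .superop(function(X) -1i * .comm(sp$Iy, X), basis),
    LQ = .superop(function(X) -1i * .comm(HQ, X), basis)
  )
  .spin32_cache$hsup <- hsup
  hsup
}

#' Build the evolution generator for one sodium environment
#'
#' Assembles the 15 x 15 complex generator `L` of the coefficient dynamics
#' `dc/dt = L c + b`, combining RF nutation at amplitude `rf_amplitude_hz`
#' (nutation frequency, Hz) and phase `rf_phase` (degrees), the residual
#' quadrupole splitting `2*pi*fQ`, and Redfield relaxation toward thermal
#' equilibrium (`b` is the equilibrium recovery drive).  Units are s^-1.
#'
#' @param env an [na_environment()]
#' @param rf_amplitude_hz RF nutation frequency in Hz (0 for free evolution)
#' @param rf_phase RF phase in degrees
#' @param fQ_hz_override residual splitting in Hz; defaults to `env$fQ_hz`
#'   (used internally for powder averaging)
#' @param m0 equilibrium longitudinal amplitude (coefficient of T_10)
#' @return list with `L` (15 x 15 complex) and `b` (length-15 complex drive)
#' @export
build_generator <- function(env, rf_amplitude_hz = 0, rf_phase = 0,
                            fQ_hz_override = NULL, m0 = 1) {
  stopifnot(inherits(env, "na_environment"))
  fq <- if (is.null(fQ_hz_override)) env$fQ_hz else fQ_hz_override
  h <- .hamiltonian_superops()
  w1 <- 2 * pi * rf_amplitude_hz
  ph <- rf_phase * pi / 180
  L <- w1 * (cos(ph) * h$Lx + sin(ph) * h$Ly) + (2 * pi * fq) * h$LQ -
    .redfield_superop(env$J0, env$J1, env$J2)
  ceq <- equilibrium_state(m0)$coeffs
  b <- .redfield_superop(env$J0, env$J1, env$J2) %*% ceq
  list(L = L, b = as.vector(b))
}
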