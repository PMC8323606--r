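# Spin states, pulse events, sequence presets and the steady-state
# relaxation-weighting computation.

#' Spin-3/2 state on the irreducible tensor basis
#'
#' @param coeffs complex vector of 15 coefficients, ordered (l, m) with
#'   l = 1..3 and m = -l..l within each l
#' @param m0 equilibrium longitudinal amplitude
#' @return object of class `na_spin_state`
#' @export
spin_state <- function(coeffs, m0 = 1) {
  stopifnot(length(coeffs) == 15)
  structure(list(coeffs = as.complex(coeffs), m0 = m0),
            class = "na_spin_state")
}

#' Thermal equilibrium state (only T_10 populated)
#' @param m0 equilibrium longitudinal amplitude
#' @return an `na_spin_state`
#' @export
equilibrium_state <- function(m0 = 1) {
  coeffs <- complex(15)
  coeffs[tensor_basis()$index(1, 0)] <- m0
  spin_state(coeffs, m0 = m0)
}

#' Hermiticity defect of a spin state
#'
#' A physical density operator requires c_{l,-m} = (-1)^m Conj(c_{l,m});
#' returns the maximum absolute violation.
#' @param state an `na_spin_state`
#' @return numeric scalar
#' @export
hermiticity_defect <- function(state) {
  lm <- tensor_basis()$lm
  idx <- tensor_basis()$index
  d <- 0
  for (k in seq_len(nrow(lm))) {
    l <- lm$l[k]; m <- lm$m[k]
    d <- max(d, abs(state$coeffs[idx(l, -m)] -
                      (-1)^m * Conj(state$coeffs[idx(l, m)])))
  }
  d
}

#' Transverse observable of a spin state
#'
#' The detected single-quantum signal, `sqrt(2) * c_{1,-1}` (complex), scaled
#' so an ideal 90 degree pulse on equilibrium gives magnitude `m0`.
#' @param state an `na_spin_state`
#' @return complex scalar
#' @export
observable_signal <- function(state) {
  sqrt(2) * state$coeffs[tensor_basis()$index(1, -1)]
}

#' RF pulse description
#'
#' @param flip_nominal nominal flip angle in degrees (0 < flip <= 360)
#' @param tau_rf_ms pulse duration in ms; `0` denotes an ideal
#'   (instantaneous) rotation
#' @param phase_deg RF phase in degrees
#' @param shape pulse shape; only `"rect"` is supported
#' @return object of class `na_pulse`
#' @export
pulse_event <- function(flip_nominal, tau_rf_ms, phase_deg = 0,
                        shape = "rect") {
  stopifnot(shape == "rect")
  if (!(flip_nominal > 0 && flip_nominal <= 360))
    stop("flip_nominal must be in (0, 360]")
  if (tau_rf_ms < 0) stop("tau_rf_ms must be >= 0")
  structure(list(flip_nominal = flip_nominal, tau_rf_ms = tau_rf_ms,
                 phase_deg = phase_deg, shape = shape),
            class = "na_pulse")
}

#' Pulse sequence description
#'
#' Timing convention: `TI_ms` runs from the end of the inversion pulse to the
#' start of the excitation pulse; `TE_ms` runs from the center of the
#' excitation pulse to signal readout.
#'
#' @param name sequence label
#' @param excitation an [pulse_event()]
#' @param TE_ms echo time in ms (from excitation pulse center)
#' @param TR_ms repetition time in ms
#' @param inversion optional inversion [pulse_event()]
#' @param TI_ms inversion time in ms (end of inversion to start of
#'   excitation); required with `inversion`
#' @return object of class `na_sequence`
#' @export
sequence_spec <- function(name, excitation, TE_ms, TR_ms,
                          inversion = NULL, TI_ms = NULL) {
  stopifnot(inherits(excitation, "na_pulse"))
  if (!is.null(inversion)) {
    stopifnot(inherits(inversion, "na_pulse"), !is.null(TI_ms))
    if (TI_ms >= TR_ms) stop("TI_ms must be < TR_ms")
  }
  if (TE_ms >= TR_ms) stop("TE_ms must be < TR_ms")
  if (TE_ms < excitation$tau_rf_ms / 2)
    stop("TE_ms is measured from the excitation pulse center and cannot ",
         "precede the end of the pulse")
  prep <- if (is.null(inversion)) 0 else inversion$tau_rf_ms + TI_ms
  if (prep + excitation$tau_rf_ms / 2 + TE_ms >= TR_ms)
    stop("sequence timing does not fit within TR")
  structure(list(name = name, inversion = inversion, TI_ms = TI_ms,
                 excitation = excitation, TE_ms = TE_ms, TR_ms = TR_ms),
            class = "na_sequence")
}

#' Preset sodium sequences
#'
#' The three acquisitions modeled: density-weighted `NaDW` (30 deg, 0.11 ms
#' pulse, TE 0.11 ms, TR 85 ms), coherent-magnetization `NaPACMAN` (110 deg,
#' 4.0 ms pulse, TE 2.5 ms, TR 25 ms), and soft inversion recovery
#' fluid-attenuated `NaSIRFLA` (180 deg soft inversion of 5.0 ms, TI 37 ms,
#' 64 deg excitation of 0.32 ms, TE 0.22 ms, TR 150 ms).
#'
#' @return named list of [sequence_spec()] objects
#' @export
#' @examples
#' names(sequence_presets())
sequence_presets <- function() {
  list(
    NaDW = sequence_spec(
      "NaDW", pulse_event(30, 0.11), TE_ms = 0.11, TR_ms = 85),
    NaPACMAN = sequence_spec(
      "NaPACMAN", pulse_event(110, 4.0), TE_ms = 2.5, TR_ms = 25),
    NaSIRFLA = sequence_spec(
      "NaSIRFLA", pulse_event(64, 0.32), TE_ms = 0.22, TR_ms = 150,
      inversion = pulse_event(180, 5.0), TI_ms = 37)
  )
}

# Affine propagator over `dur_s` seconds with constant generator (L, b):
# returns 16x16 augmented matrix acting on c(coeffs, 1).
.propagator <- function(gen, dur_s) {
  M <- matrix(0i, 16, 16)
  M[1:15, 1:15] <- gen$L * dur_s
  M[1:15, 16] <- gen$b * dur_s
  expm_complex(M)
}

# Ideal (instantaneous) rotation superoperator for flip theta (rad), phase
# phi (rad): exp(theta * (cos(phi) Lx + sin(phi) Ly)) on the 15 coefficients.
.ideal_rotation <- function(theta_rad, phase_rad = 0) {
  h <- .hamiltonian_superops()
  expm_complex(theta_rad * (cos(phase_rad) * h$Lx + sin(phase_rad) * h$Ly))
}

#' Evolve a spin state through an RF pulse or free evolution
#'
#' Propagates the state by the matrix exponential of the full generator
#' (RF nutation + residual quadrupole splitting + Redfield relaxation with
#' equilibrium recovery).  For a rect pulse the generator is constant over
#' the pulse, so a single exact exponential is used.  A pulse with
#' `tau_rf_ms = 0` is applied as an ideal instantaneous rotation.
#'
#' @param state an `na_spin_state`
#' @param env an [na_environment()]
#' @param rf optional [pulse_event()] applied during the evolution
#' @param duration_ms free-evolution duration in ms (ignored when `rf` is
#'   given with `tau_rf_ms > 0`, where the pulse duration is used)
#' @return the evolved `na_spin_state`
#' @export
evolve <- function(state, env, rf = NULL, duration_ms = 0) {
  stopifnot(inherits(state, "na_spin_state"), inherits(env, "na_environment"))
  if (duration_ms < 0) stop("duration_ms must be >= 0")
  c0 <- state$coeffs
  if (!is.null(rf) && rf$tau_rf_ms == 0) {
    R <- .ideal_rotation(rf$flip_nominal * pi / 180, rf$phase_deg * pi / 180)
    return(spin_state(as.vector(R %*% c0), m0 = state$m0))
  }
  if (is.null(rf)) {
    if (duration_ms == 0) return(state)
    gen <- build_generator(env, 0, 0, m0 = state$m0)
    dur <- duration_ms
  } else {
    amp_hz <- rf$flip_nominal / 360 / (rf$tau_rf_ms / 1000)
    gen <- build_generator(env, amp_hz, rf$phase_deg, m0 = state$m0)
    dur <- rf$tau_rf_ms
  }
  P <- .propagator(gen, dur / 1000)
  out <- P %*% c(c0, 1 + 0i)
  spin_state(out[1:15], m0 = state$m0)
}

# Build the per-TR propagators for one sequence and environment at a fixed
# residual splitting.  Returns list(P_pre, P_post, spoil) where
#   c_TE   = P_pre  %*% c(c_start, 1)
#   c_next = spoil( P_post %*% c(c_TE, 1) )
.tr_block <- function(seq, env, fq_hz, m0 = 1) {
  gen_free <- build_generator(env, 0, 0, fQ_hz_override = fq_hz, m0 = m0)
  pulse_prop <- function(p) {
    if (p$tau_rf_ms == 0) {
      R <- matrix(0i, 16, 16)
      R[1:15, 1:15] <- .ideal_rotation(p$flip_nominal * pi / 180,
                                       p$phase_deg * pi / 180)
      R[16, 16] <- 1
      return(R)
    }
    amp_hz <- p$flip_nominal / 360 / (p$tau_rf_ms / 1000)
    gen <- build_generator(env, amp_hz, p$phase_deg,
                           fQ_hz_override = fq_hz, m0 = m0)
    .propagator(gen, p$tau_rf_ms / 1000)
  }
  exc <- seq$excitation
  t_post_exc <- seq$TE_ms - exc$tau_rf_ms / 2   # pulse center -> readout
  P_pre <- .propagator(gen_free, t_post_exc / 1000) %*% pulse_prop(exc)
  t_used <- exc$tau_rf_ms + t_post_exc
  if (!is.null(seq$inversion)) {
    P_pre <- P_pre %*% .propagator(gen_free, seq$TI_ms / 1000) %*%
      pulse_prop(seq$inversion)
    t_used <- t_used + seq$inversion$tau_rf_ms + seq$TI_ms
  }
  P_post <- .propagator(gen_free, (seq$TR_ms - t_used) / 1000)
  # ideal spoiling keeps only the longitudinal (m = 0) coefficients
  keep <- c(tensor_basis()$index(1, 0), tensor_basis()$index(2, 0),
            tensor_basis()$index(3, 0), 16L)
  S <- matrix(0i, 16, 16)
  S[cbind(keep, keep)] <- 1
  list(P_pre = P_pre, P_cycle = S %*% P_post %*% P_pre)
}

.steady_signal_single <- function(seq, env, fq_hz, m0, tol, max_tr) {
  blk <- .tr_block(seq, env, fq_hz, m0)
  i_obs <- tensor_basis()$index(1, -1)
  x <- c(equilibrium_state(m0)$coeffs, 1 + 0i)
  s_prev <- NA_complex_
  for (n in seq_len(max_tr)) {
    s <- sqrt(2) * (blk$P_pre %*% x)[i_obs]
    if (!is.na(s_prev) && abs(s - s_prev) < tol * m0) return(s)
    s_prev <- s
    x <- blk$P_cycle %*% x
  }
  stop("steady state not reached after ", max_tr, " TRs")
}

#' Steady-state signal of a sequence on one environment
#'
#' Repeats the TR block (with ideal spoiling of all transverse and
#' multiple-quantum coherences at the end of each TR) from thermal
#' equilibrium until the complex readout at TE changes by less than
#' `tol * m0` between consecutive repetitions, and returns the converged
#' complex observable.  For a powder-average environment the signal is the
#' quadrature-weighted mean over orientations with splitting
#' `fQ * (3 cos^2(beta) - 1) / 2`.
#'
#' @param seq an [sequence_spec()]
#' @param env an [na_environment()]
#' @param m0 equilibrium amplitude
#' @param tol convergence tolerance (relative to `m0`)
#' @param max_tr maximum number of TR repetitions before erroring
#' @return complex signal at TE
#' @export
steady_state_signal <- function(seq, env, m0 = 1, tol = 1e-9,
                                max_tr = 10000L) {
  stopifnot(inherits(seq, "na_sequence"), inherits(env, "na_environment"))
  if (env$fQ_hz == 0 || env$fQ_model == "single-value")
    return(.steady_signal_single(seq, env, env$fQ_hz, m0, tol, max_tr))
  gq <- .gauss_legendre(env$fQ_n_orient)       # nodes on [0, 1] = cos(beta)
  s <- 0 + 0i
  for (k in seq_along(gq$x)) {
    fq <- env$fQ_hz * (3 * gq$x[k]^2 - 1) / 2
    s <- s + gq$w[k] *
      .steady_signal_single(seq, env, abs(fq), m0, tol, max_tr)
  }
  s
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch via symmetric
# tridiagonal eigendecomposition).
.gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1)] <- beta
  Jm[cbind(k + 1, k)] <- beta
  e <- eigen(Jm, symmetric = TRUE)
  x <- e$values                     # on [-1, 1]
  w <- 2 * e$vectors[1, ]^2
  list(x = (x + 1) / 2, w = w / 2)  # mapped to [0, 1], weights sum to 1
}

#' Relaxation weighting of a sequence on one environment
#'
#' The steady-state signal magnitude at TE divided by `m0 * sin(flip)` of
#' the excitation pulse, i.e. relative to an idealized instantaneous
#' excitation of fully relaxed magnetization with no relaxation loss.  A
#' relaxation-free environment therefore has weighting 1 for any sequence
#' without inversion.
#'
#' @inheritParams steady_state_signal
#' @return dimensionless scalar in [0, ~1]
#' @export
#' @examples
#' envs <- default_environments()
#' relaxation_weighting(sequence_presets()$NaDW, envs$intra)
relaxation_weighting <- function(seq, env, m0 = 1) {
  s <- steady_state_signal(seq, env, m0 = m0)
  abs(s) / (m0 * sin(seq$excitation$flip_nominal * pi / 180))
}

#' Relaxation weighting table for sets of sequences and environments
#'
#' @param seqs named list of sequences (default [sequence_presets()])
#' @param envs named list of environments (default [default_environments()])
#' @return matrix `RW[sequence, environment]`
#' @export
relaxation_weighting_table <- function(seqs = sequence_presets(),
                                       envs = default_environments()) {
  rw <- matrix(NA_real_, length(seqs), length(envs),
               dimnames = list(names(seqs), names(envs)))
  for (s in names(seqs)) for (e in names(envs))
    rw[s, e] <- relaxation_weighting(seqs[[s]], envs[[e]])
  rw
}
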