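# Spin-3/2 simulator: rates, generator, evolution, steady state.

test_that("Redfield rates follow the spin-3/2 spectral-density formulas", {
  iso <- redfield_rates(na_environment("iso", 50, 50, 50))
  expect_equal(iso$R2f, 100)
  expect_equal(iso$R2s, 100)
  expect_equal(iso$R1f, 100)
  expect_equal(iso$R1s, 100)

  r <- redfield_rates(na_environment("x", 560, 60, 40))
  expect_equal(r$R2f, 620)
  expect_equal(r$R2s, 100)
  expect_equal(r$R1f, 120)
  expect_equal(r$R1s, 80)
  expect_equal(r$a2f + r$a2s, 1)
  expect_equal(r$a1f + r$a1s, 1)

  expect_error(na_environment("bad", 50, 60, 10), "J0 >= J1")
  expect_error(na_environment("bad", 50, 10, 20), "J0 >= J1")
  expect_error(na_environment("bad", 50, 10, -1), "J0 >= J1")
})

test_that("free evolution from the generator matches an independent ODE
           integration for random environments", {
  set.seed(42)
  for (rep in 1:4) {
    J2 <- runif(1, 1, 40); J1 <- J2 + runif(1, 0, 150)
    J0 <- J1 + runif(1, 0, 400); fq <- sample(c(0, runif(1, 0, 400)), 1)
    env <- na_environment("rnd", J0, J1, J2, fQ_hz = fq)
    st <- evolve(equilibrium_state(), env, rf = pulse_event(90, 0))
    gen <- build_generator(env, 0, 0)
    t_ms <- 3
    ode <- rk4_propagate(gen$L, gen$b, st$coeffs, t_ms / 1000)
    ex <- evolve(st, env, duration_ms = t_ms)$coeffs
    expect_lt(max(abs(ex - ode)) / max(abs(ex)), 1e-8)
  }
})

test_that("generator is dissipative and reproduces the observable rates", {
  env <- na_environment("t", 300, 40, 15)
  gen <- build_generator(env, 0, 0)
  expect_lte(max(Re(eigen(gen$L, only.values = TRUE)$values)), 1e-10)
  # all-zero J and no RF: generator vanishes
  gen0 <- build_generator(na_environment("z", 0, 0, 0), 0, 0)
  expect_equal(max(abs(gen0$L)), 0)
  expect_equal(max(abs(gen0$b)), 0)
})

test_that("transverse decay is biexponential with 60/40 amplitudes and
           rates J0+J1 / J1+J2", {
  env <- na_environment("t", 560, 60, 40)
  st <- evolve(equilibrium_state(), env, rf = pulse_event(90, 0))
  ts <- seq(0, 25, length.out = 40)  # ms
  fid <- vapply(ts, function(t)
    abs(observable_signal(evolve(st, env, duration_ms = t))), numeric(1))
  A <- cbind(exp(-620 * ts / 1000), exp(-100 * ts / 1000))
  amp <- qr.solve(A, fid)
  expect_equal(unname(amp), c(0.6, 0.4), tolerance = 1e-6)
  expect_lt(max(abs(A %*% amp - fid)), 1e-9)
})

test_that("longitudinal recovery is biexponential with 20/80 amplitudes and
           rates 2J1 / 2J2", {
  env <- na_environment("t", 560, 60, 40)
  sat <- spin_state(complex(15))
  i10 <- naContrast:::tensor_basis()$index(1, 0)
  ts <- seq(0.5, 40, length.out = 40)
  rec <- vapply(ts, function(t)
    Re(evolve(sat, env, duration_ms = t)$coeffs[i10]), numeric(1))
  A <- cbind(exp(-120 * ts / 1000), exp(-80 * ts / 1000))
  amp <- qr.solve(A, 1 - rec)
  expect_equal(unname(amp), c(0.2, 0.8), tolerance = 1e-6)
})

test_that("evolution preserves Hermiticity and duration 0 is the identity", {
  env <- na_environment("t", 400, 80, 20, fQ_hz = 150)
  st <- evolve(equilibrium_state(), env, rf = pulse_event(64, 0.32))
  expect_identical(evolve(st, env, duration_ms = 0)$coeffs, st$coeffs)
  st2 <- evolve(st, env, duration_ms = 7.3)
  expect_lt(hermiticity_defect(st2), 1e-10)
})

test_that("ideal pulses nutate equilibrium by sin(theta)", {
  env <- na_environment("t", 0, 0, 0)
  for (th in c(30, 64, 90, 110)) {
    st <- evolve(equilibrium_state(), env, rf = pulse_event(th, 0))
    expect_equal(abs(observable_signal(st)), abs(sin(th * pi / 180)),
                 tolerance = 1e-12)
    expect_lt(hermiticity_defect(st), 1e-12)
  }
})

test_that("quadrupole beat after an ideal 90 splits 60/40 between satellite
           and central coherences", {
  env <- na_environment("q", 0, 0, 0, fQ_hz = 250)
  st <- evolve(equilibrium_state(), env, rf = pulse_event(90, 0))
  ts <- seq(0, 8, length.out = 33)
  fid <- vapply(ts, function(t)
    abs(observable_signal(evolve(st, env, duration_ms = t))), numeric(1))
  expect_equal(fid, abs(0.6 * cos(2 * pi * 250 * ts / 1000) + 0.4),
               tolerance = 1e-6)
})

test_that("steady state matches the closed-form spoiled saturation formula
           for mono-exponential environments with ideal pulses", {
  for (J in c(10, 25)) for (th in c(30, 64, 90)) {
    env <- na_environment("m", J, J, J)
    sq <- sequence_spec("t", pulse_event(th, 0), TE_ms = 1e-9, TR_ms = 30)
    expect_equal(abs(steady_state_signal(sq, env)),
                 saturation_formula(th, 30, 2 * J), tolerance = 1e-6)
  }
  # fully relaxed limit
  env <- na_environment("m", 20, 20, 20)
  sq <- sequence_spec("t", pulse_event(90, 0), TE_ms = 1e-9, TR_ms = 1500)
  expect_equal(abs(steady_state_signal(sq, env)), 1, tolerance = 1e-6)
})

test_that("inversion recovery nulls a mono-exponential fluid at the TI
           derived from the closed-form steady state", {
  J <- 9; R1 <- 2 * J; TR <- 150
  E_TR <- exp(-R1 * TR / 1000)
  TI <- -log((1 + E_TR) / 2) / R1 * 1000  # 1 - 2 E1 + E_TR = 0
  env <- na_environment("fluid", J, J, J)
  sq <- sequence_spec("sirfla-ideal", pulse_event(64, 0), TE_ms = 1e-9,
                      TR_ms = TR, inversion = pulse_event(180, 0),
                      TI_ms = TI)
  expect_lt(abs(steady_state_signal(sq, env)), 1e-7)
})

test_that("sequence presets carry the acquisition parameters", {
  ps <- sequence_presets()
  expect_named(ps, c("NaDW", "NaPACMAN", "NaSIRFLA"))
  expect_equal(ps$NaDW$TR_ms, 85)
  expect_equal(ps$NaDW$excitation$flip_nominal, 30)
  expect_equal(ps$NaDW$excitation$tau_rf_ms, 0.11)
  expect_equal(ps$NaPACMAN$excitation$flip_nominal, 110)
  expect_equal(ps$NaPACMAN$TE_ms, 2.5)
  expect_equal(ps$NaSIRFLA$TI_ms, 37)
  expect_equal(ps$NaSIRFLA$inversion$tau_rf_ms, 5.0)
  for (p in ps) expect_lt(p$TE_ms, p$TR_ms)
})

test_that("density-weighted relaxation weighting is non-increasing in J0", {
  sq <- sequence_presets()$NaDW
  rws <- vapply(c(150, 400, 900, 2000), function(J0)
    relaxation_weighting(sq, na_environment("s", J0, 60, 40)), numeric(1))
  expect_true(all(diff(rws) <= 1e-12))
})

test_that("powder averaging reduces the effective splitting relative to the
           single-value model", {
  sq <- sequence_presets()$NaDW
  single <- relaxation_weighting(sq, na_environment("m", 600, 40, 20,
                                                    fQ_hz = 400))
  powder <- relaxation_weighting(
    sq, na_environment("m", 600, 40, 20, fQ_hz = 400,
                       fQ_model = "powder-average", fQ_n_orient = 16))
  expect_true(is.finite(powder))
  expect_gt(powder, single)  # most orientations see a smaller splitting
  # zero splitting: both models agree
  e0 <- na_environment("m", 600, 40, 20, fQ_hz = 0,
                       fQ_model = "powder-average", fQ_n_orient = 8)
  expect_equal(relaxation_weighting(sq, e0),
               relaxation_weighting(sq, na_environment("m", 600, 40, 20)),
               tolerance = 1e-10)
})

test_that("environment configs round-trip through YAML", {
  envs <- default_environments()
  expect_named(envs, c("intra", "extra", "myelin", "edema", "csf", "agar"))
  expect_equal(envs$intra$J0, envs$extra$J0)
  expect_gt(envs$myelin$fQ_hz, 0)
  tmp <- tempfile(fileext = ".yaml")
  write_environments(envs, tmp)
  back <- read_environments(tmp)
  expect_equal(back$myelin$J0, envs$myelin$J0)
  expect_equal(back$myelin$fQ_hz, envs$myelin$fQ_hz)
})
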