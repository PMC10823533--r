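test_that("ensembles are bitwise reproducible given the seed", {
  m <- study_model(delta = 10^-0.5)
  spec <- ensemble_spec("FSSH", n_traj = 300, t_max = 5, seed = 17)
  a <- run_ensemble(spec, m)
  b <- run_ensemble(spec, m)
  expect_identical(a$p_mean, b$p_mean)
  expect_identical(a$strata, b$strata)
  expect_identical(a$counts, b$counts)
})

test_that("a single-trajectory ensemble equals that trajectory's projector", {
  # gamma = 0 MASH consumes random numbers only in the initial sampling, so
  # the ensemble member and the standalone trajectory coincide exactly
  m <- study_model(delta = 10^-0.5, gamma = 0)
  spec <- ensemble_spec("MASH", n_traj = 1, t_max = 5, seed = 31)
  cv <- run_ensemble(spec, m)
  init <- hoprates:::cpp_sample_initial(hoprates:::model_param_vector(m),
                                        1L, 0L, TRUE, 31)
  tr <- run_trajectory(init, spec, m, traj_index = 0)
  expect_equal(cv$p_mean,
               as.numeric(product_projector(tr$Q, tr$n, m)))
})

test_that("engine matches the pure-R amplitude-based reference (MASH, gamma=0)", {
  m <- study_model(delta = 10^-0.5, gamma = 0)
  # energetic start left of the crossing so the trajectory crosses and hops
  init <- list(Q = 2, P = 3.0, n = -1, Sx = 0.6, Sy = 0, Sz = -0.8)
  spec <- ensemble_spec("MASH", n_traj = 1, dt = 0.005, t_max = 6,
                        sample_stride = 10, seed = 1)
  tr <- run_trajectory(init, spec, m)
  ref <- reference_mash_trajectory(m, init$Q, init$P, init$n,
                                   c(init$Sx, init$Sy, init$Sz),
                                   dt = 0.005, nsteps = 1200, stride = 10)
  expect_gt(attr(tr, "hops_total"), 0)       # exercised the hop machinery
  expect_equal(tr$hops[nrow(tr)], ref$hops[nrow(ref)])
  expect_equal(tr$Q, ref$Q, tolerance = 1e-7)
  expect_equal(tr$P, ref$P, tolerance = 1e-7)
  expect_equal(tr$Sz, ref$Sz, tolerance = 1e-7)
  expect_equal(tr$n, as.integer(ref$n))
})

test_that("gamma = 0 dynamics conserve energy, including across hops", {
  # smooth adiabat, no hops: secular drift below 1e-6 over 1e5 steps
  m <- study_model(delta = 2, gamma = 0)
  spec <- ensemble_spec("MASH", dt = 0.01, t_max = 1000, sample_stride = 100,
                        seed = 2)
  tr <- run_trajectory(list(Q = 1.5, P = 0.5, n = -1), spec, m)
  E <- trace_energy(tr, m)
  expect_equal(attr(tr, "hops_total"), 0)
  drift <- unname(coef(lm(E ~ tr$t))[2]) * max(tr$t)
  expect_lt(abs(drift), 1e-6)
  expect_lt(max(abs(E - E[1])), 1e-4)        # bounded shadow oscillation
  # weak coupling with hops: global conservation at fine dt
  mw <- study_model(gamma = 0)
  specw <- ensemble_spec("MASH", dt = 5e-4, t_max = 50, sample_stride = 20,
                         seed = 3)
  init <- list(Q = 9, P = 1.2, n = -1, Sx = 0.3, Sy = 0.1,
               Sz = -sqrt(1 - 0.1))
  trw <- run_trajectory(init, specw, mw)
  expect_gt(attr(trw, "hops_total"), 0)
  Ew <- trace_energy(trw, mw)
  expect_lt(max(abs(Ew - Ew[1])), 1e-5)
})

test_that("frustrated hops reflect the momentum and do not count as hops", {
  # start moving up the lower surface with too little energy to hop up:
  # MASH flips Sz at the crossing, the upward attempt is frustrated
  m <- study_model(delta = 0.3, gamma = 0)    # gap 0.6 at the crossing
  spec <- ensemble_spec("MASH", dt = 0.002, t_max = 16, sample_stride = 1,
                        seed = 4)
  init <- list(Q = crossing_point(m) - 3.5, P = 1.8, n = -1)
  tr <- run_trajectory(init, spec, m)
  expect_gt(attr(tr, "frustrated_total"), 0)
  i <- which(diff(tr$frustrated) > 0)[1]      # first frustrated step
  expect_equal(tr$P[i + 1], -tr$P[i], tolerance = 0.05)
  expect_equal(tr$n[i + 1], tr$n[i])          # active state unchanged
  expect_equal(tr$hops[i + 1], tr$hops[i])    # not counted as a hop
})

test_that("MASH keeps n = sign(Sz) on frustration-free trajectories", {
  m <- study_model(delta = 10^-0.5)
  found <- FALSE
  for (seed in 1:60) {
    spec <- ensemble_spec("MASH", n_traj = 1, t_max = 20, sample_stride = 5,
                          seed = seed)
    init <- hoprates:::cpp_sample_initial(hoprates:::model_param_vector(m),
                                          1L, 0L, TRUE, seed)
    tr <- run_trajectory(init, spec, m, traj_index = 0)
    if (attr(tr, "frustrated_total") == 0 && attr(tr, "hops_total") > 0) {
      found <- TRUE
      expect_true(all(tr$n == sign(tr$Sz)))
    }
  }
  expect_true(found)
})

test_that("the Bloch norm stays on the unit sphere over long runs", {
  m <- study_model()
  spec <- ensemble_spec("MASH", dt = 0.01, t_max = 1000, sample_stride = 1000,
                        seed = 6)   # 1e5 steps
  init <- list(Q = 0, P = 1, n = -1, Sx = 0.48, Sy = -0.6,
               Sz = -sqrt(1 - 0.48^2 - 0.6^2))
  tr <- run_trajectory(init, spec, m)
  nrm <- sqrt(tr$Sx^2 + tr$Sy^2 + tr$Sz^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)
})

test_that("Langevin ensemble preserves the Boltzmann distribution", {
  m <- study_model()
  N <- 4000
  spec <- ensemble_spec("MASH", n_traj = N, t_max = 20, seed = 9)
  cv <- run_ensemble(spec, m, return_final = TRUE)
  fin <- cv$final
  # equipartition of momentum
  expect_within_se(mean(fin$P^2), 1 / m$beta, sqrt(2 / N))
  # position second moment on the lower branch vs Boltzmann quadrature
  Qx <- crossing_point(m)
  zm <- integrate(function(q) exp(-adiabatic_surfaces(q, m)$V_minus),
                  -Inf, Qx, rel.tol = 1e-10)$value
  q2 <- integrate(function(q) q^2 * exp(-adiabatic_surfaces(q, m)$V_minus),
                  -Inf, Qx, rel.tol = 1e-10)$value / zm
  sel <- fin$n == -1 & fin$Q < Qx
  expect_within_se(mean(fin$Q[sel]^2), q2,
                   sd(fin$Q[sel]^2) / sqrt(sum(sel)))
})

test_that("fewest-switches bookkeeping matches the underlying TDSE", {
  # drive the nuclear coordinate slowly through the crossing on a fixed
  # path; the deterministic master equation built from the per-step hop
  # probabilities must reproduce the adiabatic populations of the TDSE
  m <- study_model(delta = 10^-0.5)
  v <- 0.5   # Landau-Zener exponent ~1: a third of the population transfers
  dt <- 0.005
  nsteps <- round(16 / v / dt)
  Qx <- crossing_point(m)
  st <- electronic_state(0, 1)      # start purely on the lower adiabat
  f <- c(plus = 0, minus = 1)       # surface fractions under the master eq.
  Q <- Qx - 8
  for (k in seq_len(nsteps)) {
    Qmid <- Q + 0.5 * v * dt
    gap <- adiabatic_surfaces(Qmid, m)$gap
    d <- nonadiabatic_coupling(Qmid, m)
    st <- propagate_electronic(st, gap, d, v, dt)
    S <- unname(bloch_from_amplitudes(st))
    g_pm <- suppressWarnings(fssh_hop_probability(S, +1, v, d, dt))
    g_mp <- suppressWarnings(fssh_hop_probability(S, -1, v, d, dt))
    f <- c(plus = unname(f["plus"] * (1 - g_pm) + f["minus"] * g_mp),
           minus = unname(f["minus"] * (1 - g_mp) + f["plus"] * g_pm))
    Q <- Q + v * dt
  }
  S <- unname(bloch_from_amplitudes(st))
  expect_equal(unname(f["minus"]), (1 - S[3]) / 2, tolerance = 0.02)
  expect_gt(f["plus"], 0.01)   # a nontrivial amount actually transferred
  # no coupling means no hop; flux into the active state means no hop
  expect_equal(fssh_hop_probability(c(0.6, 0, 0.8), 1, 1.3, 0, 0.01), 0)
  expect_equal(fssh_hop_probability(c(-0.6, 0, 0.8), 1, 1.3, 2.5, 0.01), 0)
  expect_gt(fssh_hop_probability(c(0.6, 0, 0.8), 1, 1.3, 2.5, 0.01), 0)
})

test_that("decoherence corrections trigger on the gap and count events", {
  m <- study_model(eps = 12)
  spec_on <- ensemble_spec("MASH", n_traj = 500, t_max = 10, seed = 12,
                           decoherence = "gap_triggered")
  cv <- run_ensemble(spec_on, m)
  expect_gt(cv$counts$decoherence, 0)
  off <- run_ensemble(ensemble_spec("MASH", n_traj = 500, t_max = 10,
                                    seed = 12), m)
  expect_equal(off$counts$decoherence, 0)
  # FSSH collapse also counts
  cf <- run_ensemble(ensemble_spec("FSSH", n_traj = 200, t_max = 5, seed = 13,
                                   decoherence = "gap_triggered"), m)
  expect_gt(cf$counts$decoherence, 0)
})

test_that("apply_decoherence implements resampling and collapse", {
  set.seed(20)
  draws <- t(replicate(20000, apply_decoherence(c(0.1, 0.1,
                                                  sqrt(0.98)), 1, "MASH")))
  expect_true(all(draws[, 3] > 0))
  expect_equal(rowSums(draws^2), rep(1, nrow(draws)), tolerance = 1e-10)
  # |Sz| density prop. to |Sz|: mean 2/3 (idempotent in law)
  expect_within_se(mean(draws[, 3]), 2 / 3, sqrt(1 / 18 / nrow(draws)))
  expect_equal(apply_decoherence(c(0.3, 0.4, -sqrt(0.75)), -1, "FSSH"),
               c(0, 0, -1))
  expect_error(apply_decoherence(c(0, 0.6, -0.8), 1, "MASH"),
               "active state")
})

test_that("time-step validation and degenerate horizons behave", {
  m <- study_model()
  expect_error(run_ensemble(ensemble_spec("MASH", n_traj = 10, dt = 0.05), m),
               "resolve")
  spec0 <- ensemble_spec("MASH", n_traj = 5, t_max = 0, seed = 1)
  cv <- run_ensemble(spec0, m)
  expect_length(cv$p_mean, 1)   # only the initial sample
  expect_equal(cv$p_mean[1], 0) # reactant initialization
})

test_that("standard error shrinks as 1/sqrt(n_traj)", {
  m <- study_model(eps = 12)
  r1 <- plateau_rate(run_ensemble(ensemble_spec("MASH", n_traj = 2000,
                                                seed = 14), m))
  r2 <- plateau_rate(run_ensemble(ensemble_spec("MASH", n_traj = 8000,
                                                seed = 14), m))
  expect_equal(r1$stderr / r2$stderr, 2, tolerance = 0.35)
})

test_that("decoherence results are insensitive to the application cadence", {
  m <- study_model(eps = 12)
  rates <- lapply(c(1L, 10L, 100L), function(stride) {
    cv <- run_ensemble(ensemble_spec("MASH", n_traj = 3e4, t_max = 20,
                                     seed = 15, decoherence = "gap_triggered",
                                     decoherence_stride = stride), m)
    suppressWarnings(plateau_rate(cv))
  })
  for (i in 2:3)
    expect_lt(abs(rates[[i]]$k - rates[[1]]$k),
              3 * sqrt(rates[[i]]$stderr^2 + rates[[1]]$stderr^2))
})
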