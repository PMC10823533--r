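# Pure-R reference propagator for a single MASH trajectory at gamma = 0
# (fully deterministic).  Mirrors the integrator contract of the compiled
# engine -- BAOAB (velocity Verlet at gamma = 0) plus the exact electronic
# propagator with the mid-step field -- but goes through the amplitude
# representation (propagate_electronic), so it independently cross-checks
# the engine's Bloch-rotation arithmetic and hop bookkeeping.

reference_mash_trajectory <- function(m, Q, P, n, S = c(0, 0, n),
                                      dt, nsteps, stride = 1) {
  stopifnot(m$gamma == 0)
  state <- amplitudes_from_bloch(S)
  F <- adiabatic_force(Q, n, m)
  nsamp <- nsteps %/% stride + 1
  out <- data.frame(t = numeric(nsamp), Q = NA_real_, P = NA_real_,
                    Sx = NA_real_, Sy = NA_real_, Sz = NA_real_,
                    n = NA_integer_, hops = NA_integer_)
  hops <- 0L
  record <- function(k, tt) {
    S <- bloch_from_amplitudes(state)
    out[k, ] <<- list(tt, Q, P, S[1], S[2], S[3], n, hops)
  }
  record(1, 0)
  k <- 2
  for (step in seq_len(nsteps)) {
    Qold <- Q
    P <- P + 0.5 * dt * F
    Q <- Q + dt * P
    F <- adiabatic_force(Q, n, m)
    P <- P + 0.5 * dt * F
    Qmid <- 0.5 * (Qold + Q)
    adb <- adiabatic_surfaces(Qmid, m)
    state <- propagate_electronic(state, adb$gap,
                                  nonadiabatic_coupling(Qmid, m),
                                  (Q - Qold) / dt, dt)
    S <- bloch_from_amplitudes(state)
    if (S[3] * n < 0) {
      target <- -n
      adbQ <- adiabatic_surfaces(Q, m)
      dE <- target * adbQ$gap   # V_target - V_n = +/- gap
      P2 <- P^2 - 2 * dE
      if (P2 >= 0) {
        P <- sign(P) * sqrt(P2)
        n <- target
        hops <- hops + 1L
        F <- adiabatic_force(Q, n, m)
      } else {
        P <- -P
      }
    }
    if (step %% stride == 0) { record(k, step * dt); k <- k + 1 }
  }
  out
}

# trajectory total energy on the active surface
trace_energy <- function(trace, m) {
  adb <- adiabatic_surfaces(trace$Q, m)
  Vn <- ifelse(trace$n == 1, adb$V_plus, adb$V_minus)
  Vn + 0.5 * trace$P^2
}
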