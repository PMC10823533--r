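#' Ensemble specification for surface-hopping dynamics
#'
#' @param method \code{"MASH"} (deterministic hops when \eqn{S_z} changes
#'   sign) or \code{"FSSH"} (stochastic fewest-switches hops).
#' @param n_traj number of trajectories.
#' @param dt nuclear time step (\eqn{\beta\hbar}).  A startup check
#'   requires \code{dt * gap / hbar <= 0.25} at the initial-region well
#'   minimum so the piecewise-constant electronic field resolves the
#'   fastest relevant phase oscillation.
#' @param t_max simulation horizon (\eqn{\beta\hbar}).
#' @param sample_stride record observables every this many steps.
#' @param seed master integer seed; per-trajectory substreams are derived
#'   from it by a counter-based scheme, so results are independent of
#'   batching and execution order.
#' @param decoherence \code{"off"} or \code{"gap_triggered"}: when
#'   triggered (adiabatic gap above \code{decoherence_threshold}), MASH
#'   resamples the Bloch vector from the active-state hemisphere with
#'   density \eqn{\propto |S_z|}; FSSH collapses the amplitudes to the
#'   pure active state.
#' @param decoherence_threshold energy-gap trigger (\eqn{k_B T}; default
#'   \eqn{4 k_B T}, applied only in the wells, never near the crossing).
#' @param decoherence_stride steps between trigger checks (defaults to
#'   \code{sample_stride}; results are insensitive to this cadence).
#' @param frustrated treatment of frustrated (energy-forbidden) upward
#'   hops: \code{"reflect"} reverses the momentum component along the
#'   coupling direction (the prescription the MASH derivation yields,
#'   used for both methods by default) or \code{"ignore"}.
#' @param max_strata largest hop count tracked individually in the
#'   hop-count decomposition (larger counts pool into a remainder).
#' @param n_batches number of trajectory blocks used for block-averaged
#'   statistical errors of derived quantities (plateau slopes); block
#'   errors capture the time correlation of the curve that a pointwise
#'   binomial error cannot.
#' @return Object of class \code{"ensemble_spec"}.
#' @export
ensemble_spec <- function(method = c("MASH", "FSSH"), n_traj = 10000,
                          dt = 0.01, t_max = 20, sample_stride = 10,
                          seed = 1, decoherence = c("off", "gap_triggered"),
                          decoherence_threshold = 4,
                          decoherence_stride = sample_stride,
                          frustrated = c("reflect", "ignore"),
                          max_strata = 4, n_batches = 16) {
  method <- match.arg(method)
  decoherence <- match.arg(decoherence)
  frustrated <- match.arg(frustrated)
  stopifnot(n_traj >= 1, dt > 0, t_max >= 0, sample_stride >= 1,
            decoherence_threshold > 0, max_strata >= 0)
  structure(list(method = method, n_traj = as.integer(n_traj), dt = dt,
                 t_max = t_max, sample_stride = as.integer(sample_stride),
                 seed = as.integer(seed), decoherence = decoherence,
                 decoherence_threshold = decoherence_threshold,
                 decoherence_stride = as.integer(decoherence_stride),
                 frustrated = frustrated,
                 max_strata = as.integer(max_strata),
                 n_batches = as.integer(n_batches)),
            class = "ensemble_spec")
}

# gap at the well minimum of the initial region; used for the dt check
region_gap <- function(m, region) {
  g0 <- adiabatic_surfaces(0, m)$gap
  g1 <- adiabatic_surfaces(m$Q0, m)$gap
  switch(region, reactant = g0, product = g1, unconstrained = max(g0, g1))
}

check_timestep <- function(spec, m, region) {
  g <- region_gap(m, region)
  if (spec$dt * g / m$hbar > 0.25)
    stop(sprintf(paste0("dt = %g does not resolve the electronic gap at the ",
                        "%s well (gap = %.3g): need dt * gap / hbar <= 0.25"),
                 spec$dt, region, g))
  invisible(TRUE)
}

#' Run an ensemble of surface-hopping trajectories
#'
#' Samples initial conditions (classical Boltzmann nuclei restricted to
#' \code{region}, Boltzmann-weighted active state, method-specific
#' electronic state), propagates every trajectory with BAOAB Langevin
#' nuclear dynamics on the active adiabat plus exact Bloch precession, and
#' accumulates the ensemble-averaged product population together with its
#' hop-count decomposition.
#'
#' @param spec an \code{\link{ensemble_spec}}.
#' @param m an \code{\link{sb_model}}.
#' @param region initial region (\code{"reactant"}, \code{"product"},
#'   \code{"unconstrained"}).
#' @param return_final if TRUE, attach the final \code{(Q, P, Sz, n)} of
#'   every trajectory (used by the stationarity tests).
#' @return A \code{\link{population_curve}}.
#' @export
run_ensemble <- function(spec, m, region = "reactant", return_final = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(m, "sb_model"))
  region <- match.arg(region, c("reactant", "product", "unconstrained"))
  check_timestep(spec, m, region)
  nsteps <- round(spec$t_max / spec$dt)
  stride <- spec$sample_stride
  if (nsteps > 0) stopifnot(nsteps >= stride)
  res <- cpp_run_ensemble(model_param_vector(m),
                          method = if (spec$method == "MASH") 0L else 1L,
                          region = c(reactant = 0L, product = 1L,
                                     unconstrained = 2L)[[region]],
                          n_traj = spec$n_traj, dt = spec$dt,
                          nsteps_d = nsteps, stride = stride,
                          seed = spec$seed,
                          deco_on = spec$decoherence == "gap_triggered",
                          deco_threshold = spec$decoherence_threshold,
                          deco_stride = spec$decoherence_stride,
                          reflect_frustrated = spec$frustrated == "reflect",
                          max_strata = spec$max_strata,
                          return_final = return_final,
                          n_batches = spec$n_batches)
  N <- spec$n_traj
  p <- res$sum_pp / N
  strata <- res$strata / N
  colnames(strata) <- c(paste0("hops", 0:spec$max_strata), "remainder")
  curve <- population_curve(times = seq(0, nsteps, by = stride) * spec$dt,
                            p_mean = p,
                            p_stderr = sqrt(pmax(p * (1 - p), 0) / N),
                            n_traj = N, strata = strata,
                            method = spec$method)
  B <- min(spec$n_batches, N)
  bsizes <- tabulate((seq_len(N) - 1L) %% B + 1L, nbins = B)  # C++ i %% B
  curve$batch_means <- sweep(res$batch_pp, 2, bsizes, "/")
  curve$batch_sizes <- bsizes
  curve$counts <- list(hops = res$hops_total,
                       frustrated = res$frustrated_total,
                       decoherence = res$deco_total,
                       decoherence_skipped = res$deco_skipped,
                       prob_gt1 = res$prob_gt1,
                       hop_hist = stats::setNames(res$hop_hist,
                                                  colnames(strata)))
  if (res$prob_gt1 > 0)
    warning(sprintf(paste0("%d fewest-switches hop probabilities exceeded 1 ",
                           "and were clamped; reduce dt"), res$prob_gt1))
  curve$spec <- spec
  if (return_final)
    curve$final <- data.frame(Q = res$final_Q, P = res$final_P,
                              Sz = res$final_Sz, n = res$final_n)
  curve
}

#' Run and record a single surface-hopping trajectory
#'
#' Propagates one trajectory from an explicit initial condition and
#' returns the sampled trace.  Deterministic given \code{(init, seed)};
#' with \code{gamma = 0} and \code{method = "MASH"} the dynamics involve
#' no random numbers at all.
#'
#' @param init a one-row data.frame (or list) with \code{Q}, \code{P},
#'   \code{n}, and optionally \code{Sx}, \code{Sy}, \code{Sz} (defaults to
#'   the pure state of \code{n}).
#' @param spec an \code{\link{ensemble_spec}} (its \code{n_traj} is
#'   ignored).
#' @param m an \code{\link{sb_model}}.
#' @param traj_index substream index used to derive the trajectory RNG
#'   stream from \code{spec$seed}.
#' @return A data.frame trace with columns \code{t, Q, P, Sx, Sy, Sz, n,
#'   hops, frustrated}, with hop/decoherence counters as attributes.
#' @export
run_trajectory <- function(init, spec, m, traj_index = 0) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(m, "sb_model"))
  if (is.null(init$Sz)) {
    init$Sx <- 0; init$Sy <- 0; init$Sz <- as.numeric(init$n)
  }
  nsteps <- round(spec$t_max / spec$dt)
  res <- cpp_run_trajectory(model_param_vector(m),
                            method = if (spec$method == "MASH") 0L else 1L,
                            Q = init$Q, P = init$P, n = as.integer(init$n),
                            Sx = init$Sx, Sy = init$Sy, Sz = init$Sz,
                            dt = spec$dt, nsteps_d = nsteps,
                            stride = spec$sample_stride, seed = spec$seed,
                            traj_index = traj_index,
                            deco_on = spec$decoherence == "gap_triggered",
                            deco_threshold = spec$decoherence_threshold,
                            deco_stride = spec$decoherence_stride,
                            reflect_frustrated = spec$frustrated == "reflect")
  out <- data.frame(t = res$t, Q = res$Q, P = res$P, Sx = res$Sx,
                    Sy = res$Sy, Sz = res$Sz, n = res$n, hops = res$hops,
                    frustrated = res$frustrated)
  attr(out, "hops_total") <- res$hops_total
  attr(out, "frustrated_total") <- res$frustrated_total
  attr(out, "decoherence_total") <- res$deco_total
  out
}

#' Fewest-switches hop probability for one step
#'
#' Tully's hopping probability from the active surface \code{n} to the
#' other surface over a step \code{dt}, expressed through the Bloch
#' vector: \eqn{g = \max(0,\ n\,\dot Q\,d\,S_x\,dt/|c_n|^2)} with
#' \eqn{|c_n|^2 = (1 + n S_z)/2}.  Negative raw values mean the coherence
#' is driving population into the active state and give no hop.  Raw
#' values above 1 are clamped (and signal that \code{dt} is too large).
#'
#' @param S Bloch 3-vector of the electronic state.
#' @param n active state, \eqn{\pm 1}.
#' @param Qdot nuclear velocity over the step.
#' @param d nonadiabatic coupling at the step configuration.
#' @param dt time step.
#' @return Hop probability in \eqn{[0, 1]}.
#' @export
fssh_hop_probability <- function(S, n, Qdot, d, dt) {
  stopifnot(n %in% c(-1, 1), length(S) == 3, dt > 0)
  pop <- (1 + n * S[3]) / 2
  raw <- n * Qdot * d * S[1] * dt / max(pop, 1e-300)
  if (is.finite(raw) && raw > 1)
    warning(sprintf("raw hop probability %.3g exceeds 1; reduce dt", raw))
  min(max(raw, 0), 1)
}
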