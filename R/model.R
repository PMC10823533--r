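#' Parameters of the two-state Brownian-oscillator spin-boson model
#'
#' Collects the physical constants of the model in reduced units
#' (\eqn{\beta = \hbar = } mass \eqn{= 1} by default, so energies are in
#' \eqn{k_B T}, frequencies and rates in \eqn{1/\beta\hbar}, and times in
#' \eqn{\beta\hbar}).  The reactant and product diabats are equal-curvature
#' Marcus parabolas
#' \deqn{V_r(Q) = \tfrac12 \Omega^2 Q^2, \qquad
#'       V_p(Q) = \tfrac12 \Omega^2 (Q - Q_0)^2 - \epsilon,}
#' with \eqn{Q_0 = \sqrt{2\Lambda}/\Omega}, so the diabatic minima are
#' separated by the reorganization energy \eqn{\Lambda} and offset by the
#' driving force \eqn{\epsilon}.  The two diabats are coupled by a constant
#' diabatic coupling \eqn{\Delta}, and the solvent coordinate feels Ohmic
#' friction \eqn{\gamma} (spectral density \eqn{J(\omega) = \gamma\omega}),
#' implemented as a Langevin equation.
#'
#' @param lam reorganization energy \eqn{\Lambda} (\eqn{k_B T}); must be > 0.
#' @param eps driving force \eqn{\epsilon} (\eqn{k_B T}).
#' @param delta diabatic coupling \eqn{\Delta} (\eqn{k_B T}); must be > 0.
#' @param omega characteristic frequency \eqn{\Omega} (\eqn{1/\beta\hbar}).
#' @param gamma friction coefficient \eqn{\gamma} (\eqn{1/\beta\hbar});
#'   \eqn{\gamma = 0} gives microcanonical (velocity-Verlet) dynamics.
#' @param beta inverse temperature (fixed to 1 in reduced units).
#' @param hbar reduced Planck constant (fixed to 1 in reduced units).
#'
#' @return An object of class \code{"sb_model"}: a named list of the seven
#'   constants plus the derived quantities \code{Q0} (product-minimum
#'   position) and \code{Qx} (diabatic crossing point).
#' @examples
#' m <- sb_model(lam = 12, eps = 0, delta = 10^-1.4)
#' crossing_point(m)
#' @export
sb_model <- function(lam = 12, eps = 0, delta = 10^(-1.4),
                     omega = 0.25, gamma = omega, beta = 1, hbar = 1) {
  stopifnot(lam > 0, delta > 0, omega > 0, gamma >= 0, beta > 0, hbar > 0)
  m <- list(lam = lam, eps = eps, delta = delta, omega = omega,
            gamma = gamma, beta = beta, hbar = hbar)
  m$Q0 <- sqrt(2 * lam) / omega
  m$Qx <- (lam - eps) / (omega * sqrt(2 * lam))
  class(m) <- "sb_model"
  m
}

#' @export
print.sb_model <- function(x, ...) {
  cat("Brownian-oscillator spin-boson model (reduced units, beta = hbar = 1)\n")
  cat(sprintf("  Lambda = %g, eps = %g, Delta = %g (log10 beta*Delta = %.3f)\n",
              x$lam, x$eps, x$delta, log10(x$beta * x$delta)))
  cat(sprintf("  Omega = %g, gamma = %g; Q0 = %.4f, crossing Qx = %.4f\n",
              x$omega, x$gamma, x$Q0, x$Qx))
  invisible(x)
}

# flat numeric vector handed to the compiled engine
model_param_vector <- function(m) {
  c(lam = m$lam, eps = m$eps, delta = m$delta, omega = m$omega,
    gamma = m$gamma, beta = m$beta, hbar = m$hbar)
}

#' Diabatic Marcus parabolas and their gradients
#'
#' @param Q numeric vector of solvent-coordinate positions.
#' @param m an \code{\link{sb_model}}.
#' @return A list with components \code{V_r}, \code{V_p}, \code{dV_r},
#'   \code{dV_p}, each the length of \code{Q}.
#' @export
diabatic_potentials <- function(Q, m) {
  list(V_r  = 0.5 * m$omega^2 * Q^2,
       V_p  = 0.5 * m$omega^2 * (Q - m$Q0)^2 - m$eps,
       dV_r = m$omega^2 * Q,
       dV_p = m$omega^2 * (Q - m$Q0))
}

#' Diabatic crossing point
#'
#' Position where the reactant and product parabolas intersect,
#' \eqn{Q^\ddag = (\Lambda - \epsilon) / (\Omega\sqrt{2\Lambda})}.  The
#' reactant/product projector and the initial-condition region constraint
#' are both defined relative to this point.
#'
#' @inheritParams diabatic_potentials
#' @return The crossing position (scalar).
#' @export
crossing_point <- function(m) m$Qx

#' Adiabatic surfaces and energy gap
#'
#' \eqn{V_\pm = \tfrac12 (V_r + V_p) \pm \tfrac12 \sqrt{(V_r - V_p)^2 +
#' 4\Delta^2}}.  The gap \eqn{V_+ - V_-} is bounded below by \eqn{2\Delta},
#' attained exactly at the crossing point.
#'
#' @inheritParams diabatic_potentials
#' @return A list with components \code{V_minus}, \code{V_plus}, \code{gap}.
#' @export
adiabatic_surfaces <- function(Q, m) {
  d <- diabatic_potentials(Q, m)
  mid <- 0.5 * (d$V_r + d$V_p)
  gap <- sqrt((d$V_r - d$V_p)^2 + 4 * m$delta^2)
  list(V_minus = mid - 0.5 * gap, V_plus = mid + 0.5 * gap, gap = gap)
}

#' Nonadiabatic coupling
#'
#' First-derivative coupling \eqn{d(Q) = \Delta (V_r' - V_p') / ((V_r -
#' V_p)^2 + 4\Delta^2)}.  For equal-curvature parabolas \eqn{V_r' - V_p' =
#' \Omega^2 Q_0} is constant, so \eqn{d(Q)} is a Lorentzian of area
#' \eqn{\pi/2} centred at the crossing with peak \eqn{\Omega^2 Q_0 /
#' (4\Delta)}.  The package-wide sign convention takes \eqn{d(Q^\ddag) > 0};
#' the same sign enters the electronic equations of motion and the
#' fewest-switches hop probability, so all observables are
#' convention-independent.
#'
#' @inheritParams diabatic_potentials
#' @return Numeric vector \eqn{d(Q)} (units 1/position).
#' @export
nonadiabatic_coupling <- function(Q, m) {
  d <- diabatic_potentials(Q, m)
  m$delta * (d$dV_r - d$dV_p) / ((d$V_r - d$V_p)^2 + 4 * m$delta^2)
}

#' Force on the active adiabatic surface
#'
#' \eqn{F_n = -dV_n/dQ}, evaluated analytically.
#'
#' @inheritParams diabatic_potentials
#' @param n active state: \code{+1} (upper adiabat) or \code{-1} (lower).
#' @return Numeric vector of forces.
#' @export
adiabatic_force <- function(Q, n, m) {
  stopifnot(all(n %in% c(-1, 1)))
  d <- diabatic_potentials(Q, m)
  dV <- d$V_r - d$V_p
  root <- sqrt(dV^2 + 4 * m$delta^2)
  -(0.5 * (d$dV_r + d$dV_p) + 0.5 * n * dV * (d$dV_r - d$dV_p) / root)
}
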