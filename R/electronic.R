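#' Electronic two-level state
#'
#' Adiabatic-representation wave-function amplitudes \eqn{(c_+, c_-)},
#' normalized to \eqn{|c_+|^2 + |c_-|^2 = 1}.  The equivalent Bloch vector
#' is \eqn{S_z = |c_+|^2 - |c_-|^2} and \eqn{S_x + i S_y = 2 c_+ c_-^*}
#' (the package-wide phase convention).
#'
#' @param c_plus,c_minus complex amplitudes on the upper/lower adiabat.
#' @return Object of class \code{"electronic_state"} with fields
#'   \code{c_plus} and \code{c_minus}.
#' @export
electronic_state <- function(c_plus, c_minus) {
  nrm <- sqrt(Mod(c_plus)^2 + Mod(c_minus)^2)
  stopifnot(abs(nrm - 1) < 1e-8)
  structure(list(c_plus = as.complex(c_plus), c_minus = as.complex(c_minus)),
            class = "electronic_state")
}

#' Bloch vector of an electronic state
#'
#' @param state an \code{\link{electronic_state}}.
#' @return Numeric 3-vector \code{c(Sx, Sy, Sz)} of unit length.
#' @export
bloch_from_amplitudes <- function(state) {
  coh <- 2 * state$c_plus * Conj(state$c_minus)
  c(Sx = Re(coh), Sy = Im(coh),
    Sz = Mod(state$c_plus)^2 - Mod(state$c_minus)^2)
}

#' Amplitudes from a Bloch vector
#'
#' Inverts \code{\link{bloch_from_amplitudes}} up to the (unobservable)
#' global phase, supplied as \code{phase}.
#'
#' @param S numeric 3-vector on the unit sphere.
#' @param phase global phase in radians (default 0).
#' @return An \code{\link{electronic_state}}.
#' @export
amplitudes_from_bloch <- function(S, phase = 0) {
  stopifnot(abs(sum(S^2) - 1) < 1e-8)
  ap <- sqrt((1 + S[3]) / 2)
  am <- sqrt((1 - S[3]) / 2)
  rel <- atan2(S[2], S[1])    # arg(2 c+ c-*)
  electronic_state(ap * exp(1i * (phase + rel / 2)),
                   am * exp(1i * (phase - rel / 2)))
}

#' Propagate the electronic amplitudes over one step
#'
#' Advances the adiabatic-representation time-dependent Schroedinger
#' equation \eqn{i\hbar \dot c_\pm = V_\pm c_\pm \mp i\hbar \dot Q d\,
#' c_\mp} for a field held constant over \code{dt}, using the exact 2x2
#' matrix exponential, so the norm is conserved to machine precision.  On
#' the Bloch sphere this is a rigid precession about the axis
#' \eqn{(0,\, 2\dot Q d,\, \mathrm{gap}/\hbar)}.
#'
#' @param state an \code{\link{electronic_state}}.
#' @param gap adiabatic energy gap \eqn{V_+ - V_-} at the (mid-)step
#'   configuration.
#' @param d nonadiabatic coupling at the same configuration.
#' @param Qdot nuclear velocity over the step.
#' @param dt time step.
#' @param vmean mean potential \eqn{(V_+ + V_-)/2}; contributes only a
#'   global phase (default 0).
#' @param hbar reduced Planck constant (default 1).
#' @return The propagated \code{\link{electronic_state}}.
#' @export
propagate_electronic <- function(state, gap, d, Qdot, dt, vmean = 0, hbar = 1) {
  # H = vmean*I + (gap/2) sigma_z + (hbar*Qdot*d) sigma_y
  a <- 0.5 * gap / hbar
  b <- Qdot * d
  w <- sqrt(a^2 + b^2)
  c0 <- exp(-1i * vmean * dt / hbar)
  if (w == 0) {
    U <- diag(2) * c0
  } else {
    th <- w * dt
    # exp(-i th (uz sz + uy sy)) = cos(th) I - i sin(th) (uz sz + uy sy)
    uz <- a / w; uy <- b / w
    U <- c0 * matrix(c(cos(th) - 1i * sin(th) * uz, -sin(th) * uy,
                       sin(th) * uy,  cos(th) + 1i * sin(th) * uz),
                     2, 2, byrow = TRUE)
  }
  cc <- U %*% c(state$c_plus, state$c_minus)
  electronic_state(cc[1], cc[2])
}
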