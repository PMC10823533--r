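#' Sample classical Boltzmann initial conditions
#'
#' Draws nuclear phase points and active states from the joint classical
#' Boltzmann distribution over the two adiabatic surfaces,
#' \eqn{p(Q, n) \propto e^{-\beta V_n(Q)}}, restricted to a region of the
#' reactant/product partition, with momenta drawn independently from the
#' Maxwell--Boltzmann distribution \eqn{p(P) \propto e^{-\beta P^2/2}}.
#'
#' The region constraint uses the adiabatic projector (see
#' \code{\link{product_projector}}): within the reactant region there is
#' exactly one allowed active state at each position (\eqn{n = -} left of
#' the crossing, \eqn{n = +} right of it), so in the normal regime
#' reactants live in the left diabatic well on the lower surface while in
#' the inverted regime (\eqn{\epsilon > \Lambda}) they sit on the upper
#' adiabat.  Sampling is by exact rejection from the mixture of the two
#' diabatic Gaussians: \eqn{e^{-\beta V_n} \le e^{\beta\Delta}(e^{-\beta
#' V_r} + e^{-\beta V_p})} bounds the acceptance weight by 1.
#'
#' @param m an \code{\link{sb_model}}.
#' @param n_samples number of phase points to draw.
#' @param region \code{"reactant"}, \code{"product"} or
#'   \code{"unconstrained"}.
#' @param seed optional integer seed (uses the current RNG state if NULL).
#' @return A data.frame with columns \code{Q}, \code{P}, \code{n}
#'   (\eqn{\pm 1}).
#' @export
sample_nuclear_and_state <- function(m, n_samples, region = "reactant",
                                     seed = NULL) {
  region <- match.arg(region, c("reactant", "product", "unconstrained"))
  if (!is.null(seed)) set.seed(seed)
  sigQ <- 1 / (sqrt(m$beta) * m$omega)
  # within a constrained region the allowed branch potential tracks that
  # region's diabat to within Delta, so that diabat's Gaussian is the
  # proposal; the unconstrained case uses the Boltzmann-weighted mixture
  pr_r <- switch(region, reactant = 1, product = 0,
                 unconstrained = 1 / (1 + exp(m$beta * m$eps)))
  shift <- min(0, -m$eps)
  Q <- numeric(0); n <- integer(0)
  attempts <- 0
  while (length(Q) < n_samples) {
    todo <- n_samples - length(Q)
    nb <- max(2L * todo, 100L)
    attempts <- attempts + nb
    if (attempts > 1e6 * n_samples + 1e7)
      stop("rejection-sampling acceptance below 1e-6; check region/model")
    centre <- ifelse(stats::runif(nb) < pr_r, 0, m$Q0)
    Qp <- centre + sigQ * stats::rnorm(nb)
    np <- switch(region,
      reactant      = ifelse(Qp > m$Qx, 1L, -1L),
      product       = ifelse(Qp >= m$Qx, -1L, 1L),
      unconstrained = ifelse(stats::runif(nb) < 0.5, -1L, 1L))
    dia <- diabatic_potentials(Qp, m)
    adb <- adiabatic_surfaces(Qp, m)
    Vn <- ifelse(np == 1L, adb$V_plus, adb$V_minus)
    acc <- switch(region,
      reactant = exp(-m$beta * (Vn - dia$V_r + m$delta)),
      product  = exp(-m$beta * (Vn - dia$V_p + m$delta)),
      unconstrained = exp(-m$beta * (Vn - shift)) /
        (exp(m$beta * m$delta) *
           (exp(-m$beta * (dia$V_r - shift)) +
              exp(-m$beta * (dia$V_p - shift)))))
    keep <- stats::runif(nb) < acc
    Q <- c(Q, Qp[keep]); n <- c(n, np[keep])
  }
  Q <- Q[seq_len(n_samples)]; n <- n[seq_len(n_samples)]
  P <- stats::rnorm(n_samples) / sqrt(m$beta)
  data.frame(Q = Q, P = P, n = n)
}

#' Sample the initial electronic state for a given active state
#'
#' FSSH trajectories start in the pure state of the active surface (the
#' Bloch vector at the pole).  MASH trajectories start with the Bloch
#' vector distributed over the hemisphere of the active state with density
#' proportional to \eqn{|S_z|}: \eqn{S_z = \pm\sqrt{u}}, \eqn{u \sim
#' U(0,1]}, azimuth uniform.  This sampling replaces the stochastic hops
#' of FSSH and gives the hemisphere-average \eqn{\langle |S_z| \rangle =
#' 2/3}.
#'
#' @param n active state(s), vector of \eqn{\pm 1}.
#' @param method \code{"MASH"} or \code{"FSSH"}.
#' @param seed optional integer seed.
#' @return A data.frame with columns \code{Sx}, \code{Sy}, \code{Sz},
#'   \code{phase} (uniform random global phase, recorded for
#'   reproducibility; unobservable).
#' @export
sample_electronic <- function(n, method = c("MASH", "FSSH"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(n %in% c(-1, 1)))
  if (!is.null(seed)) set.seed(seed)
  k <- length(n)
  if (method == "FSSH")
    return(data.frame(Sx = numeric(k), Sy = numeric(k), Sz = as.numeric(n),
                      phase = numeric(k)))
  Sz <- n * sqrt(stats::runif(k))
  phi <- stats::runif(k, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - Sz^2))
  data.frame(Sx = st * cos(phi), Sy = st * sin(phi), Sz = Sz,
             phase = stats::runif(k, 0, 2 * pi))
}
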