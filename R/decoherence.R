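#' Apply a decoherence correction to an electronic state
#'
#' Implements the simple gap-triggered decoherence correction applied by
#' the engines when the adiabatic gap exceeds the threshold (i.e. far from
#' the coupling region, where the ensemble coherence vanishes and the
#' correction is a safe special case of a quantum jump).  For MASH the
#' Bloch vector is resampled from the hemisphere of the current active
#' state with density \eqn{\propto |S_z|} (identical to the initial
#' sampling, hence idempotent in distribution); for FSSH the amplitudes
#' are collapsed to the pure state of the active surface.
#'
#' @param S numeric 3-vector Bloch state.
#' @param n active state, \eqn{\pm 1}.
#' @param method \code{"MASH"} or \code{"FSSH"}.
#' @return The corrected Bloch 3-vector.
#' @export
apply_decoherence <- function(S, n, method = c("MASH", "FSSH")) {
  method <- match.arg(method)
  stopifnot(n %in% c(-1, 1), length(S) == 3)
  if (method == "FSSH") return(c(0, 0, n))
  if (sign(S[3]) != n)
    stop("MASH decoherence requested while sign(Sz) disagrees with the ",
         "active state; resampling here would silently switch surfaces")
  sz <- n * sqrt(stats::runif(1))
  phi <- stats::runif(1, 0, 2 * pi)
  st <- sqrt(1 - sz^2)
  c(st * cos(phi), st * sin(phi), sz)
}
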