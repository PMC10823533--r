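#' Product-population curve
#'
#' Container for the ensemble-averaged product population
#' \eqn{\langle P_p(t) \rangle}, its standard error, and (optionally) its
#' decomposition over trajectory hop counts.  The strata sum to the total
#' curve exactly (the hop counts partition the ensemble).
#'
#' @param times sample times (\eqn{\beta\hbar}).
#' @param p_mean product population at each time, in \eqn{[0, 1]}.
#' @param p_stderr standard error of \code{p_mean}.
#' @param n_traj ensemble size.
#' @param strata optional matrix (times x hop-count buckets) of stratified
#'   populations.
#' @param method label, e.g. \code{"MASH"}.
#' @return Object of class \code{"population_curve"}.
#' @export
population_curve <- function(times, p_mean, p_stderr = NULL, n_traj = NA,
                             strata = NULL, method = NA_character_) {
  stopifnot(length(times) == length(p_mean),
            all(p_mean >= -1e-12 & p_mean <= 1 + 1e-12))
  if (!is.null(strata)) {
    stopifnot(nrow(strata) == length(times))
    stopifnot(max(abs(rowSums(strata) - p_mean)) < 1e-9)
  }
  structure(list(times = times, p_mean = p_mean, p_stderr = p_stderr,
                 n_traj = n_traj, strata = strata, method = method),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("Product-population curve (%s, %s trajectories)\n",
              x$method, format(x$n_traj, big.mark = ",")))
  cat(sprintf("  t in [%g, %g] beta*hbar (%d samples); final <Pp> = %.4g\n",
              min(x$times), max(x$times), length(x$times),
              x$p_mean[length(x$p_mean)]))
  if (!is.null(x$counts))
    cat(sprintf("  hops: %g, frustrated: %g, decoherence events: %g\n",
                x$counts$hops, x$counts$frustrated, x$counts$decoherence))
  invisible(x)
}

#' Product projector
#'
#' Adiabatic definition of products: everything on the lower surface to
#' the right of the diabatic crossing, or on the upper surface to the left
#' of it.  The boundary \eqn{Q = Q^\ddag} itself is assigned to the
#' reactant (measure-zero convention).  \eqn{P_r = 1 - P_p}.
#'
#' @param Q position(s).
#' @param n active state(s), \eqn{\pm 1}.
#' @param m an \code{\link{sb_model}}.
#' @return Integer vector of 0/1 product indicators.
#' @export
product_projector <- function(Q, n, m) {
  stopifnot(all(n %in% c(-1, 1)))
  as.integer((n == -1 & Q > m$Qx) | (n == 1 & Q < m$Qx))
}

#' Rate-constant result
#'
#' @param k forward rate constant (\eqn{1/\beta\hbar}).
#' @param estimator one of \code{"plateau_slope"}, \code{"decay_fit"},
#'   \code{"marcus"}.
#' @param stderr statistical error of \code{k}.
#' @param window slope-fit window (plateau estimator only).
#' @param method dynamics method label.
#' @param extra named list of estimator-specific fields.
#' @return Object of class \code{"rate_result"}.
#' @export
rate_result <- function(k, estimator, stderr = NA_real_, window = NULL,
                        method = NA_character_, extra = list()) {
  stopifnot(k >= 0 || is.na(k))
  structure(c(list(k = k, estimator = estimator, stderr = stderr,
                   window = window, method = method), extra),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("Rate constant: k = %.4g (1/beta*hbar)  [%s%s]\n", x$k,
              x$estimator,
              if (!is.na(x$method)) paste0(", ", x$method) else ""))
  if (!is.na(x$stderr)) cat(sprintf("  stderr = %.2g (%.1f%%)\n",
                                    x$stderr, 100 * x$stderr / x$k))
  if (!is.null(x$window)) cat(sprintf("  fit window: [%g, %g]\n",
                                      x$window[1], x$window[2]))
  invisible(x)
}

#' Plateau-slope rate estimator
#'
#' Fits the slope of \eqn{\langle P_p(t) \rangle} over the plateau window
#' (default \eqn{t \in [10, 20]\,\beta\hbar}) by least squares and divides
#' by the mean reactant population over the window, which makes the
#' estimator exact for two-state kinetics and reduces bias outside the
#' weak-coupling regime.  The statistical error is block-averaged when the
#' curve carries trajectory blocks (the slope is recomputed per block and
#' the error is the standard error over blocks, which captures both the
#' time correlation of the curve and projector recrossing noise);
#' otherwise it falls back to a Poisson estimate from the count of net
#' reactive events in the window.
#'
#' @param curve a \code{\link{population_curve}}.
#' @param window numeric length-2 fit window (\eqn{\beta\hbar}).
#' @return A \code{\link{rate_result}}.
#' @export
plateau_rate <- function(curve, window = c(10, 20)) {
  stopifnot(inherits(curve, "population_curve"),
            window[1] >= min(curve$times), window[2] <= max(curve$times))
  sel <- curve$times >= window[1] & curve$times <= window[2]
  stopifnot(sum(sel) >= 3)
  t <- curve$times[sel]; p <- curve$p_mean[sel]
  fit <- stats::lm(p ~ t)
  slope <- unname(stats::coef(fit)[2])
  pr <- 1 - mean(p)
  if (pr < 0.9)
    message(sprintf("mean reactant population in window is %.3f; ", pr),
            "the slope is normalized by it (outside the rare-event regime)")
  # transient check: is a quadratic term statistically significant?
  fit2 <- stats::lm(p ~ t + I(t^2))
  tval <- tryCatch(
    suppressWarnings(summary(fit2)$coefficients["I(t^2)", "t value"]),
    error = function(e) 0)
  if (is.finite(tval) && abs(tval) > 4)
    warning("significant curvature in the fit window; ",
            "the transient may not have subsided")
  k <- max(slope, 0) / pr
  se <- NA_real_
  if (!is.null(curve$batch_means) && ncol(curve$batch_means) >= 4) {
    B <- ncol(curve$batch_means)
    tc <- t - mean(t)
    kb <- as.numeric(crossprod(curve$batch_means[sel, , drop = FALSE], tc) /
                       sum(tc^2)) / pr
    w <- curve$batch_sizes / sum(curve$batch_sizes)
    kbar <- sum(w * kb)
    se <- sqrt(sum(w * (kb - kbar)^2) / (B - 1))
  } else if (is.finite(curve$n_traj) && !is.na(curve$n_traj)) {
    nreact <- max(curve$n_traj * abs(slope) * diff(window), 1)
    se <- sqrt(nreact) / curve$n_traj / diff(window) / pr
  }
  rate_result(k, "plateau_slope", stderr = se, window = window,
              method = curve$method,
              extra = list(slope = slope, p_reactant = pr))
}

#' Full-decay rate estimator
#'
#' Weighted fit of two-state relaxation kinetics
#' \eqn{p(t) = p_{eq}(1 - e^{-(k_f + k_b) t})} with
#' \eqn{p_{eq} = k_f/(k_f + k_b)} to a full population-decay curve started
#' in the reactant.  Returns the forward rate \eqn{k_f} and the half-life
#' \eqn{\ln 2/(k_f + k_b)} of the reactant-population excess (which is
#' invariant to \eqn{p_{eq}}, enabling half-life ratio comparisons between
#' methods).  Errors if the curve does not span at least two fitted
#' half-lives.
#'
#' @param curve a \code{\link{population_curve}}.
#' @return A \code{\link{rate_result}} with fields \code{k_total},
#'   \code{p_eq} and \code{half_life}.
#' @export
decay_rate <- function(curve) {
  stopifnot(inherits(curve, "population_curve"))
  t <- curve$times; p <- curve$p_mean
  keep <- t > 0
  t <- t[keep]; p <- p[keep]
  peq0 <- mean(p[t >= 0.9 * max(t)])
  if (peq0 <= 0) stop("no product formation; cannot fit a decay")
  ihalf <- which(p >= 0.5 * peq0)[1]
  k0 <- log(2) / t[ihalf]
  w <- if (!is.null(curve$p_stderr)) {
    se <- curve$p_stderr[keep]
    1 / pmax(se, max(se, 1e-12) / 50)^2
  } else rep(1, length(t))
  fit <- tryCatch(
    stats::nls(p ~ peq * (1 - exp(-ktot * t)),
               start = list(peq = peq0, ktot = k0), weights = w,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("decay fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  ktot <- unname(cf["ktot"]); peq <- unname(cf["peq"])
  half <- log(2) / ktot
  if (max(t) < 2 * half)
    stop(sprintf("curve spans %.2f fitted half-lives; need at least 2",
                 max(t) / half))
  # statistical errors: refit per trajectory block where blocks exist (the
  # pointwise nls covariance badly underestimates the error because curve
  # noise is trajectory-correlated across times); otherwise fall back to
  # the nls covariance
  vc <- stats::vcov(fit)
  se_kf <- sqrt(ktot^2 * vc["peq", "peq"] + peq^2 * vc["ktot", "ktot"] +
                  2 * peq * ktot * vc["peq", "ktot"])
  se_ktot <- sqrt(vc["ktot", "ktot"])
  if (!is.null(curve$batch_means) && ncol(curve$batch_means) >= 4) {
    fits <- lapply(seq_len(ncol(curve$batch_means)), function(b) {
      pb <- curve$batch_means[keep, b]
      tryCatch(stats::coef(stats::nls(pb ~ pq * (1 - exp(-kt * t)),
                                      start = list(pq = peq, kt = ktot),
                                      control = stats::nls.control(
                                        maxiter = 100, warnOnly = TRUE))),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (sum(ok) >= 4) {
      B <- sum(ok)
      w <- curve$batch_sizes[ok] / sum(curve$batch_sizes[ok])
      kt_b <- vapply(fits[ok], function(cf) cf[["kt"]], numeric(1))
      kf_b <- vapply(fits[ok], function(cf) cf[["pq"]] * cf[["kt"]],
                     numeric(1))
      se_ktot <- sqrt(sum(w * (kt_b - sum(w * kt_b))^2) / (B - 1))
      se_kf <- sqrt(sum(w * (kf_b - sum(w * kf_b))^2) / (B - 1))
    }
  }
  rate_result(peq * ktot, "decay_fit", stderr = se_kf,
              method = curve$method,
              extra = list(k_total = ktot, p_eq = peq, half_life = half,
                           stderr_k_total = se_ktot))
}

#' Marcus-theory rate
#'
#' Classical golden-rule (Marcus) forward rate
#' \deqn{k_{MT} = \frac{\Delta^2}{\hbar} \sqrt{\frac{\pi\beta}{\Lambda}}
#'   \exp\!\left(-\frac{\beta(\Lambda - \epsilon)^2}{4\Lambda}\right),}
#' exact for this model in the weak-coupling limit with classical nuclei.
#' It is maximal at the activationless point \eqn{\epsilon = \Lambda} and
#' satisfies detailed balance
#' \eqn{k_{MT}(\epsilon)/k_{MT}(-\epsilon) = e^{\beta\epsilon}}.
#'
#' @param m an \code{\link{sb_model}}.
#' @return A \code{\link{rate_result}}.
#' @export
marcus_rate <- function(m) {
  k <- m$delta^2 / m$hbar * sqrt(pi * m$beta / m$lam) *
    exp(-m$beta * (m$lam - m$eps)^2 / (4 * m$lam))
  rate_result(k, "marcus", method = "Marcus")
}

#' Hop-count decomposition of a population curve
#'
#' Extracts \eqn{\langle P_p(t)\, 1[\mathrm{hops}(t) = m] \rangle} for the
#' requested hop counts from a curve produced by
#' \code{\link{run_ensemble}}.  The strata plus the remainder sum to the
#' total curve exactly.
#'
#' @param curve a \code{\link{population_curve}} with strata.
#' @param counts integer hop counts of interest (default \code{c(0, 2)},
#'   the single-passage and recrossing pathways).
#' @return A data.frame with column \code{t}, one column per requested
#'   count, their sum, and the total curve.
#' @export
hop_decomposition <- function(curve, counts = c(0, 2)) {
  stopifnot(inherits(curve, "population_curve"), !is.null(curve$strata))
  cols <- paste0("hops", counts)
  missing <- setdiff(cols, colnames(curve$strata))
  if (length(missing))
    stop("strata not tracked for: ", paste(missing, collapse = ", "),
         " (increase max_strata)")
  out <- data.frame(t = curve$times)
  for (cc in cols) out[[cc]] <- curve$strata[, cc]
  out$sum_requested <- rowSums(curve$strata[, cols, drop = FALSE])
  out$total <- curve$p_mean
  out
}

#' Plateau-rate scan over a model parameter
#'
#' Runs MASH and FSSH ensembles on a grid of diabatic couplings or driving
#' forces and tabulates the plateau-slope rates next to the analytic
#' Marcus rate.  The same master seed is reused at every grid point for
#' variance-reduced ratios.
#'
#' @param m base \code{\link{sb_model}}.
#' @param variable \code{"delta"} or \code{"eps"}.
#' @param values grid of parameter values.
#' @param spec an \code{\link{ensemble_spec}} template (its method field
#'   is overridden).
#' @param methods methods to run at each point.
#' @param window plateau window passed to \code{\link{plateau_rate}}.
#' @return A data.frame with one row per grid point and per-method rate
#'   and stderr columns plus \code{k_marcus}.
#' @export
scan_rates <- function(m, variable = c("delta", "eps"), values, spec,
                       methods = c("MASH", "FSSH"), window = c(10, 20)) {
  variable <- match.arg(variable)
  rows <- lapply(values, function(v) {
    mi <- m
    mi[[variable]] <- v
    mi <- sb_model(lam = mi$lam, eps = mi$eps, delta = mi$delta,
                   omega = mi$omega, gamma = mi$gamma, beta = mi$beta,
                   hbar = mi$hbar)
    row <- stats::setNames(list(v), variable)
    for (meth in methods) {
      sp <- spec
      sp$method <- meth
      cv <- run_ensemble(sp, mi)
      rr <- plateau_rate(cv, window = window)
      row[[paste0("k_", tolower(meth))]] <- rr$k
      row[[paste0("stderr_", tolower(meth))]] <- rr$stderr
    }
    row$k_marcus <- marcus_rate(mi)$k
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
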