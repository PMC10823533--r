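#' Parse a run-configuration file
#'
#' Reads a minimal TOML-like configuration with \code{[section]} headers
#' and \code{key = value} lines (\code{#} comments allowed).  Recognized
#' sections and keys:
#' \describe{
#'   \item{\code{[model]}}{\code{lam, eps, delta, omega, gamma} (reduced
#'     units \eqn{\beta\Lambda}, \eqn{\beta\epsilon}, \eqn{\beta\Delta},
#'     \eqn{\beta\hbar\Omega}, \eqn{\beta\hbar\gamma}).}
#'   \item{\code{[ensemble]}}{\code{method, n_traj, dt, t_max,
#'     sample_stride, seed, decoherence, decoherence_threshold,
#'     frustrated, max_strata}.}
#'   \item{\code{[init]}}{\code{region}.}
#'   \item{\code{[scan]}}{\code{variable} (\code{delta} or \code{eps}) and
#'     \code{values} (comma-separated numbers).}
#'   \item{\code{[output]}}{\code{dir}, \code{prefix}.}
#' }
#' Unknown sections or keys are rejected.  The \code{[model]} section is
#' mandatory.
#'
#' @param path file path.
#' @return A named list of sections, each a named list of parsed values.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  known <- list(
    model    = c("lam", "eps", "delta", "omega", "gamma"),
    ensemble = c("method", "n_traj", "dt", "t_max", "sample_stride", "seed",
                 "decoherence", "decoherence_threshold", "frustrated",
                 "max_strata"),
    init     = c("region"),
    scan     = c("variable", "values"),
    output   = c("dir", "prefix"))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(known))
        stop("unknown config section: [", section, "]")
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside any [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% known[[section]])
        stop("unknown key '", key, "' in section [", section, "]")
      val <- gsub('^"|"$', "", val)
      if (key == "values") {
        val <- as.numeric(trimws(strsplit(val, ",")[[1]]))
        if (anyNA(val)) stop("non-numeric entry in scan values")
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (!is.na(num)) val <- num
      }
      cfg[[section]][[key]] <- val
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  if (is.null(cfg$model))
    stop("config is missing the mandatory [model] section")
  cfg
}

config_model <- function(cfg) {
  a <- cfg$model
  omega <- if (!is.null(a$omega)) a$omega else 0.25
  sb_model(lam = if (!is.null(a$lam)) a$lam else 12,
           eps = if (!is.null(a$eps)) a$eps else 0,
           delta = if (!is.null(a$delta)) a$delta else 10^(-1.4),
           omega = omega,
           gamma = if (!is.null(a$gamma)) a$gamma else omega)
}

config_spec <- function(cfg, overrides = list()) {
  e <- cfg$ensemble
  if (is.null(e)) e <- list()
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) e[[nm]] <- overrides[[nm]]
  args <- list(
    method = if (!is.null(e$method)) e$method else "MASH",
    n_traj = if (!is.null(e$n_traj)) e$n_traj else 10000,
    dt = if (!is.null(e$dt)) e$dt else 0.01,
    t_max = if (!is.null(e$t_max)) e$t_max else 20,
    sample_stride = if (!is.null(e$sample_stride)) e$sample_stride else 10,
    seed = if (!is.null(e$seed)) e$seed else 1,
    decoherence = if (!is.null(e$decoherence)) e$decoherence else "off",
    frustrated = if (!is.null(e$frustrated)) e$frustrated else "reflect")
  if (!is.null(e$decoherence_threshold))
    args$decoherence_threshold <- e$decoherence_threshold
  if (!is.null(e$max_strata)) args$max_strata <- e$max_strata
  do.call(ensemble_spec, args)
}
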