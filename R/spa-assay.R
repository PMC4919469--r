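# SPA titration forward model and nonlinear Kd fitting.
#
# Direct mode: bead-immobilized receptor at a fixed (reporter)
# concentration, radiolabelled ligand varied; signal tracks receptor
# occupancy.  Competition mode: preformed 30 nM / 30 nM reporter pair,
# unlabelled competitor varied; signal falls as the reporter ligand is
# displaced.  All equilibria are solved exactly (ligand depletion kept).

#' Construct an SPA titration series
#'
#' @param mode \code{"direct"} or \code{"competition"}.
#' @param varied_conc concentrations of the varied species (molar or unit
#'   strings), strictly increasing, length >= 4.
#' @param signal scintillation counts at each point.
#' @param control_signal optional no-fusion-protein control counts
#'   (same length), subtracted by \code{\link{correct_signal}}.
#' @param fixed named list of fixed species concentrations:
#'   direct mode needs \code{receptor}; competition mode needs
#'   \code{receptor} and \code{ligand} (the reporter pair).
#' @param known_kd_reporter reporter-pair Kd (molar), required to fit
#'   competition data (the reporter interaction is characterized
#'   separately, e.g. by self-competition).
#' @return object of class \code{"titration_series"}.
#' @export
titration_series <- function(mode = c("direct", "competition"),
                             varied_conc, signal,
                             control_signal = NULL,
                             fixed = list(),
                             known_kd_reporter = NULL) {
  mode <- match.arg(mode)
  varied_conc <- parse_conc(varied_conc)
  n <- length(varied_conc)
  if (n < 4L) stop("titration_series: need at least 4 titration points")
  if (length(signal) != n)
    stop("titration_series: signal length must match varied_conc")
  if (!is.null(control_signal) && length(control_signal) != n)
    stop("titration_series: control_signal length must match varied_conc")
  if (any(varied_conc < 0)) stop("titration_series: concentrations must be >= 0")
  if (is.unsorted(varied_conc, strictly = TRUE))
    stop("titration_series: varied_conc must be strictly increasing")
  fixed <- lapply(fixed, parse_conc)
  need <- if (mode == "direct") "receptor" else c("receptor", "ligand")
  miss <- setdiff(need, names(fixed))
  if (length(miss))
    stop("titration_series: 'fixed' must name: ", paste(miss, collapse = ", "))
  if (!is.null(known_kd_reporter)) known_kd_reporter <- parse_conc(known_kd_reporter)
  structure(list(mode = mode, varied_conc = varied_conc,
                 signal = as.numeric(signal),
                 control_signal = if (is.null(control_signal)) NULL else as.numeric(control_signal),
                 fixed = fixed, known_kd_reporter = known_kd_reporter),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("SPA titration (%s mode), %d points, varied %.3g-%.3g M\n",
              x$mode, length(x$varied_conc),
              min(x$varied_conc), max(x$varied_conc)))
  invisible(x)
}

#' Subtract control counts from raw counts
#'
#' The SPA signal is corrected by subtraction of a control series recorded
#' without the fusion protein.  Negative corrected values are noise and
#' are preserved as-is.
#'
#' @param raw,control equal-length count vectors.
#' @return corrected counts.
#' @export
correct_signal <- function(raw, control) {
  if (length(raw) != length(control))
    stop("correct_signal: raw and control must have equal length")
  as.numeric(raw) - as.numeric(control)
}

#' Express a signal as percent of its maximum
#'
#' Display-only normalization (binding curves are plotted as percent of
#' maximum signal); fitting always operates on corrected counts.
#'
#' @param signal counts, with \code{max(signal) > 0}.
#' @return signal scaled so its maximum is exactly 100.
#' @export
normalize_percent_max <- function(signal) {
  m <- max(signal)
  if (!is.finite(m) || m <= 0)
    stop("normalize_percent_max: maximum signal must be positive")
  # divide first: x/max(x) is exactly 1 at the maximum, so the maximum
  # normalized value is exactly 100
  100 * (signal / m)
}

# Receptor occupancy at one titration point.  Direct: ligand varied.
# Competition: competitor varied against the fixed reporter pair; the
# observable is the reporter-ligand complex (only RL scintillates).
.spa_fraction <- function(mode, conc, fixed, kd, kd_reporter = NULL) {
  if (mode == "direct") {
    st <- solve_binary(fixed$receptor, conc, kd)
    fraction_bound(st, "receptor")
  } else {
    sys <- binding_system(fixed$receptor, fixed$ligand,
                          kd_ligand = kd_reporter,
                          competitor_total = conc, kd_competitor = kd)
    st <- solve_competition(sys)
    st$complex_RL / sys$receptor_total
  }
}

#' Forward-model an SPA signal
#'
#' signal_i = s_max * occupancy_i + background + nonspecific_slope * conc_i
#' where occupancy is the exactly solved bound fraction of the
#' bead-immobilized receptor at point i.  The linear term models
#' nonspecific signal at high protein concentrations; it defaults to 0
#' both here and in fitting.
#'
#' @param mode \code{"direct"} or \code{"competition"}.
#' @param varied_conc concentrations of the varied species (molar).
#' @param kd dissociation constant of the varied interaction (molar).
#' @param fixed named list as in \code{\link{titration_series}}.
#' @param s_max full-occupancy signal (counts).
#' @param background counts at zero occupancy.
#' @param nonspecific_slope counts per molar of varied species.
#' @param kd_reporter reporter Kd (competition mode only).
#' @return numeric vector of noise-free counts.
#' @export
simulate_signal <- function(mode, varied_conc, kd, fixed,
                            s_max, background = 0, nonspecific_slope = 0,
                            kd_reporter = NULL) {
  if (s_max < 0 || background < 0 || nonspecific_slope < 0)
    stop("simulate_signal: signal parameters must be >= 0")
  varied_conc <- parse_conc(varied_conc)
  kd <- parse_conc(kd)
  fixed <- lapply(fixed, parse_conc)
  if (mode == "competition" && is.null(kd_reporter))
    stop("simulate_signal: competition mode needs kd_reporter")
  if (!is.null(kd_reporter)) kd_reporter <- parse_conc(kd_reporter)
  occ <- vapply(varied_conc, .spa_fraction, numeric(1),
                mode = mode, fixed = fixed, kd = kd, kd_reporter = kd_reporter)
  s_max * occ + background + nonspecific_slope * varied_conc
}

.fit_result <- function(kd_hat, kd_se, s_max, background, converged,
                        residual_rms, mode, fit) {
  structure(list(kd_hat = kd_hat, kd_se = kd_se, s_max = s_max,
                 background = background, converged = converged,
                 residual_rms = residual_rms, mode = mode, fit = fit),
            class = "spa_fit")
}

#' @export
print.spa_fit <- function(x, ...) {
  cat(sprintf("SPA %s fit: Kd = %.4g +/- %.2g M  (s_max %.4g, background %.4g)\n",
              x$mode, x$kd_hat, x$kd_se, x$s_max, x$background))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

# Shared Levenberg-Marquardt machinery.  Kd is fitted on the log10 scale
# (positivity, better conditioning over the nM-uM span); its standard
# error is mapped back by the delta method.  Weights: uniform, or
# 1/signal (quasi-Poisson) for raw count data.
.fit_spa <- function(series, mode, kd_reporter = NULL,
                     weights = c("uniform", "poisson"),
                     fit_slope = FALSE) {
  weights <- match.arg(weights)
  y <- series$signal
  if (!is.null(series$control_signal))
    y <- correct_signal(y, series$control_signal)
  conc <- series$varied_conc
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    stop("unidentifiable fit: no signal gradient across the series")
  w <- if (weights == "uniform") rep(1, length(y)) else 1 / pmax(y, max(y) * 1e-3)

  # initial values: Kd at the half-maximal corrected signal
  if (mode == "direct") {
    half <- min(y) + 0.5 * diff(range(y))
    idx <- which.min(abs(y - half))
    kd0 <- max(conc[idx], 1e-12)
    smax0 <- diff(range(y)); bg0 <- max(min(y), 0)
  } else {
    half <- min(y) + 0.5 * diff(range(y))
    idx <- which.min(abs(y - half))
    kd0 <- max(conc[idx], 1e-12)
    smax0 <- diff(range(y)) /
      max(.spa_fraction("competition", 0, series$fixed, kd0, kd_reporter), 1e-6)
    bg0 <- max(min(y), 0)
  }

  model <- function(p) {
    kd <- 10^p[["log_kd"]]
    occ <- vapply(conc, .spa_fraction, numeric(1), mode = mode,
                  fixed = series$fixed, kd = kd, kd_reporter = kd_reporter)
    mu <- p[["s_max"]] * occ + p[["background"]]
    if (fit_slope) mu <- mu + p[["slope"]] * conc
    mu
  }
  p0 <- c(log_kd = log10(kd0), s_max = smax0, background = bg0)
  if (fit_slope) p0 <- c(p0, slope = 0)
  resfun <- function(p) sqrt(w) * (y - model(p))
  fit <- minpack.lm::nls.lm(par = p0, fn = resfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  converged <- fit$info %in% 1:4
  res <- resfun(p)
  dof <- max(length(y) - length(p), 1)
  sigma2 <- sum(res^2) / dof
  # covariance from a central-difference Jacobian with absolute step
  # floors (nls.lm's relative steps degenerate when a parameter sits
  # near zero, e.g. the background on noise-free data)
  jac <- vapply(seq_along(p), function(k) {
    h <- max(1e-7, 1e-6 * abs(p[k]))
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    sqrt(w) * (model(pp) - model(pm)) / (2 * h)
  }, numeric(length(y)))
  covmat <- tryCatch(sigma2 * solve(crossprod(jac)), error = function(e) NULL)
  if (!is.null(covmat)) dimnames(covmat) <- list(names(p), names(p))
  kd_hat <- 10^p[["log_kd"]]
  kd_se <- if (is.null(covmat)) NA_real_ else {
    se_log <- sqrt(max(covmat["log_kd", "log_kd"], 0))
    kd_hat * log(10) * se_log            # delta method
  }
  .fit_result(kd_hat = kd_hat, kd_se = kd_se,
              s_max = p[["s_max"]], background = p[["background"]],
              converged = converged,
              residual_rms = sqrt(mean((y - model(p))^2)),
              mode = mode, fit = fit)
}

#' Fit a direct SPA titration
#'
#' Weighted least-squares fit of the exact-depletion binding isotherm to a
#' direct titration, floating Kd, the full-occupancy signal and the
#' background.  The reported \code{kd_se} is the standard error from the
#' local covariance of the fit (the "curve-fitting error" convention of
#' +/- reporting).
#'
#' @param series a direct-mode \code{\link{titration_series}}.
#' @param weights \code{"uniform"} (default) or \code{"poisson"}
#'   (1/signal, for raw counts).
#' @param fit_slope also float a linear nonspecific-signal term
#'   (default FALSE: nonspecific signal is handled by restricting the
#'   concentration range, not by modelling).
#' @return an object of class \code{"spa_fit"} with \code{kd_hat},
#'   \code{kd_se}, \code{s_max}, \code{background}, \code{converged},
#'   \code{residual_rms}.
#' @export
fit_direct <- function(series, weights = "uniform", fit_slope = FALSE) {
  if (!inherits(series, "titration_series") || series$mode != "direct")
    stop("fit_direct: need a direct-mode titration_series")
  .fit_spa(series, "direct", weights = weights, fit_slope = fit_slope)
}

#' Fit a competition SPA titration
#'
#' Fits the competitor Kd (plus signal scale and background) with the
#' reporter-pair Kd held fixed at its independently determined value; the
#' three-species equilibrium is solved exactly at every iteration, so the
#' fit is valid under ligand depletion where Cheng-Prusoff is not.
#'
#' @param series a competition-mode \code{\link{titration_series}} with
#'   \code{known_kd_reporter} set.
#' @inheritParams fit_direct
#' @return an object of class \code{"spa_fit"}.
#' @export
fit_competition <- function(series, weights = "uniform", fit_slope = FALSE) {
  if (!inherits(series, "titration_series") || series$mode != "competition")
    stop("fit_competition: need a competition-mode titration_series")
  if (is.null(series$known_kd_reporter))
    stop("fit_competition: known_kd_reporter is required")
  pos <- series$varied_conc[series$varied_conc > 0]
  if (length(pos) == 0)
    stop("unidentifiable fit: competitor concentration is zero everywhere")
  if (max(pos) / min(pos) < 10)
    warning("fit_competition: competitor range spans < 10-fold; Kd may be poorly constrained")
  .fit_spa(series, "competition", kd_reporter = series$known_kd_reporter,
           weights = weights, fit_slope = fit_slope)
}

#' Read an SPA titration from CSV
#'
#' Expected columns: \code{varied_conc}, \code{signal} and optionally
#' \code{control}.  Concentrations may carry unit suffixes (nM/uM/mM) or
#' be plain molar numbers; \code{conc_unit} applies one unit to bare
#' numbers.
#'
#' @param path CSV file path.
#' @param mode,fixed,known_kd_reporter passed to
#'   \code{\link{titration_series}}.
#' @param conc_unit optional unit suffix applied to numeric
#'   concentrations (e.g. \code{"uM"}).
#' @return a \code{titration_series}.
#' @export
read_titration_csv <- function(path, mode, fixed = list(),
                               known_kd_reporter = NULL, conc_unit = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("varied_conc", "signal") %in% names(df)))
    stop("read_titration_csv: need columns varied_conc, signal")
  conc <- df$varied_conc
  if (!is.null(conc_unit) && is.numeric(conc))
    conc <- parse_conc(paste0(conc, conc_unit))
  titration_series(mode = mode, varied_conc = conc, signal = df$signal,
                   control_signal = df[["control"]],
                   fixed = fixed, known_kd_reporter = known_kd_reporter)
}
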