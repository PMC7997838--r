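#' Gompertz biomass forcing
#'
#' Biomass in the batch reactor is modeled as an exogenous forcing, not as a
#' state variable: growth is driven by the non-aromatic substrates in the
#' hydrolysate, so the aromatic network does not feed back on it. We use the
#' modified (Zwietering) Gompertz parameterization
#' \deqn{X(t) = A \exp\left(-\exp\left(\frac{\mu e}{A}(\lambda - t) + 1\right)\right)}
#' with asymptote `A` (mg/l), maximum growth rate `mu` (mg l^-1 h^-1) and
#' lag time `lag` (h) — the standard convention in microbiology because its
#' parameters are directly interpretable from a growth curve.
#'
#' @param A asymptotic biomass, mg/l, `> 0`.
#' @param mu maximum growth rate, mg l^-1 h^-1, `> 0`.
#' @param lag lag time, h, `>= 0`.
#' @param od_to_biomass conversion from OD600 to mg/l dry weight, used when
#'   observations arrive as optical density. Default 500 mg/l per OD unit.
#' @return An object of class `biomass_model`.
#' @seealso [gompertz_biomass()], [fit_biomass()]
#' @export
biomass_model <- function(A, mu, lag, od_to_biomass = 500) {
  if (!is.finite(A) || A <= 0) abort("`A` must be > 0")
  if (!is.finite(mu) || mu <= 0) abort("`mu` must be > 0")
  if (!is.finite(lag) || lag < 0) abort("`lag` must be >= 0")
  if (!is.finite(od_to_biomass) || od_to_biomass <= 0) {
    abort("`od_to_biomass` must be > 0")
  }
  structure(list(A = A, mu = mu, lag = lag, od_to_biomass = od_to_biomass),
            class = "biomass_model")
}

#' Evaluate the Gompertz biomass curve
#'
#' @param t time(s), h, `>= 0`.
#' @param bm a [biomass_model()].
#' @return Biomass concentration(s) X(t), mg/l; `0 < X(t) <= A`,
#'   non-decreasing in `t`.
#' @export
gompertz_biomass <- function(t, bm) {
  if (!inherits(bm, "biomass_model")) abort("`bm` must be a biomass_model")
  if (any(t < 0)) abort("`t` must be >= 0")
  bm$A * exp(-exp(bm$mu * exp(1) / bm$A * (bm$lag - t) + 1))
}

#' @export
print.biomass_model <- function(x, ...) {
  cat(sprintf(
    "<biomass_model> Gompertz: A = %.4g mg/l, mu = %.4g mg/l/h, lag = %.4g h (OD600 x %.4g)\n",
    x$A, x$mu, x$lag, x$od_to_biomass))
  invisible(x)
}

#' Fit a Gompertz curve to biomass observations
#'
#' Least-squares fit of the modified Gompertz parameters (A, mu, lag) to a
#' biomass time series, via Levenberg-Marquardt with data-driven starting
#' values (A from the largest observation, mu from the steepest observed
#' rise, lag from the last time before growth reaches 10% of the maximum).
#' OD600 readings are converted to mg/l before fitting.
#'
#' Near-constant series make mu and lag unidentifiable; such fits are
#' flagged (`converged = FALSE` in the `fit` attribute, with a warning) and
#' a degenerate model close to the constant level is returned rather than an
#' error.
#'
#' @param data data frame with column `time_h` and either `biomass_mg_per_l`
#'   or `od600`; at least 4 rows.
#' @param od_to_biomass conversion factor applied to `od600`, mg/l per OD.
#' @return A [biomass_model()] carrying a `fit` attribute:
#'   `list(rss, converged, n_obs, message)`.
#' @export
fit_biomass <- function(data, od_to_biomass = 500) {
  data <- tibble::as_tibble(data)
  if (!"time_h" %in% names(data)) abort("`data` needs a `time_h` column")
  if ("biomass_mg_per_l" %in% names(data)) {
    y <- data$biomass_mg_per_l
  } else if ("od600" %in% names(data)) {
    y <- data$od600 * od_to_biomass
  } else {
    abort("`data` needs a `biomass_mg_per_l` or `od600` column")
  }
  t <- data$time_h
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 4) abort("need at least 4 biomass observations")
  if (any(y < 0)) abort("biomass observations must be >= 0")

  degenerate <- function(msg) {
    warn(paste0("Gompertz fit degenerate: ", msg))
    bm <- biomass_model(A = max(mean(y), .Machine$double.eps), mu = 1e-8,
                        lag = 0, od_to_biomass = od_to_biomass)
    attr(bm, "fit") <- list(rss = sum((y - mean(y))^2), converged = FALSE,
                            n_obs = length(y), message = msg)
    bm
  }
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1)) {
    return(degenerate("biomass series is constant; mu and lag unidentifiable"))
  }

  A0 <- max(y)
  slopes <- diff(y) / diff(t)
  mu0 <- max(slopes, 1e-6)
  lag0 <- max(t[which(y >= 0.1 * A0)[1]] - 0.1 * A0 / mu0, 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-exp(mu * exp(1) / A * (lag - t) + 1)),
      start = list(A = A0, mu = mu0, lag = lag0),
      lower = c(A = 1e-8, mu = 1e-10, lag = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(degenerate(conditionMessage(fit)))
  est <- stats::coef(fit)
  bm <- biomass_model(A = est[["A"]], mu = est[["mu"]], lag = est[["lag"]],
                      od_to_biomass = od_to_biomass)
  attr(bm, "fit") <- list(rss = sum(stats::residuals(fit)^2), converged = TRUE,
                          n_obs = length(y), message = "converged")
  bm
}
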