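#' Simplified Vogel-Fulcher-Tammann interpolation
#'
#' Over a moderate temperature range the logarithm of a liquid's viscosity is
#' close to linear in 1/T (the simplified VFT relation). Given measured
#' values at two or more temperatures, this regresses ln(value) on 1/T and
#' evaluates the regression at the query temperatures.
#'
#' @param temperatures experimental temperatures (K), at least 2 distinct.
#' @param values strictly positive values (e.g. viscosities, Pa s) at
#'   `temperatures`.
#' @param t_query temperatures at which to interpolate (K).
#' @return Interpolated values at `t_query`.
#' @examples
#' vft_interpolate(c(288.15, 308.15), c(1.14e-3, 0.72e-3), 298.15)
#' @export
vft_interpolate <- function(temperatures, values, t_query) {
  if (length(temperatures) != length(values) ||
      length(unique(temperatures)) < 2L)
    stop_trapcal("need values at >= 2 distinct temperatures", "parameter_error")
  if (any(values <= 0))
    stop_trapcal("values must be strictly positive for the log-linear regression",
                 "sign_error")
  fit <- stats::lm(log(values) ~ I(1 / temperatures))
  exp(fit$coefficients[[1L]] + fit$coefficients[[2L]] / t_query)
}

#' Built-in water viscosity reference
#'
#' `water_viscosity_table()` returns dynamic viscosity of pure water from
#' 15 to 35 degrees C in 1 K steps, generated from the standard
#' three-parameter Vogel correlation for water,
#' eta = 0.02939 exp(507.88/(T - 149.3)) mPa s, which reproduces handbook
#' values to a fraction of a percent over this range. `water_viscosity()`
#' evaluates the reference at arbitrary in-range temperatures through the
#' simplified VFT regression of the table ([vft_interpolate()]).
#'
#' @param temperature query temperature (K), within 288.15-308.15.
#' @return `water_viscosity_table()`: a data frame with `temperature_k` and
#'   `eta_pa_s`; `water_viscosity()`: dynamic viscosity (Pa s).
#' @examples
#' water_viscosity(297.25)    # ~0.910e-3 Pa s
#' @export
water_viscosity_table <- function() {
  tk <- seq(288.15, 308.15, by = 1)
  data.frame(temperature_k = tk,
             eta_pa_s = 0.02939e-3 * exp(507.88 / (tk - 149.3)))
}

#' @rdname water_viscosity_table
#' @export
water_viscosity <- function(temperature) {
  tab <- water_viscosity_table()
  if (any(temperature < min(tab$temperature_k) |
          temperature > max(tab$temperature_k)))
    stop_trapcal("temperature outside the 288.15-308.15 K reference range",
                 "extrapolation_error")
  vft_interpolate(tab$temperature_k, tab$eta_pa_s, temperature)
}

#' Excess viscosity of a binary mixture
#'
#' The deviation of the measured mixture viscosity from the mole-fraction
#' weighted linear combination of the pure components:
#' \eqn{\eta^E = \eta_{exp} - \eta_{lin}}. May be negative.
#'
#' @param eta_exp experimental mixture viscosity (Pa s).
#' @param eta_lin linear-mixture baseline (Pa s), see
#'   [linear_mixture_viscosity()].
#' @return Excess viscosity (Pa s).
#' @export
excess_viscosity <- function(eta_exp, eta_lin) {
  if (any(!is.finite(eta_exp)) || any(!is.finite(eta_lin)))
    stop_trapcal("inputs must be finite", "parameter_error")
  eta_exp - eta_lin
}

#' Least-squares polynomial fit of the excess viscosity isotherm
#'
#' Fits the excess viscosity at one temperature as a polynomial in the molar
#' fraction (order 3-6, as the smoothness of the isotherm dictates). The
#' power basis is centred at x = 0.5 for conditioning.
#'
#' @param x_b molar fractions of component B.
#' @param eta_excess excess viscosities (Pa s) at `x_b`.
#' @param order polynomial order, 3 to 6, needing `order + 1` distinct
#'   `x_b` values.
#' @return Object of class `excess_polynomial` with `coefficients` (in the
#'   centred basis), `order`, `fitted`, `residuals`; evaluate with
#'   `predict()`.
#' @export
fit_excess_polynomial <- function(x_b, eta_excess, order) {
  if (!order %in% 3:6)
    stop_trapcal("polynomial order must be between 3 and 6", "parameter_error")
  if (length(unique(x_b)) < order + 1L)
    stop_trapcal(sprintf("need >= %d distinct molar fractions for order %d (try a lower order)",
                         order + 1L, order), "fit_error")
  X <- outer(x_b - 0.5, 0:order, `^`)
  qr_ <- qr(X)
  if (qr_$rank < order + 1L)
    stop_trapcal("rank-deficient design: reduce the polynomial order", "fit_error")
  cf <- qr.coef(qr_, eta_excess)
  fitted <- as.numeric(X %*% cf)
  structure(list(coefficients = cf, order = order, x_b = x_b,
                 fitted = fitted, residuals = eta_excess - fitted),
            class = "excess_polynomial")
}

#' @export
predict.excess_polynomial <- function(object, x_b, ...) {
  as.numeric(outer(x_b - 0.5, 0:object$order, `^`) %*% object$coefficients)
}

#' Mixed-solvent viscosity model
#'
#' Builds the composition-temperature viscosity surface of a binary mixture
#' from experimental data: pure-component tables give \eqn{\eta_A(T)} and
#' \eqn{\eta_B(T)} (interpolated in temperature by the simplified VFT
#' relation), each experimental isotherm yields an excess-viscosity
#' polynomial in the molar fraction, and the isotherm series is interpolated
#' across temperature through a log-linear (or, when the excess changes sign
#' along the series, linear) regression in 1/T.
#'
#' @param data a data frame with columns `x_b` (molar fraction of component
#'   B), `temperature_k` and `eta_pa_s`; rows with `x_b` 0 or 1 are the pure
#'   components. See [read_viscosity_dataset()].
#' @param order excess-polynomial order (3-6).
#' @return Object of class `viscosity_model`.
#' @seealso [linear_mixture_viscosity()], [mixture_viscosity()]
#' @export
viscosity_model <- function(data, order = 4) {
  data <- as.data.frame(data)
  need <- c("x_b", "temperature_k", "eta_pa_s")
  if (!all(need %in% names(data)))
    stop_trapcal("data needs columns x_b, temperature_k, eta_pa_s", "format_error")
  if (any(data$x_b < 0 | data$x_b > 1))
    stop_trapcal("molar fractions must lie in [0, 1]", "parameter_error")
  if (any(data$eta_pa_s <= 0))
    stop_trapcal("viscosities must be positive", "parameter_error")
  pure_a <- data[data$x_b == 0, ]
  pure_b <- data[data$x_b == 1, ]
  if (nrow(pure_a) < 2L || nrow(pure_b) < 2L)
    stop_trapcal("need pure-component rows (x_b = 0 and 1) at >= 2 temperatures",
                 "format_error")
  mix <- data[data$x_b > 0 & data$x_b < 1, ]
  temps <- sort(unique(mix$temperature_k))

  isotherms <- lapply(temps, function(tj) {
    pts <- mix[mix$temperature_k == tj, ]
    ea <- vft_interpolate(pure_a$temperature_k, pure_a$eta_pa_s, tj)
    eb <- vft_interpolate(pure_b$temperature_k, pure_b$eta_pa_s, tj)
    lin <- ea * (1 - pts$x_b) + eb * pts$x_b
    exc <- excess_viscosity(pts$eta_pa_s, lin)
    # the excess vanishes at the pure endpoints by definition
    fit_excess_polynomial(c(0, pts$x_b, 1), c(0, exc, 0), order)
  })
  structure(list(pure_a = pure_a, pure_b = pure_b,
                 temperatures = temps, isotherms = isotherms,
                 order = order,
                 t_range = range(data$temperature_k),
                 data = data),
            class = "viscosity_model")
}

#' @export
print.viscosity_model <- function(x, ...) {
  cat(sprintf("Binary-mixture viscosity model: %d isotherm(s) at %s K, excess polynomial order %d\n",
              length(x$temperatures),
              paste(format(x$temperatures), collapse = ", "), x$order))
  invisible(x)
}

check_t_range <- function(temperature, model, extrapolate) {
  if (!extrapolate &&
      (temperature < model$t_range[1L] || temperature > model$t_range[2L]))
    stop_trapcal(sprintf(
      "temperature %g K outside the data range [%g, %g] K (set extrapolate = TRUE to override)",
      temperature, model$t_range[1L], model$t_range[2L]), "extrapolation_error")
}

#' Linear (ideal) mixture viscosity
#'
#' The mole-fraction weighted average of the pure-component viscosities,
#' \eqn{\eta_{lin}(x_B, T) = \eta_A(T)(1-x_B) + \eta_B(T)x_B}, with the pure
#' values taken from their simplified-VFT temperature regressions.
#'
#' @param x_b molar fraction of component B, in [0, 1].
#' @param temperature temperature (K), inside the data range unless
#'   `extrapolate`.
#' @param model a [viscosity_model()].
#' @param extrapolate allow temperatures outside the data range.
#' @return Viscosity (Pa s).
#' @export
linear_mixture_viscosity <- function(x_b, temperature, model, extrapolate = FALSE) {
  stopifnot(inherits(model, "viscosity_model"))
  if (x_b < 0 || x_b > 1) stop_trapcal("x_b must lie in [0, 1]", "parameter_error")
  check_t_range(temperature, model, extrapolate)
  ea <- vft_interpolate(model$pure_a$temperature_k, model$pure_a$eta_pa_s, temperature)
  eb <- vft_interpolate(model$pure_b$temperature_k, model$pure_b$eta_pa_s, temperature)
  ea * (1 - x_b) + eb * x_b
}

#' Mixture viscosity at any composition and temperature
#'
#' Evaluates \eqn{\eta(x_B, T) = \eta_{lin}(x_B, T) + \eta^E(x_B, T)}: the
#' excess at `x_b` is read off every experimental isotherm polynomial and the
#' resulting series is carried to `temperature` by a log-linear regression in
#' 1/T (on \eqn{|\eta^E|}, all isotherm values sharing one sign) or, if the
#' series changes sign, by a plain linear regression in 1/T with a warning.
#' At the pure endpoints the model reduces to the pure components exactly.
#'
#' @inheritParams linear_mixture_viscosity
#' @return Viscosity (Pa s).
#' @export
mixture_viscosity <- function(x_b, temperature, model, extrapolate = FALSE) {
  stopifnot(inherits(model, "viscosity_model"))
  if (x_b < 0 || x_b > 1) stop_trapcal("x_b must lie in [0, 1]", "parameter_error")
  check_t_range(temperature, model, extrapolate)
  lin <- linear_mixture_viscosity(x_b, temperature, model, extrapolate)
  if (x_b == 0 || x_b == 1) return(lin)
  ex_series <- vapply(model$isotherms, function(f) predict(f, x_b), 0)
  nt <- length(model$temperatures)
  if (nt == 1L) {
    exq <- ex_series
  } else if (all(ex_series > 0) || all(ex_series < 0)) {
    sgn <- sign(ex_series[1L])
    exq <- sgn * vft_interpolate(model$temperatures, abs(ex_series), temperature)
  } else {
    warn_trapcal("excess viscosity changes sign across isotherms: using linear interpolation in 1/T",
                 "sign_warning")
    fit <- stats::lm(ex_series ~ I(1 / model$temperatures))
    exq <- fit$coefficients[[1L]] + fit$coefficients[[2L]] / temperature
  }
  lin + exq
}

#' @rdname viscosity_model
#' @param path CSV file with header `component,x_b,temperature_k,eta_pa_s`
#'   (the component label is informational; pure rows have `x_b` 0 or 1).
#' @export
read_viscosity_dataset <- function(path) {
  d <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("x_b", "temperature_k", "eta_pa_s") %in% names(d)))
    stop_trapcal("dataset needs columns x_b, temperature_k, eta_pa_s", "format_error")
  d
}
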