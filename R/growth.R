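# Cumulative submission time series and growth-curve fitting.
#
# Cumulative microarray submissions follow a logistic (saturating) curve
# y = L / (1 + exp(-k (x - x0))); cumulative RNA-seq submissions are
# well described by a cubic polynomial. Cubic fitting is done on a
# CENTERED year coordinate: raw-year cubic coefficients suffer
# catastrophic cancellation (years ~2000 cubed reach 8e9), so raw-basis
# coefficients are derived outputs, never the fitting basis.

#' Build a cumulative yearly submission series
#'
#' Bins records by calendar year of submission and cumulates the counts.
#' Records with missing dates are dropped with a warning; intermediate
#' years with no submissions appear with a carried-forward cumulative
#' count.
#'
#' @param records list of [gsm_record()] objects.
#' @param technology optional filter: `"microarray"` or `"rnaseq"`
#'   (matched against each record's `technology_hint`).
#' @return list of class `growth_series`: numeric `x` (years, strictly
#'   increasing), `y` (cumulative counts, non-decreasing), `technology`.
#' @export
cumulative_by_year <- function(records, technology = NULL) {
  if (!is.null(technology)) {
    records <- Filter(function(r) r$technology_hint == technology, records)
  }
  dates <- as.Date(vapply(records, function(r) as.character(r$submission_date),
                          character(1)))
  if (any(is.na(dates))) {
    warning(sum(is.na(dates)), " record(s) without a valid submission date ",
            "excluded from the growth series", call. = FALSE)
  }
  dates <- dates[!is.na(dates)]
  if (!length(dates)) {
    stop("empty series: no dated records",
         if (!is.null(technology)) paste0(" for technology '", technology, "'"))
  }
  yr <- as.integer(format(dates, "%Y"))
  years <- seq(min(yr), max(yr))
  counts <- vapply(years, function(y) sum(yr == y), integer(1))
  structure(list(x = as.numeric(years), y = cumsum(counts),
                 technology = technology %||% "all"),
            class = "growth_series")
}

#' Construct a logistic growth fit object
#'
#' `L` is the upper asymptote (records), `k` the growth rate (1/year),
#' `x0` the midpoint/inflection year.
#'
#' @param L,k,x0 logistic parameters.
#' @param r_squared optional goodness of fit.
#' @return object of class `logistic_fit`.
#' @export
logistic_fit <- function(L, k, x0, r_squared = NA_real_) {
  stopifnot(L > 0)
  structure(list(L = L, k = k, x0 = x0, r_squared = r_squared),
            class = "logistic_fit")
}

#' Evaluate a logistic growth model
#'
#' @param fit a [logistic_fit()].
#' @param x year(s), fractional allowed.
#' @return model value `L / (1 + exp(-k (x - x0)))`.
#' @export
logistic_value <- function(fit, x) {
  fit$L / (1 + exp(-fit$k * (x - fit$x0)))
}

#' Asymptote of a logistic growth model
#'
#' The closed-form limit of [logistic_value()] as x tends to infinity:
#' exp(-k(x - x0)) vanishes for k > 0, leaving L.
#'
#' @param fit a [logistic_fit()].
#' @return the limiting number of records, `L`.
#' @export
asymptote <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$k <= 0) stop("asymptote undefined for non-positive growth rate")
  fit$L / (1 + exp(-fit$k * .Machine$double.xmax^0.1)) # underflows to L/1
}

#' Inflection year of a logistic growth model
#'
#' The root of the second derivative of the logistic; analytically equal
#' to the midpoint parameter x0.
#'
#' @param fit a [logistic_fit()].
#' @return inflection year.
#' @export
inflection_year <- function(fit) {
  if (fit$k == 0) stop("undefined inflection: zero growth rate")
  fit$x0
}

#' Fit a logistic growth model by nonlinear least squares
#'
#' Initialization: L0 = 1.05 max(y), x0_0 = median(x), k0 = 0.5, with
#' bounds L > 0, k > 0 (port algorithm). Convergence tolerance 1e-8 on
#' relative parameter change. Internally the year coordinate is centered
#' at median(x) for conditioning.
#'
#' @param series a [cumulative_by_year()] result, or a list with numeric
#'   `x` and `y`.
#' @return a [logistic_fit()] with `r_squared` populated.
#' @export
fit_logistic <- function(series) {
  x <- series$x; y <- series$y
  if (length(x) < 4) stop("fit error: logistic fit needs >= 4 points")
  if (stats::sd(y) == 0) {
    stop("fit error: constant series, logistic parameters unidentifiable")
  }
  xc <- x - stats::median(x)
  start <- list(L = 1.05 * max(y), k = 0.5, x0 = 0)
  fit <- tryCatch(
    stats::nls(y ~ L / (1 + exp(-k * (xc - x0))), start = start,
               algorithm = "port",
               lower = c(L = .Machine$double.eps, k = .Machine$double.eps,
                         x0 = -Inf),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            minFactor = 1e-12,
                                            warnOnly = FALSE)),
    error = function(e) {
      stop("fit error: logistic least squares did not converge (",
           conditionMessage(e), "); n = ", length(x),
           ", y range [", min(y), ", ", max(y), "]")
    })
  p <- stats::coef(fit)
  resid <- y - p[["L"]] / (1 + exp(-p[["k"]] * (xc - p[["x0"]])))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  logistic_fit(L = p[["L"]], k = p[["k"]],
               x0 = p[["x0"]] + stats::median(x), r_squared = r2)
}

#' Construct a cubic growth fit object
#'
#' Coefficients live on the centered coordinate `xc = x - center`;
#' raw-year coefficients are derived via binomial expansion.
#'
#' @param a3,a2,a1,a0 centered-basis coefficients (cubic first).
#' @param center the year offset subtracted before evaluation.
#' @param r_squared optional goodness of fit.
#' @return object of class `cubic_fit`.
#' @export
cubic_fit <- function(a3, a2, a1, a0, center = 0, r_squared = NA_real_) {
  structure(list(a3 = a3, a2 = a2, a1 = a1, a0 = a0, center = center,
                 r_squared = r_squared),
            class = "cubic_fit")
}

#' Evaluate a cubic growth model
#'
#' @param fit a [cubic_fit()].
#' @param x year(s).
#' @return model value on the raw-year scale.
#' @export
cubic_value <- function(fit, x) {
  xc <- x - fit$center
  ((fit$a3 * xc + fit$a2) * xc + fit$a1) * xc + fit$a0
}

#' Raw-basis coefficients of a cubic fit
#'
#' Expands the centered polynomial about zero; at 2000-scale years these
#' coefficients are ill-conditioned to print at low precision, which is
#' why they are a derived output only.
#'
#' @param fit a [cubic_fit()].
#' @return named numeric vector `c(a3, a2, a1, a0)` on raw years.
#' @export
cubic_raw_coefficients <- function(fit) {
  c0 <- -fit$center
  c(a3 = fit$a3,
    a2 = fit$a2 + 3 * fit$a3 * c0,
    a1 = fit$a1 + 2 * fit$a2 * c0 + 3 * fit$a3 * c0^2,
    a0 = fit$a0 + fit$a1 * c0 + fit$a2 * c0^2 + fit$a3 * c0^3)
}

#' Fit a cubic growth model by ordinary least squares
#'
#' The design matrix is built on the centered year coordinate
#' `x - mean(x)` for numerical conditioning.
#'
#' @param series a [cumulative_by_year()] result, or list with `x`, `y`.
#' @return a [cubic_fit()].
#' @export
fit_cubic <- function(series) {
  x <- series$x; y <- series$y
  if (length(x) < 5) stop("fit error: cubic fit needs >= 5 points")
  center <- mean(x)
  xc <- x - center
  X <- cbind(xc^3, xc^2, xc, 1)
  qrX <- qr(X)
  if (qrX$rank < 4) stop("fit error: rank-deficient cubic design")
  beta <- unname(qr.coef(qrX, y))
  resid <- y - X %*% beta
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  cubic_fit(beta[1], beta[2], beta[3], beta[4], center = center,
            r_squared = r2)
}

#' Model value at a year, generic over fit type
#'
#' @param fit a [logistic_fit()] or [cubic_fit()].
#' @param x year(s).
#' @return model value.
#' @export
growth_value <- function(fit, x) UseMethod("growth_value")

#' @export
growth_value.logistic_fit <- function(fit, x) logistic_value(fit, x)

#' @export
growth_value.cubic_fit <- function(fit, x) cubic_value(fit, x)

#' Projected fold change of combined record counts
#'
#' Evaluates both technology models at two years and returns the ratio of
#' combined totals, `(A(to) + B(to)) / (A(from) + B(from))`.
#'
#' @param fit_a,fit_b fitted growth models (one per technology).
#' @param year_from,year_to years to compare.
#' @return fold-change ratio.
#' @export
project_fold_change <- function(fit_a, fit_b, year_from, year_to) {
  denom <- growth_value(fit_a, year_from) + growth_value(fit_b, year_from)
  if (abs(denom) < .Machine$double.eps) {
    stop("zero denominator: no records at year_from")
  }
  (growth_value(fit_a, year_to) + growth_value(fit_b, year_to)) / denom
}
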