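test_that("cumulative_by_year bins and cumulates", {
  mk <- function(acc, date) gsm_record(acc, submission_date = as.Date(date))
  recs <- c(lapply(1:3, function(i) mk(paste0("A", i), "2001-06-01")),
            lapply(1:2, function(i) mk(paste0("B", i), "2003-02-01")))
  s <- cumulative_by_year(recs)
  expect_equal(s$x, c(2001, 2002, 2003))
  expect_equal(s$y, c(3, 3, 5))
  expect_error(cumulative_by_year(list(), "rnaseq"), "empty series")
  expect_warning(
    s2 <- cumulative_by_year(c(recs, list(gsm_record("C1")))),
    "without a valid submission date")
  expect_equal(s2$y, s$y)
})

test_that("yearly series of a generated corpus matches the manifest", {
  corp <- generate_corpus(small_config(n = 400L, seed = 31L))
  gsms <- gsm_records(corp$document)
  for (tk in c("microarray", "rnaseq")) {
    s <- cumulative_by_year(gsms, tk)
    yrs <- corp$manifest$year[corp$manifest$technology == tk]
    expected <- cumsum(vapply(s$x, function(y) sum(yrs == y), numeric(1)))
    expect_equal(s$y, expected, info = tk)
    expect_true(all(diff(s$y) >= 0))
  }
})

test_that("logistic closed forms: value, asymptote, inflection", {
  fit <- paper_logistic()
  # midpoint value is exactly L/2 (closed form L/(1+e^0))
  expect_equal(logistic_value(fit, fit$x0), 22646.895)
  expect_equal(asymptote(fit), 45293.79)
  expect_equal(inflection_year(fit), 2011.245)
  # value approaches the asymptote
  expect_equal(logistic_value(fit, 1e6), 45293.79)
  # k = 0 degenerates to L/2 everywhere; inflection undefined
  flat <- logistic_fit(L = 10, k = 0, x0 = 2000)
  expect_equal(logistic_value(flat, c(1900, 2000, 2100)), rep(5, 3))
  expect_error(inflection_year(flat), "undefined")
  expect_error(asymptote(flat), "non-positive")
})

test_that("numeric second-derivative root agrees with the analytic inflection", {
  fit <- paper_logistic()
  d2 <- function(x) {
    h <- 1e-3
    (logistic_value(fit, x + h) - 2 * logistic_value(fit, x) +
        logistic_value(fit, x - h)) / h^2
  }
  root <- stats::uniroot(d2, c(2000, 2020), tol = 1e-10)$root
  expect_equal(root, fit$x0, tolerance = 1e-6)
  # translation equivariance
  shifted <- logistic_fit(fit$L, fit$k, fit$x0 + 5)
  expect_equal(inflection_year(shifted), inflection_year(fit) + 5)
})

test_that("logistic fit recovers noiseless parameters to 1e-6 relative", {
  truth <- paper_logistic()
  x <- 2000:2025
  series <- list(x = x, y = logistic_value(truth, x))
  fit <- fit_logistic(series)
  expect_equal(fit$L, truth$L, tolerance = 1e-6)
  expect_equal(fit$k, truth$k, tolerance = 1e-6)
  expect_equal(fit$x0, truth$x0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # model value strictly increasing and bounded by L
  v <- logistic_value(fit, seq(1990, 2050, by = 0.5))
  expect_true(all(diff(v) > 0))
  expect_true(all(v < fit$L))
})

test_that("logistic fit errors on degenerate input", {
  expect_error(fit_logistic(list(x = 2000:2001, y = c(1, 2))), ">= 4")
  expect_error(fit_logistic(list(x = 2000:2010, y = rep(7, 11))),
               "constant series")
})

test_that("noisy logistic recovery: median over 100 replicates", {
  truth <- paper_logistic()
  x <- 2000:2025
  clean <- logistic_value(truth, x)
  Ls <- x0s <- numeric(100)
  for (r in 1:100) {
    set.seed(1000 + r)
    y <- clean + stats::rnorm(length(x), sd = 0.01 * truth$L)
    fit <- tryCatch(fit_logistic(list(x = x, y = y)), error = function(e) NULL)
    Ls[r] <- if (is.null(fit)) NA else fit$L
    x0s[r] <- if (is.null(fit)) NA else fit$x0
  }
  expect_lt(abs(stats::median(Ls, na.rm = TRUE) - truth$L) / truth$L, 0.05)
  expect_lt(abs(stats::median(x0s, na.rm = TRUE) - truth$x0), 0.5)
})

test_that("cubic fit recovers centered coefficients exactly on noiseless data", {
  x <- 2009:2025
  truth <- cubic_fit(a3 = 1.5, a2 = -2, a1 = 30, a0 = 100, center = mean(x))
  series <- list(x = x, y = cubic_value(truth, x))
  fit <- fit_cubic(series)
  expect_equal(fit$center, mean(x))
  expect_equal(c(fit$a3, fit$a2, fit$a1, fit$a0),
               c(truth$a3, truth$a2, truth$a1, truth$a0), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # raw-basis coefficients evaluate identically
  rc <- cubic_raw_coefficients(fit)
  xx <- c(2010.5, 2020)
  expect_equal(((rc["a3"] * xx + rc["a2"]) * xx + rc["a1"]) * xx + rc["a0"],
               cubic_value(fit, xx), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("cubic fit: linear data, year-shift insensitivity, errors", {
  x <- 2000:2010
  fit <- fit_cubic(list(x = x, y = 2 * x - 3500))
  expect_lt(abs(fit$a3), 1e-9)
  expect_lt(abs(fit$a2), 1e-9)
  # centered-basis coefficients invariant under shifting all years
  y <- (x - 2005)^3 + 5 * (x - 2005) + 20
  f1 <- fit_cubic(list(x = x, y = y))
  f2 <- fit_cubic(list(x = x + 2000, y = y))
  expect_equal(c(f1$a3, f1$a2, f1$a1, f1$a0),
               c(f2$a3, f2$a2, f2$a1, f2$a0), tolerance = 1e-8)
  expect_error(fit_cubic(list(x = 2000:2003, y = 1:4)), ">= 5")
  expect_error(fit_cubic(list(x = rep(2000, 5), y = 1:5)), "rank-deficient")
})

test_that("fold-change projection combines both technologies", {
  fa <- paper_logistic()
  fb <- cubic_fit(1, 2, 12, 0, center = 2009)
  expect_equal(project_fold_change(fa, fb, 2025, 2025), 1)
  # logistic-only corpus at saturation tends to 1
  expect_equal(project_fold_change(fa, logistic_fit(1e-9, 1, 2000),
                                   2100, 2130), 1, tolerance = 1e-6)
  # matches direct evaluation of the generator curves
  direct <- (logistic_value(fa, 2030) + cubic_value(fb, 2030)) /
    (logistic_value(fa, 2025) + cubic_value(fb, 2025))
  expect_equal(project_fold_change(fa, fb, 2025, 2030), direct)
  expect_error(project_fold_change(fb, fb, 2009, 2030), "zero denominator")
})
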