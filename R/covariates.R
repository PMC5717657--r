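#' Average a point series into time bins
#'
#' Aggregates a series of dated point measurements (e.g. oxygen-isotope
#' values) into per-bin arithmetic means. A point belongs to a bin when
#' `younger <= age < older`, so a point exactly on a shared boundary goes to
#' the older of the two bins; the oldest bin also includes its own older
#' boundary so no point inside the binned span is lost. Empty bins are
#' missing (NA).
#'
#' @param points data frame with columns `age` (Ma) and `value`.
#' @param bins a [time_bins()] series.
#' @return Named numeric vector, one value per bin.
#' @export
bin_average <- function(points, bins) {
  stopifnot(inherits(bins, "time_bins"))
  if (!all(c("age", "value") %in% names(points)))
    .input_error("point table needs columns 'age' and 'value'")
  if (any(points$age < 0)) .input_error("point ages must be >= 0 Ma")
  out <- vapply(seq_len(nrow(bins)), function(i) {
    sel <- points$age >= bins$younger[i] &
      (points$age < bins$older[i] | (i == 1L & points$age <= bins$older[i]))
    if (!any(sel)) NA_real_ else mean(points$value[sel])
  }, numeric(1))
  if (all(is.na(out))) warning("no points fall in any bin; all-missing series")
  stats::setNames(out, bins$name)
}

## internal: drop incomplete pairs, preserving order
.complete_pairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using average ranks for ties. The two-sided p-value comes
#' from the exact permutation distribution of the rank statistic when there
#' are at most 9 complete pairs, and from the t approximation
#' \eqn{t = r_S \sqrt{(n-2)/(1-r_S^2)}} otherwise. When either variable is
#' entirely tied the coefficient is reported as 0 with `all_tied = TRUE`.
#'
#' @param x,y numeric vectors (pairs with a missing member are dropped).
#' @return List with `estimate` (r_S), `p.value`, `n`, `method`, `all_tied`.
#' @export
spearman_test <- function(x, y) {
  cp <- .complete_pairs(x, y)
  if (cp$n < 3L) .input_error("need at least 3 complete pairs")
  rx <- rank(cp$x)
  ry <- rank(cp$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(estimate = 0, p.value = 1, n = cp$n,
                method = "degenerate (all ranks tied)", all_tied = TRUE))
  r <- stats::cor(rx, ry)
  n <- cp$n
  if (n <= 9L) {
    perms <- e1071::permutations(n)
    tt <- matrix(rx[perms], nrow = nrow(perms)) %*% ry
    tobs <- sum(rx * ry)
    p <- mean(abs(tt - mean(tt)) >= abs(tobs - mean(tt)) - 1e-9)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(estimate = r, p.value = min(p, 1), n = n, method = method, all_tied = FALSE)
}

#' Ordinary least-squares fit of disparity against a covariate
#'
#' Simple linear regression with the slope's two-sided t-test. A constant
#' response yields slope 0 and \eqn{R^2 = 0}; a constant predictor is an
#' input error.
#'
#' @param x,y numeric vectors (pairs with a missing member are dropped).
#' @return List with `slope`, `intercept`, `r.squared`, `p.value`, `n`.
#' @export
ols_fit <- function(x, y) {
  cp <- .complete_pairs(x, y)
  if (cp$n < 3L) .input_error("need at least 3 complete pairs")
  if (stats::sd(cp$x) == 0) .input_error("predictor is constant")
  if (stats::sd(cp$y) == 0)
    return(list(slope = 0, intercept = mean(cp$y), r.squared = 0, p.value = 1, n = cp$n))
  fit <- stats::lm(y ~ x, data = data.frame(x = cp$x, y = cp$y))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r.squared = sm$r.squared,
       p.value = sm$coefficients["x", "Pr(>|t|)"],
       n = cp$n)
}

#' GLS fit with AR(1) serial correlation across time bins
#'
#' Linear model whose residuals follow a first-order autoregressive process
#' over the ordered bin sequence, fitted via [nlme::gls()]. The correlation
#' parameter is profiled by restricted maximum likelihood by default: REML
#' removes the downward bias that plain ML incurs from estimating the
#' regression coefficients (about \eqn{-(1+3\phi)/n} plus a per-coefficient
#' penalty), which matters at time-series lengths typical of bin counts.
#' With `phi` fixed at 0 the coefficient estimates reduce to ordinary least
#' squares. Data must be supplied in temporal order; incomplete pairs are
#' dropped (the AR index follows the original bin positions).
#'
#' @param x,y numeric vectors in temporal (bin) order.
#' @param phi optional fixed AR(1) parameter in (-1, 1); `NULL` (default)
#'   profiles it.
#' @param method `"REML"` (default) or `"ML"`.
#' @return List with `slope`, `intercept`, `phi`, `p.value` (slope),
#'   `converged`, `n`, and `message` (empty when converged).
#' @export
gls_ar1_fit <- function(x, y, phi = NULL, method = c("REML", "ML")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  d <- data.frame(x = x[ok], y = y[ok], tindex = which(ok))
  if (nrow(d) < 5L) .input_error("need at least 5 complete pairs")
  cs <- if (is.null(phi)) nlme::corAR1(form = ~ tindex)
        else nlme::corAR1(value = phi, form = ~ tindex, fixed = TRUE)
  fit <- tryCatch(nlme::gls(y ~ x, data = d, correlation = cs, method = method),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(list(slope = NA_real_, intercept = NA_real_, phi = NA_real_,
                p.value = NA_real_, converged = FALSE, n = nrow(d),
                message = conditionMessage(fit)))
  phi_hat <- if (is.null(phi)) {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else phi
  tt <- summary(fit)$tTable
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       phi = phi_hat, p.value = unname(tt["x", "p-value"]),
       converged = TRUE, n = nrow(d), message = "")
}

#' First-difference association test
#'
#' Spearman test on the changes of both series across successive time bins:
#' \eqn{\Delta x_i = x_{i+1} - x_i}, likewise for y. Differences with a
#' missing endpoint are dropped.
#'
#' @param x,y numeric vectors in temporal (bin) order.
#' @return As [spearman_test()], computed on the paired differences.
#' @export
first_difference_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) .input_error("x and y must have equal length")
  if (n < 4L) .input_error("need at least 4 consecutive bins")
  dx <- diff(x)
  dy <- diff(y)
  ok <- is.finite(dx) & is.finite(dy)
  if (sum(ok) < 3L) .input_error("fewer than 3 complete difference pairs")
  spearman_test(dx[ok], dy[ok])
}

#' Correlate a disparity series with a covariate
#'
#' Runs the full battery for one comparison: Spearman rank correlation, OLS,
#' GLS with AR(1) errors, and the first-difference Spearman test, on the
#' per-bin disparity values (typically the ensemble median) against the
#' covariate series. All p-values are two-sided and unadjusted.
#'
#' @param disparity numeric per-bin disparity values (temporal order), or a
#'   `disparity_ensemble` (its `median` column is used).
#' @param covariate numeric per-bin covariate values, same bin order.
#' @param label,covariate_label row annotations for the results table.
#' @return One-row data frame: `label`, `covariate`, `n`, `r_s`, `p_spearman`,
#'   `r_squared`, `slope`, `intercept`, `p_ols`, `gls_slope`, `gls_phi`,
#'   `p_gls`, `gls_converged`, `fd_r_s`, `p_first_diff`.
#' @export
correlate_disparity <- function(disparity, covariate, label = "all",
                                covariate_label = "covariate") {
  if (inherits(disparity, "disparity_ensemble")) disparity <- disparity$median
  sp <- spearman_test(disparity, covariate)
  ol <- ols_fit(covariate, disparity)
  gl <- tryCatch(gls_ar1_fit(covariate, disparity),
                 error = function(e) list(slope = NA_real_, phi = NA_real_,
                                          p.value = NA_real_, converged = FALSE))
  fd <- tryCatch(first_difference_test(covariate, disparity),
                 error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  data.frame(label = label, covariate = covariate_label, n = sp$n,
             r_s = sp$estimate, p_spearman = sp$p.value,
             r_squared = ol$r.squared, slope = ol$slope,
             intercept = ol$intercept, p_ols = ol$p.value,
             gls_slope = gl$slope, gls_phi = gl$phi, p_gls = gl$p.value,
             gls_converged = gl$converged,
             fd_r_s = fd$estimate, p_first_diff = fd$p.value)
}

#' Read a covariate table
#'
#' Point series have columns `age`, `value`; per-bin series have columns
#' `bin`, `value` and are matched to the bin series by name.
#'
#' @param file CSV path.
#' @param bins a [time_bins()] series.
#' @return Named numeric vector aligned to `bins`.
#' @export
read_covariate <- function(file, bins) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (all(c("age", "value") %in% names(d))) return(bin_average(d, bins))
  if (all(c("bin", "value") %in% names(d))) {
    v <- d$value[match(bins$name, d$bin)]
    return(stats::setNames(v, bins$name))
  }
  .input_error("covariate table needs columns (age,value) or (bin,value)")
}
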