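# Cross-validation of computed AAP against human valence ratings: ordinary
# least squares and a 4-parameter logistic, with adjusted R-squared.

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - n_params - 1)`, the standard
#' degrees-of-freedom correction. Always `<= r2`, with equality iff
#' `r2 = 1` or `n_params = 0`.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations; must exceed `n_params + 1`.
#' @param n_params Number of fitted parameters (excluding the error
#'   variance).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, n_params) {
  if (!is_scalar_number(r2) || r2 > 1) {
    abort_sb("`r2` must be a single number <= 1", "sentibook_config_error")
  }
  if (!is_count(n) || !(is.numeric(n_params) && length(n_params) == 1L &&
                        n_params == round(n_params) && n_params >= 0)) {
    abort_sb("`n` and `n_params` must be non-negative integers",
             "sentibook_config_error")
  }
  if (n <= n_params + 1) {
    abort_sb("adjusted R-squared needs n > n_params + 1",
             "sentibook_config_error")
  }
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

# 4-parameter logistic: lower/upper asymptotes, slope, inflection point.
fpl <- function(x, lower, upper, slope, xmid) {
  lower + (upper - lower) / (1 + exp(-slope * (x - xmid)))
}

#' Fit the AAP-to-rating response curve
#'
#' Cross-validates computed word AAP against human valence ratings.
#' `"linear"` fits ordinary least squares (2 parameters). `"logistic"` fits
#' a 4-parameter logistic (lower and upper asymptote, slope, inflection) by
#' nonlinear least squares — the natural shape for ratings on a bounded
#' scale, which compress toward the scale ends. Initialization: asymptotes
#' from the rating range, inflection at the median AAP, slope from the AAP
#' spread; up to 10 deterministically jittered restarts are attempted
#' before giving up. The parameters are box-constrained (asymptotes within
#' twice the rating span, slope magnitude capped far beyond step-function
#' resolution) so sparsely sampled transition regions cannot push the fit
#' into the degenerate infinite-slope limit. For both models R-squared is
#' computed as `1 - SS_res / SS_tot` and reported with its adjusted
#' version.
#'
#' @param aap Numeric vector of computed AAP values.
#' @param ratings Numeric vector of mean human valence ratings, same
#'   length; at least 8 observations.
#' @param model_kind `"logistic"` (default) or `"linear"`.
#' @return An object of class `valence_fit`: `model_kind`, `parameters`
#'   (named: `intercept`/`slope` or `lower`/`upper`/`slope`/`xmid`), `r2`,
#'   `r2_adj`, `n`, `n_params`, `fitted`, `residuals`.
#' @export
fit_valence_curve <- function(aap, ratings,
                              model_kind = c("logistic", "linear")) {
  model_kind <- match.arg(model_kind)
  if (!is.numeric(aap) || !is.numeric(ratings) ||
      length(aap) != length(ratings)) {
    abort_sb("`aap` and `ratings` must be numeric vectors of equal length",
             "sentibook_config_error")
  }
  keep <- !is.na(aap) & !is.na(ratings)
  aap <- aap[keep]
  ratings <- ratings[keep]
  n <- length(aap)
  if (n < 8L) {
    abort_sb("curve fitting needs at least 8 complete observations",
             "sentibook_config_error")
  }
  ss_tot <- sum((ratings - mean(ratings))^2)
  if (model_kind == "linear") {
    fit <- lm(ratings ~ aap)
    params <- c(intercept = unname(coef(fit)[[1L]]),
                slope = unname(coef(fit)[[2L]]))
    fitted_vals <- unname(fitted(fit))
    n_params <- 2L
  } else {
    if (ss_tot == 0) {
      abort_sb("logistic fit needs non-constant ratings",
               "sentibook_config_error")
    }
    fit <- fit_fpl(aap, ratings)
    params <- fit$parameters
    fitted_vals <- fit$fitted
    n_params <- 4L
  }
  ss_res <- sum((ratings - fitted_vals)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      model_kind = model_kind,
      parameters = params,
      r2 = r2,
      r2_adj = adjusted_r2(r2, n, n_params),
      n = n,
      n_params = n_params,
      fitted = fitted_vals,
      residuals = ratings - fitted_vals
    ),
    class = "valence_fit"
  )
}

#' @export
print.valence_fit <- function(x, ...) {
  cat(sprintf("<valence_fit> %s fit, n = %d: R2 = %.4f, R2_adj = %.4f\n",
              x$model_kind, x$n, x$r2, x$r2_adj))
  print(round(x$parameters, 4))
  invisible(x)
}

# 4PL least squares with deterministic jittered restarts.
fit_fpl <- function(x, y, max_restarts = 10L) {
  rng_y <- range(y)
  span <- diff(rng_y)
  if (span == 0) span <- 1
  x_span <- diff(range(x))
  if (x_span == 0) x_span <- 1
  start0 <- list(
    lower = rng_y[[1L]],
    upper = rng_y[[2L]],
    slope = 6 / x_span,
    xmid = median(x)
  )
  # fixed multiplicative jitters (not RNG-dependent) so fits are reproducible
  jitters <- seq(0.5, 2, length.out = max_restarts)
  attempts <- c(list(start0), lapply(jitters, function(j) {
    list(lower = start0$lower - 0.1 * span * j,
         upper = start0$upper + 0.1 * span * j,
         slope = start0$slope * j,
         xmid = start0$xmid + (j - 1.25) * 0.2 * x_span)
  }))
  resid_fn <- function(par) {
    y - fpl(x, par[["lower"]], par[["upper"]], par[["slope"]], par[["xmid"]])
  }
  # box constraints keep the fit away from the degenerate step-function
  # limit (slope -> Inf), which least squares can drift toward when the
  # predictor leaves the transition region under-sampled; the slope bound
  # is far beyond any curve distinguishable from a step at data resolution
  slope_max <- 200 / x_span
  par_lower <- c(lower = rng_y[[1L]] - 2 * span,
                 upper = rng_y[[1L]] - 2 * span,
                 slope = -slope_max, xmid = min(x) - x_span)
  par_upper <- c(lower = rng_y[[2L]] + 2 * span,
                 upper = rng_y[[2L]] + 2 * span,
                 slope = slope_max, xmid = max(x) + x_span)
  best <- NULL
  diag_msgs <- character()
  for (st in attempts) {
    st <- pmin(pmax(unlist(st), par_lower), par_upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn,
        lower = par_lower, upper = par_upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    if (!fit$info %in% 1:3) {  # Levenberg-Marquardt convergence codes
      diag_msgs <- c(diag_msgs, fit$message)
      next
    }
    best <- fit
    break  # first converging start wins; restarts exist for robustness
  }
  if (is.null(best)) {
    abort_sb(
      paste0("4PL fit failed to converge after restarts; diagnostics: ",
             paste(unique(diag_msgs), collapse = " | ")),
      "sentibook_fit_error"
    )
  }
  cf <- best$par
  # canonical orientation: upper >= lower (flip is compensated by slope sign)
  if (cf[["upper"]] < cf[["lower"]]) {
    cf <- c(lower = cf[["upper"]], upper = cf[["lower"]],
            slope = -cf[["slope"]], xmid = cf[["xmid"]])
  }
  list(
    parameters = c(lower = cf[["lower"]], upper = cf[["upper"]],
                   slope = cf[["slope"]], xmid = cf[["xmid"]]),
    fitted = unname(fpl(x, cf[["lower"]], cf[["upper"]], cf[["slope"]],
                        cf[["xmid"]]))
  )
}
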