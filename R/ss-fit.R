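# Nonlinear least-squares fitting of the Sharpe-Schoolfield model, with
# multi-start initialisation and the fallback rule for sparse data.

#' Fit a Sharpe-Schoolfield thermal performance curve
#'
#' Least-squares fit of the four-parameter Sharpe-Schoolfield model (see
#' [ss_evaluate]) to temperature-rate observations, minimizing squared
#' residuals on the linear rate scale (optionally on the log scale).
#' `log(B0)` is optimized together with `E`, `ED - E` and `Tpk` under box
#' constraints, so `ED > E` and `B0 > 0` hold by construction.  A
#' multi-start grid over activation-energy initials protects against
#' local minima; the start with the lowest residual sum of squares wins,
#' ties going to the smaller `E`.
#'
#' Non-positive observed rates are dropped before fitting (the model is
#' strictly positive); a message reports how many.  When fewer than
#' `min_temps` distinct temperatures remain, no curve is fitted: the
#' thermal optimum falls back to the temperature of the highest directly
#' measured rate (`method = "fallback"`).  When the fitted peak lies at
#' or beyond the warmest measured temperature (rates still rising across
#' the sampled window), the fit is kept but flagged with a warning.
#'
#' @param temp assay temperatures in degrees Celsius (one per
#'   observation), or a data.frame with columns `temp` and `rate`.
#' @param rate observed rates (per hour); same length as `temp`.
#' @param Tref reference temperature in Kelvin.  Only rescales `B0`.
#' @param min_temps minimum number of distinct temperatures for a full
#'   four-parameter fit (default 5).
#' @param e_starts multi-start initial values for `E` (eV).
#' @param e_bounds,ed_gap_bounds box constraints: `E` within `e_bounds`;
#'   `ED - E` within `ed_gap_bounds` (eV).
#' @param tpk_pad Kelvin padding of the `Tpk` box below the coldest and
#'   above the warmest observed temperature, `c(below, above)`.
#' @param log_scale fit on log(rate) instead of the linear rate scale
#'   (default `FALSE`).
#' @param niche_floor floor (degC) passed to [operational_niche_width].
#' @return an object of class `"ss_fit"`: a list with elements `params`
#'   ([ss_params], `NULL` for fallback fits), `topt` (degC), `peak_rate`,
#'   `niche_width` (degC or `NA`), `method` (`"fitted"` or
#'   `"fallback"`), `n_obs`, `n_temps`, `rss`, `r_squared`, `aic`,
#'   `data` (the observations used), `dropped` (count of non-positive
#'   rates removed), and `rising` (`TRUE` when the peak was not bracketed
#'   by the data).
#' @examples
#' truth <- ss_params(B0 = 0.3, E = 0.65, ED = 3, Tpk = celsius_to_kelvin(30))
#' temps <- c(4, 10, 15, 21, 26, 30, 35)
#' fit <- fit_ss(temps, ss_evaluate(truth, celsius_to_kelvin(temps)))
#' coef(fit)
#' @export
fit_ss <- function(temp, rate = NULL, Tref = 273.15, min_temps = 5,
                   e_starts = c(0.2, 0.65, 1.2),
                   e_bounds = c(0.01, 10), ed_gap_bounds = c(0.01, 30),
                   tpk_pad = c(5, 10), log_scale = FALSE,
                   niche_floor = -10) {
  if (is.data.frame(temp)) {
    rate <- temp$rate
    temp <- temp$temp
  }
  stopifnot(length(temp) == length(rate))
  keep <- is.finite(rate) & is.finite(temp) & rate > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("fit_ss: dropped %d non-positive/non-finite rate(s)",
                    dropped))
  temp <- temp[keep]; rate <- rate[keep]
  if (length(rate) == 0) stop("no positive rates to fit")
  ord <- order(temp, rate)
  temp <- temp[ord]; rate <- rate[ord]
  tk <- celsius_to_kelvin(temp)
  n_temps <- length(unique(temp))

  if (n_temps < min_temps) {
    return(.ss_fallback(temp, rate, dropped))
  }

  # fit on rates normalized by their maximum: conditions the problem
  # and makes the fit exactly invariant to uniform rescaling (B0 is
  # scaled back afterwards)
  rscale <- max(rate)
  rate_n <- rate / rscale
  obj <- function(par) {
    p <- list(B0 = exp(par[1]), E = par[2], ED = par[2] + par[3],
              Tpk = par[4], Tref = Tref)
    pred <- ss_evaluate(p, tk)
    if (log_scale) sum((log(rate_n) - log(pred))^2)
    else sum((rate_n - pred)^2)
  }
  lower <- c(-50, e_bounds[1], ed_gap_bounds[1], min(tk) - tpk_pad[1])
  upper <- c(50, e_bounds[2], ed_gap_bounds[2], max(tk) + tpk_pad[2])
  tpk0 <- tk[which.max(rate)]
  i_ref <- which.min(abs(tk - Tref))
  best <- NULL
  for (e0 in e_starts) {
    # back-correct the observation nearest Tref to a B0 initial
    b0_0 <- rate_n[i_ref] * exp(e0 / boltzmann_k * (1 / tk[i_ref] - 1 / Tref))
    par0 <- c(log(max(b0_0, 1e-12)), e0, 3 * e0,
              min(max(tpk0, lower[4] + 1e-6), upper[4] - 1e-6))
    opt <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1, maxit = 2000,
                                  parscale = c(1, 0.3, 1, 5))),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 && opt$par[2] < best$par[2]))
      best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed")

  par <- best$par
  params <- ss_params(B0 = exp(par[1]) * rscale, E = par[2],
                      ED = par[2] + par[3], Tpk = par[4], Tref = Tref)
  pred <- ss_evaluate(params, tk)
  rss <- sum((rate - pred)^2)
  tss <- sum((rate - mean(rate))^2)
  n <- length(rate)
  aic <- n * log(rss / n) + 2 * 5  # 4 curve params + error variance
  rising <- params$Tpk >= max(tk) - 1e-9
  if (rising)
    warning("fitted Tpk at or beyond the warmest measured temperature; ",
            "rates may still be rising across the sampled window")
  nw <- operational_niche_width(params, floor = niche_floor)
  structure(list(
    params = params,
    topt = kelvin_to_celsius(params$Tpk),
    peak_rate = peak_rate(params),
    niche_width = as.numeric(nw),
    niche_defined = isTRUE(attr(nw, "defined")),
    method = "fitted",
    n_obs = n, n_temps = n_temps,
    rss = rss, r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aic = aic, log_scale = log_scale,
    data = data.frame(temp = temp, rate = rate),
    dropped = dropped, rising = rising
  ), class = "ss_fit")
}

# Fallback when too few distinct temperatures: thermal optimum taken as
# the temperature with the highest directly measured rate.
.ss_fallback <- function(temp, rate, dropped) {
  i <- which.max(rate)
  structure(list(
    params = NULL,
    topt = temp[i],
    peak_rate = rate[i],
    niche_width = NA_real_, niche_defined = FALSE,
    method = "fallback",
    n_obs = length(rate), n_temps = length(unique(temp)),
    rss = NA_real_, r_squared = NA_real_, aic = NA_real_,
    log_scale = FALSE,
    data = data.frame(temp = temp, rate = rate),
    dropped = dropped, rising = NA
  ), class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, digits = 4, ...) {
  cat("Sharpe-Schoolfield thermal performance curve fit\n")
  cat(sprintf("  method: %s (%d obs at %d temperatures)\n",
              x$method, x$n_obs, x$n_temps))
  cat(sprintf("  Topt = %.2f degC, peak rate = %.*g\n",
              x$topt, digits, x$peak_rate))
  if (x$method == "fitted") {
    cat(sprintf("  E = %.*g eV, ED = %.*g eV, B0 = %.*g\n",
                digits, x$params$E, digits, x$params$ED,
                digits, x$params$B0))
    if (x$niche_defined)
      cat(sprintf("  operational niche width = %.2f degC\n", x$niche_width))
    else
      cat("  operational niche width: undefined above the search floor\n")
    cat(sprintf("  RSS = %.*g, R^2 = %.3f\n", digits, x$rss, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.ss_fit <- function(object, ...) {
  if (object$method != "fitted")
    return(c(topt = object$topt, peak_rate = object$peak_rate))
  with(object$params, c(B0 = B0, E = E, ED = ED, Tpk = Tpk))
}

#' @export
summary.ss_fit <- function(object, ...) {
  s <- object
  s$derived <- c(topt = object$topt, peak_rate = object$peak_rate,
                 niche_width = object$niche_width)
  class(s) <- c("summary.ss_fit", "ss_fit")
  s
}

#' @export
print.summary.ss_fit <- function(x, ...) {
  print.ss_fit(x, ...)
  if (x$method == "fitted") {
    res <- stats::residuals(x)
    cat("  residuals: ")
    print(summary(res))
  }
  invisible(x)
}

#' Predict rates from a fitted thermal performance curve
#'
#' @param object an `"ss_fit"` object with `method = "fitted"`.
#' @param newdata optional vector of temperatures in degrees Celsius (or
#'   data.frame with a `temp` column); defaults to the fitted data.
#' @param ... unused.
#' @return predicted rates.
#' @export
predict.ss_fit <- function(object, newdata = NULL, ...) {
  if (object$method != "fitted")
    stop("predict() requires a fitted curve (method = \"fitted\")")
  temp <- if (is.null(newdata)) object$data$temp
          else if (is.data.frame(newdata)) newdata$temp
          else newdata
  ss_evaluate(object$params, celsius_to_kelvin(temp))
}

#' @export
residuals.ss_fit <- function(object, ...) {
  if (object$method != "fitted")
    stop("residuals() requires a fitted curve")
  object$data$rate - predict(object)
}

#' @export
fitted.ss_fit <- function(object, ...) predict(object)

#' Plot a fitted thermal performance curve
#'
#' Observations with the fitted curve overlaid and the thermal optimum
#' marked.
#'
#' @param x an `"ss_fit"` object.
#' @param n_grid resolution of the curve.
#' @param ... passed to [plot].
#' @export
plot.ss_fit <- function(x, n_grid = 200, ...) {
  plot(x$data$temp, x$data$rate, xlab = "Temperature (degC)",
       ylab = "Rate (per h)", pch = 19, ...)
  if (x$method == "fitted") {
    tt <- seq(min(x$data$temp), max(x$data$temp), length.out = n_grid)
    graphics::lines(tt, predict(x, tt))
    graphics::abline(v = x$topt, lty = 2)
  }
  invisible(x)
}

#' Fit thermal performance curves for every isolate in a rate table
#'
#' Convenience wrapper applying [fit_ss] per isolate (and per rate type
#' when a `rate_type` column is present).
#'
#' @param table data.frame with columns `isolate_id`, `temp` (degC),
#'   `rate`, and optionally `rate_type`.
#' @param ... passed to [fit_ss].
#' @return a data.frame with one row per isolate (x rate type): `topt`,
#'   `peak_rate`, `niche_width`, `e`, `ed`, `b0`, `method`, `n_temps`,
#'   `rss`, `r_squared`.  The `"ss_fit"` objects are attached as
#'   attribute `fits`.
#' @export
fit_ss_table <- function(table, ...) {
  stopifnot(all(c("isolate_id", "temp", "rate") %in% names(table)))
  key <- if ("rate_type" %in% names(table))
    interaction(table$isolate_id, table$rate_type, drop = TRUE)
  else factor(table$isolate_id)
  groups <- split(table, key)
  fits <- lapply(groups, function(g)
    suppressWarnings(fit_ss(g$temp, g$rate, ...)))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    g <- groups[[nm]]
    data.frame(
      isolate_id = g$isolate_id[1],
      rate_type = if ("rate_type" %in% names(g)) g$rate_type[1] else "rate",
      topt = f$topt, peak_rate = f$peak_rate,
      niche_width = f$niche_width,
      e = if (is.null(f$params)) NA_real_ else f$params$E,
      ed = if (is.null(f$params)) NA_real_ else f$params$ED,
      b0 = if (is.null(f$params)) NA_real_ else f$params$B0,
      method = f$method, n_temps = f$n_temps,
      rss = f$rss, r_squared = f$r_squared,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
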