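#' Irradiation time course
#'
#' @param time Minutes, increasing, starting at 0.
#' @param f_norm Fluorescence normalized to the t = 0 value.
#' @param label Sample id.
#' @return Object of class `time_course` (a data.frame `time_min`,
#'   `f_norm`).
#' @export
time_course <- function(time, f_norm, label = "sample") {
  stop_if(any(diff(time) <= 0), "time must increase")
  stop_if(abs(f_norm[1] - 1) > 0.2, "f_norm must start near 1 (normalized)")
  structure(data.frame(time_min = time, f_norm = f_norm),
            label = label, class = c("time_course", "data.frame"))
}

#' Fit and classify a photodimerization time course
#'
#' Fits both a pseudo-first-order exponential
#' \eqn{F = p + (1 - p) e^{-k t}} and a linear drift \eqn{F = 1 - s t} by
#' least squares, selects between them by AICc (the exponential must win by
#' at least `delta_aicc`), and calls the reaction complete when the
#' exponential is selected and its fitted end-of-run value is below
#' `completion_threshold`.
#'
#' @param tc A [time_course()] with >= 8 points spanning >= 20 min.
#' @param delta_aicc Margin by which the exponential AICc must beat the
#'   linear AICc (default 2).
#' @param completion_threshold Final fitted fraction below which the
#'   reaction is deemed complete (default 0.1).
#' @return List: `model` ("exponential" or "linear"), `rate` (k, min^-1) or
#'   `slope` (s, min^-1), `plateau`, `aicc` (named vector), `completion`,
#'   `rate_equivalent` (initial fractional loss rate, min^-1, comparable
#'   across both models), `fallback` (TRUE when the exponential fit failed).
#' @export
fit_timecourse <- function(tc, delta_aicc = 2, completion_threshold = 0.1) {
  t <- tc$time_min
  f <- tc$f_norm
  stop_if(length(t) < 8, "need >= 8 time points")
  stop_if(max(t) - min(t) < 20, "time course must span >= 20 min")
  n <- length(f)

  aicc <- function(rss, k_par) {
    k <- k_par + 1  # + residual variance
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }

  # linear through (0, 1): minimize sum (1 - s t - f)^2
  s_hat <- sum(t * (1 - f)) / sum(t^2)
  rss_lin <- sum((1 - s_hat * t - f)^2)
  aicc_lin <- aicc(rss_lin, 1)

  # exponential: par = (log k, plateau)
  fallback <- FALSE
  exp_fit <- tryCatch({
    resid_fn <- function(par) {
      p <- par[2]
      p + (1 - p) * exp(-exp(par[1]) * t) - f
    }
    fits <- lapply(c(0.02, 0.1, 0.5), function(k0) {
      minpack.lm::nls.lm(par = c(log(k0), max(min(f), 0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300))
    })
    ssrs <- vapply(fits, function(ft) sum(ft$fvec^2), 1)
    fits[[which.min(ssrs)]]
  }, error = function(e) NULL)

  if (is.null(exp_fit) || !(exp_fit$info %in% 1:4)) {
    fallback <- TRUE
    return(list(model = "linear", slope = s_hat, rate = NA_real_,
                plateau = NA_real_,
                aicc = c(exponential = NA_real_, linear = aicc_lin),
                completion = FALSE, rate_equivalent = s_hat,
                fallback = fallback))
  }
  k_hat <- exp(exp_fit$par[1])
  p_hat <- exp_fit$par[2]
  rss_exp <- sum(exp_fit$fvec^2)
  aicc_exp <- aicc(rss_exp, 2)

  use_exp <- (aicc_lin - aicc_exp) >= delta_aicc
  final_fitted <- p_hat + (1 - p_hat) * exp(-k_hat * max(t))
  if (use_exp) {
    list(model = "exponential", rate = k_hat, slope = NA_real_,
         plateau = p_hat,
         aicc = c(exponential = aicc_exp, linear = aicc_lin),
         completion = final_fitted < completion_threshold,
         rate_equivalent = k_hat * (1 - p_hat), fallback = fallback)
  } else {
    list(model = "linear", slope = s_hat, rate = NA_real_,
         plateau = NA_real_,
         aicc = c(exponential = aicc_exp, linear = aicc_lin),
         completion = FALSE, rate_equivalent = s_hat, fallback = fallback)
  }
}

#' Classify a panel of irradiation time courses against controls
#'
#' Each control is fitted and its initial fractional loss rate recorded;
#' the control band is mean +/- 2 SD of those rates. A sample is
#' `promoted` when its exponential model is selected and its rate
#' equivalent exceeds 3x the maximum control rate; `inhibited` when the
#' linear model is selected and its slope lies within twice the control
#' band's upper edge; otherwise `ambiguous`.
#'
#' @param tcs List of sample [time_course()]s.
#' @param controls List of control [time_course()]s (>= 1).
#' @return data.frame: `label` (sample id), `model`, `rate_equivalent`,
#'   `completion`, `class`.
#' @export
classify_panel <- function(tcs, controls) {
  stop_if(length(tcs) == 0, "empty panel")
  stop_if(length(controls) == 0, "need at least one control")
  ctrl_rates <- vapply(controls,
                       function(tc) fit_timecourse(tc)$rate_equivalent, 1)
  ctrl_max <- max(ctrl_rates)
  band_upper <- mean(ctrl_rates) + 2 * stats::sd(c(ctrl_rates, ctrl_rates[1]))
  if (!is.finite(band_upper)) band_upper <- ctrl_max
  band_upper <- max(band_upper, ctrl_max)

  rows <- lapply(tcs, function(tc) {
    ft <- fit_timecourse(tc)
    cls <- if (ft$model == "exponential" &&
               ft$rate_equivalent > 3 * ctrl_max) {
      "promoted"
    } else if (ft$model == "linear" && ft$rate_equivalent <= 2 * band_upper) {
      "inhibited"
    } else {
      "ambiguous"
    }
    data.frame(label = attr(tc, "label") %||% "sample", model = ft$model,
               rate_equivalent = ft$rate_equivalent,
               completion = ft$completion, class = cls)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
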