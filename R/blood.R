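#' Fit the extended Hill model to parent plasma fraction samples
#'
#' The parent plasma fraction (PPf) — the fraction of plasma radioactivity
#' that is unmetabolized tracer — is modelled with an extended Hill function
#' \deqn{PPf(t) = 1 - \frac{a\,t^b}{t^b + c}}
#' with \eqn{a \in [0, 1]}, \eqn{b > 0}, \eqn{c > 0}. The curve starts at 1
#' (no metabolites at injection) and declines monotonically towards
#' \eqn{1 - a}.
#'
#' @param times sample times in minutes (at least 4, strictly increasing).
#' @param ppf_samples measured parent fractions in (0, 1].
#' @return A `hill_fit` object with elements `pars` (a, b, c), `converged`,
#'   `rss`, `diagnostics`, and a `predict()` method.
#' @examples
#' t <- c(5, 10, 20, 30, 50, 70, 90)
#' fit <- fit_parent_fraction(t, 1 - 0.9 * t^2 / (t^2 + 50))
#' fit$pars
#' @export
fit_parent_fraction <- function(times, ppf_samples) {
  check_blood_samples(times, ppf_samples, min_n = 4)
  if (any(ppf_samples <= 0 | ppf_samples > 1 + 1e-9)) {
    stop("parent fractions must lie in (0, 1]")
  }
  eval_fun <- function(p, t) 1 - p[["a"]] * t^p[["b"]] / (t^p[["b"]] + p[["c"]])
  start <- c(a = max(1e-3, 1 - min(ppf_samples)), b = 2, c = 50)
  fit <- hill_nls(times, ppf_samples, eval_fun, start,
                  lower = c(a = 0, b = 1e-2, c = 1e-4),
                  upper = c(a = 1, b = 20, c = 1e5))
  new_hill_fit(fit, eval_fun, kind = "ppf")
}

#' Fit the extended Hill model to plasma-over-blood ratio samples
#'
#' Same functional family as [fit_parent_fraction()] but anchored at the
#' measured early ratio rather than at 1:
#' \deqn{POB(t) = r_0 + \frac{d\,t^b}{t^b + c}}
#' where \eqn{r_0 = POB(0)} is fitted and the signed amplitude \eqn{d}
#' allows the ratio to rise (typical for this tracer) or fall.
#'
#' @param times sample times in minutes.
#' @param pob_samples measured plasma-over-blood ratios (> 0).
#' @return A `hill_fit` with parameters `r0`, `d`, `b`, `c`.
#' @export
fit_pob <- function(times, pob_samples) {
  check_blood_samples(times, pob_samples, min_n = 4)
  if (any(pob_samples <= 0)) stop("plasma-over-blood ratios must be positive")
  eval_fun <- function(p, t) {
    p[["r0"]] + p[["d"]] * t^p[["b"]] / (t^p[["b"]] + p[["c"]])
  }
  n <- length(times)
  start <- c(r0 = pob_samples[1],
             d = pob_samples[n] - pob_samples[1], b = 1.5, c = 30)
  rng <- max(pob_samples) - min(pob_samples) + max(pob_samples)
  fit <- hill_nls(times, pob_samples, eval_fun, start,
                  lower = c(r0 = 1e-6, d = -rng, b = 1e-2, c = 1e-4),
                  upper = c(r0 = 10, d = rng, b = 20, c = 1e5))
  new_hill_fit(fit, eval_fun, kind = "pob")
}

#' @export
predict.hill_fit <- function(object, newdata, ...) {
  t <- if (missing(newdata)) object$times else as.numeric(newdata)
  object$eval_fun(object$pars, pmax(t, 0))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Extended Hill fit (%s): %s; RSS %.3g; %s\n", x$kind,
              paste(sprintf("%s=%.4g", names(x$pars), x$pars), collapse = ", "),
              x$rss, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a piecewise linear/multi-exponential model to a whole-blood curve
#'
#' Whole-blood activity is modelled as a straight rise from zero to the
#' measured peak followed by a sum of 2 or 3 decaying exponentials:
#' \deqn{C_b(t) = \sum_i A_i e^{-\lambda_i (t - t_{peak})}, \quad t \ge t_{peak}}
#' and \eqn{C_b(t) = (t / t_{peak}) \sum_i A_i} before the peak, which makes
#' the model continuous at the peak by construction. The number of
#' exponentials (2 vs 3) is chosen by AIC. Evaluation beyond the last sample
#' extrapolates with the fitted exponentials.
#'
#' @param times sample times in minutes (merged continuous + discrete series).
#' @param activity whole-blood activity, kBq/mL.
#' @return A `wholeblood_model` with `t_peak`, `A`, `lambda` (sorted by
#'   decreasing rate), `n_exp`, `rss`, `converged`, and a `predict()` method.
#' @export
fit_wholeblood <- function(times, activity) {
  ord <- order(times)
  times <- as.numeric(times)[ord]
  activity <- as.numeric(activity)[ord]
  if (length(times) < 8) stop("need at least 8 whole-blood samples")
  if (all(activity <= 0)) stop("whole-blood curve is non-positive everywhere")
  ipk <- which.max(activity)
  if (ipk >= length(times) - 2) {
    stop("whole-blood peak not identifiable: series is still rising")
  }
  t_peak <- times[ipk]
  peak <- activity[ipk]
  post_t <- times[times >= t_peak] - t_peak
  post_y <- activity[times >= t_peak]

  fit_k <- function(k) {
    lam0 <- switch(k - 1, c(3, 0.2), c(4, 0.3, 0.02))
    frac0 <- switch(k - 1, c(0.8, 0.2), c(0.72, 0.22, 0.06))
    p0 <- c(log(frac0 * peak), log(lam0))
    res_fun <- function(p) {
      A <- exp(p[seq_len(k)]); lam <- exp(p[k + seq_len(k)])
      pred <- colSums(A * exp(-outer(lam, post_t)))
      post_y - pred
    }
    fit <- minpack.lm::nls.lm(p0, fn = res_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 400))
    rss <- sum(fit$fvec^2)
    list(A = exp(fit$par[seq_len(k)]), lambda = exp(fit$par[k + seq_len(k)]),
         rss = rss, info = fit$info,
         aic = length(post_y) * log(max(rss, 1e-300) / length(post_y)) + 2 * 2 * k)
  }
  cand <- lapply(c(2L, 3L), fit_k)
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aic"))]]
  ord_l <- order(best$lambda, decreasing = TRUE)
  structure(
    list(t_peak = t_peak, A = best$A[ord_l], lambda = best$lambda[ord_l],
         n_exp = length(best$A), rss = best$rss,
         converged = best$info %in% 1:4, times = times),
    class = "wholeblood_model"
  )
}

#' @export
predict.wholeblood_model <- function(object, newdata, ...) {
  t <- if (missing(newdata)) object$times else as.numeric(newdata)
  t <- pmax(t, 0)
  c0 <- sum(object$A)
  out <- numeric(length(t))
  pre <- t < object$t_peak
  out[pre] <- c0 * t[pre] / object$t_peak
  if (any(!pre)) {
    tau <- t[!pre] - object$t_peak
    out[!pre] <- colSums(object$A * exp(-outer(object$lambda, tau)))
  }
  pmax(out, 0)
}

#' @export
print.wholeblood_model <- function(x, ...) {
  cat(sprintf(
    "Whole-blood model: peak %.3g kBq/mL at %.3g min; %d exponentials (lambda %s)\n",
    sum(x$A), x$t_peak, x$n_exp,
    paste(sprintf("%.3g", x$lambda), collapse = ", ")))
  invisible(x)
}

#' Cross-calibrate the continuous sampling system against discrete samples
#'
#' The continuous (automatic) whole-blood series and the discrete manual
#' samples overlap at the calibration times (5, 10, 15 min by default). A
#' single multiplicative factor is estimated by least squares through the
#' origin of discrete on continuous, so `factor * continuous` matches the
#' discrete modality.
#'
#' @param continuous_times,continuous_activity the automatic series.
#' @param discrete_times,discrete_activity the manual samples.
#' @param calibration_times times at which both modalities are compared.
#' @return The scale factor (single number).
#' @export
calibrate_continuous_to_discrete <- function(continuous_times,
                                             continuous_activity,
                                             discrete_times, discrete_activity,
                                             calibration_times = c(5, 10, 15)) {
  use <- calibration_times[calibration_times <= max(continuous_times) &
                             calibration_times >= min(continuous_times) &
                             calibration_times %in% discrete_times]
  if (length(use) < 2) {
    stop("need at least 2 overlapping calibration samples")
  }
  cont <- stats::approx(continuous_times, continuous_activity, xout = use)$y
  disc <- discrete_activity[match(use, discrete_times)]
  if (any(cont <= 0)) stop("continuous activity non-positive at calibration times")
  sum(cont * disc) / sum(cont^2)
}

#' Fit the blood-to-tissue delay
#'
#' Scans a grid of candidate delays (default -1 to +1 min in 0.01-min
#' steps); for each, shifts the input function and fits a single-tissue
#' compartment model to the early whole-brain TAC (frames up to
#' `early_min`) by the same weighted least squares used everywhere else.
#' The delay minimizing the weighted residual sum of squares is returned.
#'
#' @param input an [input_function()] (its own `delay` is added to).
#' @param whole_brain_tac frame-averaged whole-brain activity, kBq/mL.
#' @param schedule the [frame_schedule()] of the TAC.
#' @param delay_grid candidate delays in minutes.
#' @param early_min only frames ending before this time are fitted.
#' @param dt fine-grid spacing for model evaluation.
#' @return A list with `delay` (minutes), `rss` (profile over the grid),
#'   `grid`, and `boundary`/`degenerate` flags.
#' @export
fit_delay <- function(input, whole_brain_tac, schedule,
                      delay_grid = seq(-1, 1, by = 0.01), early_min = 5,
                      dt = 1 / 60) {
  stopifnot(inherits(input, "input_function"))
  keep <- which(schedule$end <= early_min + 1e-9)
  if (length(keep) < 5) stop("need early frames (<= 5 min) to fit a delay")
  sub_sched <- frame_schedule(schedule$start[keep], schedule$duration[keep])
  tac <- whole_brain_tac[keep]
  if (max(tac) - min(tac) < 1e-9 || max(tac) <= 0) {
    return(list(delay = 0, grid = delay_grid,
                rss = rep(NA_real_, length(delay_grid)),
                boundary = FALSE, degenerate = TRUE))
  }
  w <- tac_weights(tac, sub_sched)
  rss <- vapply(delay_grid, function(d) {
    shifted <- input_function(input$components$wholeblood,
                              input$components$pob, input$components$ppf,
                              delay = input$delay + d)
    di <- discretize_input(shifted, sub_sched, dt)
    f <- fit_wnlls(tac, di, sub_sched, model = "1tcm", weights = w, dt = dt,
                   compute_uncertainty = FALSE, multi_start = 1)
    f$rss
  }, numeric(1))
  i <- which.min(rss)
  list(delay = delay_grid[i], grid = delay_grid, rss = rss,
       boundary = i == 1L || i == length(delay_grid), degenerate = FALSE)
}

#' Compose a metabolite-corrected plasma input function from blood fits
#'
#' Convenience wrapper applying the fitted delay to the three fitted blood
#' components; see [input_function()] for the composition
#' \eqn{C_p(t) = C_b(t-d) POB(t-d) PPf(t-d)}.
#'
#' @param wholeblood,pob,ppf fitted blood components.
#' @param delay delay in minutes (e.g. from [fit_delay()]).
#' @return An [input_function()].
#' @export
build_input_function <- function(wholeblood, pob, ppf, delay = 0) {
  input_function(wholeblood, pob, ppf, delay = delay)
}

# ---- internal helpers -------------------------------------------------

check_blood_samples <- function(times, values, min_n) {
  if (length(times) != length(values)) stop("times and samples differ in length")
  if (length(times) < min_n) stop("need at least ", min_n, " samples")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("samples must be finite")
  }
  invisible(TRUE)
}

hill_nls <- function(times, y, eval_fun, start, lower, upper) {
  res_fun <- function(p) {
    names(p) <- names(start)
    y - eval_fun(p, times)
  }
  fit <- minpack.lm::nls.lm(start, fn = res_fun, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  pars <- fit$par
  names(pars) <- names(start)
  list(pars = pars, rss = sum(fit$fvec^2), info = fit$info,
       message = fit$message, times = times, y = y)
}

new_hill_fit <- function(fit, eval_fun, kind) {
  structure(
    list(pars = fit$pars, eval_fun = eval_fun, kind = kind, rss = fit$rss,
         converged = fit$info %in% 1:4,
         diagnostics = list(info = fit$info, message = fit$message),
         times = fit$times, samples = fit$y),
    class = "hill_fit"
  )
}
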