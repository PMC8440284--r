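#' Two-tissue compartment model curve
#'
#' Evaluates the 2TCM tissue activity for given micro-parameters and input
#' function. The state equations are
#' \deqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2}
#' \deqn{dC_2/dt = k_3 C_1 - k_4 C_2}
#' and the measured signal is
#' \eqn{C_T(t) = (1 - V_B)(C_1 + C_2) + V_B C_b(t)}. The solution is the
#' convolution of a bi-exponential impulse response with \eqn{C_p},
#' evaluated on a fine uniform grid and averaged over each frame interval
#' (short early frames make midpoint sampling biased).
#'
#' @param params named vector/list with `K1` (mL cm^-3 min^-1), `k2`, `k3`,
#'   `k4` (min^-1) and `vB` (unitless blood volume fraction).
#' @param input an [input_function()] or [discretize_input()] result.
#' @param schedule a [frame_schedule()].
#' @param dt fine-grid spacing in minutes.
#' @return Frame-averaged tissue activity (kBq/mL), one value per frame.
#' @export
model_2tcm <- function(params, input, schedule, dt = 1 / 60) {
  di <- discretize_input(input, schedule, dt)
  p <- unlist(params)
  check_tcm_params(p, c("K1", "k2", "k3", "k4", "vB"))
  ct <- tissue_response(p, di)
  frame_average((1 - p[["vB"]]) * ct + p[["vB"]] * di$cb, di$dt, schedule)
}

#' Two-tissue compartment model with irreversible vascular binding (2TCM1K)
#'
#' Extends [model_2tcm()] with an additional compartment representing
#' tracer irreversibly bound to the endothelium, fed from whole blood at
#' rate `Kb`: \eqn{dC_{vasc}/dt = K_b C_b(t)}. The accumulated vascular
#' signal \eqn{K_b \int_0^t C_b\,ds} is added to the measured curve, so the
#' model reduces exactly to the 2TCM when `Kb = 0`. `Kb` does not enter
#' \eqn{V_T}, which keeps its 2TCM meaning on the exchangeable compartments.
#'
#' @inheritParams model_2tcm
#' @param params as in [model_2tcm()] plus `Kb` (min^-1).
#' @return Frame-averaged tissue activity (kBq/mL).
#' @export
model_2tcm1k <- function(params, input, schedule, dt = 1 / 60) {
  di <- discretize_input(input, schedule, dt)
  p <- unlist(params)
  check_tcm_params(p, c("K1", "k2", "k3", "k4", "vB", "Kb"))
  base <- model_2tcm(p[c("K1", "k2", "k3", "k4", "vB")], di, schedule, dt)
  if (p[["Kb"]] == 0) return(base)
  base + frame_average(p[["Kb"]] * cum_trapz(di$cb, di$dt), di$dt, schedule)
}

#' Total distribution volume from micro-parameters
#'
#' \deqn{V_T = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right)}
#' For the 2TCM1K the same formula applies to its exchangeable
#' compartments; `Kb` is excluded.
#'
#' @param params named vector/list with at least `K1`, `k2`, `k3`, `k4`.
#' @return V_T in mL/cm^3.
#' @export
compute_vt <- function(params) {
  p <- unlist(params)
  if (!all(c("K1", "k2", "k3", "k4") %in% names(p))) {
    stop("params must contain K1, k2, k3, k4")
  }
  if (p[["k2"]] <= 0 || p[["k4"]] <= 0) {
    stop("V_T undefined for k2 <= 0 or k4 <= 0")
  }
  unname((p[["K1"]] / p[["k2"]]) * (1 + p[["k3"]] / p[["k4"]]))
}

#' WNLLS frame weights
#'
#' Weights proportional to frame duration over activity,
#' \eqn{w_i = \Delta t_i / \max(C_i, \epsilon)}, normalized to sum to 1.
#' This is the inverse of the assumed count-statistics variance
#' \eqn{\sigma_i^2 \propto C_i / \Delta t_i} up to a constant, and matches
#' the noise model of the synthetic-data generator.
#'
#' @param tac frame activities (kBq/mL).
#' @param schedule a [frame_schedule()].
#' @param eps floor (kBq/mL) protecting against zero/negative frames.
#' @return Normalized weights, one per frame.
#' @export
tac_weights <- function(tac, schedule, eps = 0.01) {
  w <- schedule$duration / pmax(tac, eps)
  w / sum(w)
}

#' Fit a compartment model to a TAC by weighted nonlinear least squares
#'
#' Minimizes \eqn{\sum_i w_i (C_i - \hat C_i(\theta))^2} with bounded
#' Levenberg–Marquardt least squares, three deterministically perturbed
#' starts (best final weighted RSS wins), asymptotic standard errors from
#' the Jacobian-based covariance, delta-method propagation to \eqn{V_T},
#' and the exclusion rule applied to the result: a fit is excluded when
#' \eqn{V_T > 10} mL/cm^3 or CV(\eqn{V_T}) > 50\%.
#'
#' @param tac frame-averaged activity (kBq/mL), one value per frame.
#' @param input an [input_function()] or [discretize_input()] result.
#' @param schedule a [frame_schedule()].
#' @param model `"2tcm"`, `"2tcm1k"`, `"1tcm"`, or `"2tcm_k2c"` (the
#'   SIME-constrained variant, requires `vnd`).
#' @param weights frame weights; defaults to [tac_weights()].
#' @param init named vector of starting values overriding the defaults.
#' @param vnd fixed K1/k2 ratio, only for `model = "2tcm_k2c"`.
#' @param multi_start number of perturbed starts (default 3).
#' @param dt fine-grid spacing in minutes.
#' @param compute_uncertainty set `FALSE` to skip the covariance step
#'   (used in inner loops such as the delay search).
#' @return A `tcm_fit` with `params`, `vt`, `se`, `cv` (percent, per
#'   parameter), `cv_vt`, `rss` (weighted), `converged`, `excluded`,
#'   `exclusion_reason`, `fitted`, `weights`.
#' @export
fit_wnlls <- function(tac, input, schedule, model = c("2tcm", "2tcm1k", "1tcm",
                                                      "2tcm_k2c"),
                      weights = NULL, init = NULL, vnd = NULL,
                      multi_start = 3, dt = 1 / 60,
                      compute_uncertainty = TRUE) {
  model <- match.arg(model)
  di <- discretize_input(input, schedule, dt)
  if (length(tac) != length(schedule$start)) {
    stop("TAC length does not match the frame schedule")
  }
  spec <- tcm_model_spec(model, vnd)
  if (is.null(weights)) weights <- tac_weights(tac, schedule)
  weights <- weights / sum(weights)
  sw <- sqrt(weights)
  start <- spec$init
  if (!is.null(init)) start[names(init)] <- unlist(init)
  start <- pmin(pmax(start, spec$lower + 1e-10), spec$upper - 1e-10)

  res_fun <- function(p) {
    names(p) <- spec$par_names
    sw * (tac - spec$fun(p, di))
  }
  # perturbed starts explore different k3/k4 basins (slow vs fast
  # specific-binding kinetics), where uniform rescaling would not
  pert <- list(
    c(K1 = 1.5, k2 = 0.67, k3 = 2, k4 = 0.4, vB = 1, Kb = 1.5),
    c(K1 = 0.67, k2 = 1.5, k3 = 0.4, k4 = 2, vB = 1, Kb = 0.67)
  )
  starts <- list(start)
  for (k in seq_len(min(multi_start - 1, length(pert)))) {
    s2 <- start * pert[[k]][spec$par_names]
    starts <- c(starts, list(pmin(pmax(s2, spec$lower + 1e-10),
                                  spec$upper - 1e-10)))
  }
  if (model == "2tcm1k") {
    # seed the sweep with the nested 2TCM optimum (Kb ~ 0): Levenberg-
    # Marquardt only accepts improving steps, so the fitted 2TCM1K RSS can
    # never exceed the nested model's
    nested <- fit_wnlls(tac, di, schedule, model = "2tcm", weights = weights,
                        init = init[names(init) != "Kb"],
                        multi_start = multi_start, dt = dt,
                        compute_uncertainty = FALSE)
    starts <- c(starts, list(pmin(pmax(
      c(nested$free_params, Kb = spec$lower[["Kb"]] + 1e-10),
      spec$lower + 1e-10), spec$upper - 1e-10)))
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      s, fn = res_fun, lower = spec$lower, upper = spec$upper,
      control = minpack.lm::nls.lm.control(maxiter = 300, ptol = 1e-10,
                                           ftol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  pars <- best$par
  names(pars) <- spec$par_names
  full <- spec$full_params(pars)
  vt <- tryCatch(compute_vt(full), error = function(e) NA_real_)

  se <- rep(NA_real_, length(pars)); names(se) <- spec$par_names
  cv <- se; cv_vt <- NA_real_
  if (compute_uncertainty) {
    np <- length(pars); nf <- length(tac)
    sigma2 <- best$deviance / max(nf - np, 1)
    covm <- try(sigma2 * solve(best$hessian), silent = TRUE)
    if (inherits(covm, "try-error") || any(!is.finite(diag(covm))) ||
        any(diag(covm) < 0)) {
      cv[] <- Inf; cv_vt <- Inf
    } else {
      se <- sqrt(diag(covm)); names(se) <- spec$par_names
      cv <- 100 * se / pmax(abs(pars), 1e-12)
      g <- spec$vt_grad(pars)
      if (is.null(g) || anyNA(g)) {
        cv_vt <- Inf
      } else {
        v <- drop(t(g) %*% covm %*% g)
        cv_vt <- if (is.finite(v) && v >= 0 && is.finite(vt) && vt > 0) {
          100 * sqrt(v) / vt
        } else Inf
      }
    }
  }

  excl <- exclusion_flag(vt, cv_vt)
  structure(
    list(model = model, params = full, free_params = pars, vt = vt,
         se = se, cv = cv, cv_vt = cv_vt, rss = best$deviance,
         converged = best$info %in% 1:4, n_frames = length(tac),
         excluded = excl$excluded, exclusion_reason = excl$reason,
         fitted = spec$fun(pars, di), tac = tac, weights = weights,
         vnd_constraint = vnd),
    class = "tcm_fit"
  )
}

#' Exclusion rule for regional fits
#'
#' A fitted region is excluded as non-physiological when
#' \eqn{V_T >} `vt_max` (default 10 mL/cm^3) or when its precision is
#' unreliable, CV(\eqn{V_T}) > `cv_max` (default 50\%). A pure function of
#' the two values; `NA`/infinite CV forces exclusion.
#'
#' @param vt fitted V_T (mL/cm^3).
#' @param cv_vt coefficient of variation of V_T, percent.
#' @param vt_max,cv_max thresholds.
#' @return list with `excluded` (logical) and `reason` (character or NA).
#' @export
exclusion_flag <- function(vt, cv_vt, vt_max = 10, cv_max = 50) {
  if (!is.finite(vt)) return(list(excluded = TRUE, reason = "V_T undefined"))
  if (vt > vt_max) {
    return(list(excluded = TRUE,
                reason = sprintf("V_T > %g mL/cm^3", vt_max)))
  }
  if (!is.finite(cv_vt) || cv_vt > cv_max) {
    return(list(excluded = TRUE, reason = sprintf("CV(V_T) > %g%%", cv_max)))
  }
  list(excluded = FALSE, reason = NA_character_)
}

#' Standardized uptake value of a TAC
#'
#' \eqn{SUV(t) = C(t) / (\mathrm{dose}/\mathrm{weight})} with activity in
#' kBq/mL, injected dose in MBq and weight in kg (1 mL of tissue taken as
#' 1 g, so the normalizer dose/weight is in kBq/g). The scan summary is the
#' time-weighted mean over the acquisition; `summary = "final"` returns the
#' last frame instead.
#'
#' @param tac frame activities, kBq/mL.
#' @param schedule a [frame_schedule()].
#' @param injected_dose injected dose, MBq (> 0).
#' @param weight subject weight, kg (> 0).
#' @param summary `"mean"` (time-weighted over the scan) or `"final"`.
#' @return list with `suv` (per frame) and `summary`.
#' @export
compute_suv <- function(tac, schedule, injected_dose, weight,
                        summary = c("mean", "final")) {
  summary <- match.arg(summary)
  if (!is.finite(injected_dose) || injected_dose <= 0) {
    stop("injected dose must be positive")
  }
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  suv <- tac / (injected_dose * 1000 / (weight * 1000))
  s <- switch(summary,
              mean = sum(suv * schedule$duration) / sum(schedule$duration),
              final = suv[length(suv)])
  list(suv = suv, summary = s)
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat(sprintf("%s fit: V_T %.3f mL/cm^3 (CV %.1f%%), wRSS %.3g%s\n",
              toupper(x$model), x$vt, x$cv_vt, x$rss,
              if (x$excluded) paste0(" [EXCLUDED: ", x$exclusion_reason, "]")
              else ""))
  invisible(x)
}

# ---- internal ---------------------------------------------------------

check_tcm_params <- function(p, need) {
  if (!all(need %in% names(p))) {
    stop("params must contain ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(p[need]))) stop("non-finite compartment parameters")
  if (any(p[need] < 0)) stop("compartment parameters must be non-negative")
  if (p[["vB"]] > 0.2 + 1e-12) stop("vB must lie in [0, 0.2]")
  invisible(TRUE)
}

# C1(t) + C2(t): convolution of the bi-exponential impulse response with Cp
tissue_response <- function(p, di) {
  K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
  if (K1 == 0) return(numeric(length(di$cp)))
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  th1 <- (s + disc) / 2
  th2 <- (s - disc) / 2
  if (th1 - th2 < 1e-9) {
    # (near-)repeated eigenvalue; nudge to keep the two-term form stable
    th1 <- th1 + 5e-10
    th2 <- max(th2 - 5e-10, 0)
  }
  ph1 <- K1 * (th1 - k3 - k4) / (th1 - th2)
  ph2 <- K1 * (k3 + k4 - th2) / (th1 - th2)
  ph1 * exp_conv(di$cp, th1, di$dt) + ph2 * exp_conv(di$cp, th2, di$dt)
}

tcm_model_spec <- function(model, vnd = NULL) {
  init_all <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05, vB = 0.05,
                Kb = 0.01)
  lower_all <- c(K1 = 1e-4, k2 = 1e-4, k3 = 0, k4 = 1e-4, vB = 0, Kb = 0)
  upper_all <- c(K1 = 2, k2 = 2, k3 = 2, k4 = 2, vB = 0.2, Kb = 1)
  grad_vt_2tcm <- function(p) {
    K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
    if (k2 <= 0 || k4 <= 0) return(NULL)
    g <- c((1 + k3 / k4) / k2,
           -K1 * (1 + k3 / k4) / k2^2,
           K1 / (k2 * k4),
           -K1 * k3 / (k2 * k4^2))
    c(g, rep(0, length(p) - 4))
  }
  switch(
    model,
    "2tcm" = {
      nm <- c("K1", "k2", "k3", "k4", "vB")
      list(par_names = nm, init = init_all[nm], lower = lower_all[nm],
           upper = upper_all[nm],
           fun = function(p, di) {
             ct <- tissue_response(p, di)
             frame_average((1 - p[["vB"]]) * ct + p[["vB"]] * di$cb,
                           di$dt, di$schedule)
           },
           full_params = function(p) p,
           vt_grad = grad_vt_2tcm)
    },
    "2tcm1k" = {
      nm <- c("K1", "k2", "k3", "k4", "vB", "Kb")
      list(par_names = nm, init = init_all[nm], lower = lower_all[nm],
           upper = upper_all[nm],
           fun = function(p, di) {
             ct <- tissue_response(p, di)
             inst <- (1 - p[["vB"]]) * ct + p[["vB"]] * di$cb +
               p[["Kb"]] * cum_trapz(di$cb, di$dt)
             frame_average(inst, di$dt, di$schedule)
           },
           full_params = function(p) p,
           vt_grad = grad_vt_2tcm)
    },
    "1tcm" = {
      nm <- c("K1", "k2", "vB")
      list(par_names = nm, init = init_all[nm], lower = lower_all[nm],
           upper = upper_all[nm],
           fun = function(p, di) {
             ct <- p[["K1"]] * exp_conv(di$cp, p[["k2"]], di$dt)
             frame_average((1 - p[["vB"]]) * ct + p[["vB"]] * di$cb,
                           di$dt, di$schedule)
           },
           full_params = function(p) c(p, k3 = 0, k4 = init_all[["k4"]]),
           vt_grad = function(p) NULL)
    },
    "2tcm_k2c" = {
      if (is.null(vnd) || !is.finite(vnd) || vnd <= 0) {
        stop("constrained 2TCM requires vnd > 0")
      }
      nm <- c("K1", "k3", "k4", "vB")
      list(par_names = nm, init = init_all[nm], lower = lower_all[nm],
           upper = upper_all[nm],
           fun = function(p, di) {
             pf <- c(K1 = p[["K1"]], k2 = p[["K1"]] / vnd, k3 = p[["k3"]],
                     k4 = p[["k4"]], vB = p[["vB"]])
             ct <- tissue_response(pf, di)
             frame_average((1 - pf[["vB"]]) * ct + pf[["vB"]] * di$cb,
                           di$dt, di$schedule)
           },
           full_params = function(p) {
             c(K1 = unname(p[["K1"]]), k2 = unname(p[["K1"]]) / vnd,
               k3 = unname(p[["k3"]]), k4 = unname(p[["k4"]]),
               vB = unname(p[["vB"]]))
           },
           # V_T = vnd (1 + k3/k4): independent of K1 under the constraint
           vt_grad = function(p) {
             k3 <- p[["k3"]]; k4 <- p[["k4"]]
             if (k4 <= 0) return(NULL)
             c(0, vnd / k4, -vnd * k3 / k4^2, 0)
           })
    }
  )
}
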