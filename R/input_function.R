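#' Arterial input function
#'
#' Bundles the three fitted blood components — whole-blood activity
#' \eqn{C_b(t)}, plasma-over-blood ratio POB(t) and parent plasma fraction
#' PPf(t) — with a fitted delay into continuous-time evaluators. The
#' metabolite-corrected plasma input is
#' \deqn{C_p(t) = C_b(t - d) \cdot POB(t - d) \cdot PPf(t - d)}
#' and is zero before the delay \eqn{d}. All curves are assumed
#' decay-corrected; no radioactive decay constant is applied.
#'
#' @param wholeblood a `wholeblood_model` (see [fit_wholeblood()]) or any
#'   function of time returning kBq/mL.
#' @param pob a `hill_fit` from [fit_pob()], a function of time, or a single
#'   number for a constant ratio.
#' @param ppf a `hill_fit` from [fit_parent_fraction()], a function of time,
#'   or a single number in (0, 1].
#' @param delay delay in minutes applied to both the parent plasma and
#'   whole-blood curves (positive: blood curves lag the tissue clock).
#'
#' @return An `input_function` object with elements `cp(t)`, `cb(t)`,
#'   `pob(t)`, `ppf(t)` (vectorized evaluators) and `delay`.
#' @export
input_function <- function(wholeblood, pob, ppf, delay = 0) {
  cb_raw <- as_time_fun(wholeblood)
  pob_raw <- as_time_fun(pob)
  ppf_raw <- as_time_fun(ppf)
  delay <- as.numeric(delay)
  stopifnot(length(delay) == 1, is.finite(delay))
  shift <- function(f) {
    force(f)
    function(t) {
      ts <- t - delay
      out <- numeric(length(ts))
      ok <- ts >= 0
      if (any(ok)) out[ok] <- f(ts[ok])
      out
    }
  }
  structure(
    list(
      cb = shift(cb_raw),
      pob = shift(pob_raw),
      ppf = shift(ppf_raw),
      cp = function(t) {
        ts <- t - delay
        out <- numeric(length(ts))
        ok <- ts >= 0
        if (any(ok)) {
          out[ok] <- pmax(0, cb_raw(ts[ok]) * pob_raw(ts[ok]) * ppf_raw(ts[ok]))
        }
        out
      },
      delay = delay,
      components = list(wholeblood = wholeblood, pob = pob, ppf = ppf)
    ),
    class = "input_function"
  )
}

# coerce model objects / constants to a vectorized function of time
as_time_fun <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, c("hill_fit", "wholeblood_model"))) {
    return(function(t) predict(x, t))
  }
  if (is.numeric(x) && length(x) == 1) {
    return(function(t) rep(as.numeric(x), length(t)))
  }
  stop("cannot interpret blood component of class ", paste(class(x), collapse = "/"))
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Metabolite-corrected plasma input function (delay %.3f min)\n",
              x$delay))
  invisible(x)
}

#' Evaluate an input function on the fine grid used by the compartment models
#'
#' Internal workhorse behind all model fitting: samples \eqn{C_p} and
#' \eqn{C_b} on a uniform grid covering the frame schedule, so every
#' convolution and frame average downstream is a cheap vector operation.
#'
#' @param input an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param dt grid spacing in minutes; must evenly divide all frame
#'   boundaries. The default (1 s) resolves the 15-s early frames.
#' @return A `discretized_input` list with `t`, `cp`, `cb`, `dt`, `schedule`.
#' @export
discretize_input <- function(input, schedule, dt = 1 / 60) {
  if (inherits(input, "discretized_input")) {
    if (abs(input$dt - dt) < 1e-12 &&
        length(input$schedule$start) == length(schedule$start) &&
        max(abs(input$schedule$start - schedule$start)) < 1e-9) {
      return(input)
    }
    stop("discretized input does not match the requested schedule/dt")
  }
  stopifnot(inherits(input, "input_function"))
  check_grid_dt(schedule, dt)
  t <- seq(0, max(schedule$end), by = dt)
  structure(
    list(t = t, cp = input$cp(t), cb = input$cb(t), dt = dt,
         schedule = schedule),
    class = "discretized_input"
  )
}
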