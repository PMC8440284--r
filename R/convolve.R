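# Internal numerics shared by the compartment-model code.
#
# All model evaluation happens on a uniform fine time grid; the convolution
# of a piecewise-linear input with a decaying exponential kernel has a
# closed-form one-step update, so the whole convolution is an order-1
# recursive filter (exact for piecewise-linear inputs, O(n)).

# y(t) = int_0^t x(s) exp(-theta (t - s)) ds for x piecewise linear on a
# uniform grid with spacing dt. Returns y on the same grid.
exp_conv <- function(x, theta, dt) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  xth <- theta * dt
  if (!is.finite(xth) || xth < 0) stop("invalid kernel rate in exp_conv")
  if (xth < 1e-8) {
    # theta ~ 0: kernel is flat, plain cumulative trapezoid
    z <- dt * (x[-n] + x[-1]) / 2
    E <- exp(-xth)
  } else {
    E <- exp(-xth)
    # int_0^dt (x0 + (x1-x0) u/dt) exp(-theta (dt-u)) du
    a0 <- (1 - E) / (theta^2 * dt) - E / theta   # weight on left node
    a1 <- 1 / theta - (1 - E) / (theta^2 * dt)   # weight on right node
    z <- a0 * x[-n] + a1 * x[-1]
  }
  c(0, as.numeric(stats::filter(z, E, method = "recursive")))
}

# cumulative trapezoidal integral on a uniform grid
cum_trapz <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum(dt * (x[-n] + x[-1]) / 2))
}

# average of a fine-grid curve over each frame of a schedule, by exact
# trapezoidal integration between frame boundaries (the grid is chosen so
# boundaries fall on grid nodes)
frame_average <- function(y, dt, schedule) {
  ci <- cum_trapz(y, dt)
  i0 <- round(schedule$start / dt) + 1L
  i1 <- round(schedule$end / dt) + 1L
  if (max(i1) > length(y)) stop("fine grid does not cover the frame schedule")
  (ci[i1] - ci[i0]) / schedule$duration
}

# grid spacing compatible with a schedule: all frame boundaries must be
# integer multiples of dt
check_grid_dt <- function(schedule, dt) {
  b <- c(schedule$start, schedule$end) / dt
  if (max(abs(b - round(b))) > 1e-6) {
    stop("dt must evenly divide all frame boundaries")
  }
  invisible(TRUE)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
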