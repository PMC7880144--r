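#' Simulate a pilot tracking the sum-of-sines target
#'
#' A proportional-derivative pursuit model of the boundary-avoidance task:
#' the simulated pilot deflects the stick in proportion to the tracking
#' error and its derivative, the aircraft pitch rate follows the stick
#' deflection, and the effective gain grows by `gain_growth` at every
#' boundary step — shrinking boundaries compel a tighter, more aggressive
#' control strategy, so per-step duty cycle and aggressiveness rise across
#' the run. A small Gaussian remnant on the stick models neuromotor noise.
#'
#' Special cases: `kp = Inf` is the ideal-pursuit limit (own pitch equals
#' the target exactly, stick set to the deflection that would produce that
#' pitch rate); `kp = 0` with `kd = 0` leaves the aircraft untouched, so
#' the error equals minus the target.
#'
#' @param sos An [sos_spec()].
#' @param schedule A [boundary_schedule()].
#' @param n_steps Number of boundary steps to span.
#' @param rate Sampling rate, Hz.
#' @param kp,kd Proportional and derivative pilot gains
#'   (stick deg per error deg, and per deg/s).
#' @param gain_growth Fractional gain increase per boundary step
#'   (default 0.3).
#' @param control_effectiveness Pitch rate per stick deflection,
#'   (deg/s)/deg.
#' @param noise_sd Stick remnant SD, degrees.
#' @param seed Integer RNG seed.
#' @return A [tracking_trace()] spanning `n_steps * step_interval`
#'   seconds, with attribute `gain_schedule` (per-step gain multipliers).
#' @export
simulate_pilot_tracking <- function(sos = sos_spec(),
                                    schedule = boundary_schedule(),
                                    n_steps = 3, rate = 100,
                                    kp = 0.8, kd = 0.15, gain_growth = 0.3,
                                    control_effectiveness = 5,
                                    noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(sos, "sos_spec"), inherits(schedule, "boundary_schedule"))
  assert_number(rate, "rate", lower = 10)
  assert_number(noise_sd, "noise_sd", lower = 0)
  set.seed(as.integer(seed))

  total <- n_steps * schedule$step_interval
  dt <- 1 / rate
  tg <- seq(0, total - dt, by = dt)
  target <- sos_signal(sos, tg)
  gain_mult <- (1 + gain_growth)^(floor(tg / schedule$step_interval))

  n <- length(tg)
  own <- numeric(n)
  stick <- numeric(n)

  if (is.infinite(kp)) {
    own <- target
    d_target <- c(diff(target) / dt, 0)
    stick <- d_target / control_effectiveness
  } else {
    # first-order lags: smoothed error derivative (tau_d) and neuromuscular
    # stick lag (tau_n); both stabilise the discrete loop at high gain
    tau_d <- 0.05
    tau_n <- 0.08
    a_d <- dt / (tau_d + dt)
    a_n <- dt / (tau_n + dt)
    err_prev <- target[1] - own[1]
    derr_f <- 0
    u_f <- 0
    noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
    for (i in seq_len(n)) {
      err <- target[i] - own[i]
      derr <- if (i == 1L) 0 else (err - err_prev) / dt
      err_prev <- err
      derr_f <- derr_f + a_d * (derr - derr_f)
      u_cmd <- gain_mult[i] * (kp * err + kd * derr_f + noise[i])
      u_f <- u_f + a_n * (u_cmd - u_f)
      stick[i] <- max(min(u_f, 20), -20)
      if (i < n) own[i + 1L] <- own[i] + control_effectiveness * stick[i] * dt
      if (!is.finite(own[min(i + 1L, n)]) || abs(own[min(i + 1L, n)]) > 1e3)
        stopf("unstable gain configuration: pitch diverged at t = %.2f s (reduce kp/kd or control_effectiveness)",
              tg[i])
    }
  }

  if (!is.infinite(kp) && mean(abs(stick) >= 20) > 0.2)
    stopf("unstable gain configuration: stick saturated %.0f%% of the time (reduce kp/kd or control_effectiveness)",
          100 * mean(abs(stick) >= 20))

  trace <- tracking_trace(tg, target, own, stick,
                          boundary_half_width = boundary_at(schedule, tg))
  attr(trace, "gain_schedule") <- (1 + gain_growth)^(seq_len(n_steps) - 1L)
  attr(trace, "seed") <- seed
  trace
}
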