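#' Lumped photothermal cycle protocol
#'
#' Laser on/off heating-cooling cycles of a nanoparticle suspension treated
#' as a single thermal mass with Newtonian exchange: during the on-stage the
#' temperature relaxes exponentially toward
#' `T_ss = ambient + eta * flux * area_abs / loss` with time constant
#' `tau = heat_capacity_eff / loss`; during the off-stage it decays toward
#' ambient with the same `tau`. All segments are closed-form (no ODE
#' discretization error).
#'
#' @param flux Laser flux in W/cm^2 during the on-stage (default 1.0).
#' @param on_duration,off_duration Stage lengths in s (defaults 70 and 100).
#' @param n_cycles Number of on/off cycles (default 2).
#' @param ambient Ambient temperature in K (default 308.15, i.e. 35 C).
#' @param absorption_efficiency Dimensionless fraction of incident power
#'   absorbed (default 1; folded into the calibration).
#' @param absorbing_area Illuminated/absorbing area in m^2 (default the
#'   (3000 nm)^2 face of the simulation cube).
#' @param heat_capacity_eff Lumped heat capacity, J/K.
#' @param loss_coefficient Newtonian loss coefficient, W/K.
#' @return A `thermal_protocol` object.
#' @seealso [calibrate_thermal_protocol()] for the default calibration.
#' @export
thermal_protocol <- function(flux = 1.0, on_duration = 70,
                             off_duration = 100, n_cycles = 2,
                             ambient = 308.15,
                             absorption_efficiency = 1,
                             absorbing_area = (3000e-9)^2,
                             heat_capacity_eff, loss_coefficient) {
  stopifnot(on_duration > 0, off_duration > 0, flux >= 0, n_cycles >= 1,
            absorption_efficiency >= 0, absorbing_area > 0)
  if (loss_coefficient <= 0 || heat_capacity_eff <= 0) {
    stop("loss_coefficient and heat_capacity_eff must be positive",
         call. = FALSE)
  }
  tau <- heat_capacity_eff / loss_coefficient
  if (!is.finite(tau) || tau <= 0) {
    stop("thermal time constant must be positive and finite", call. = FALSE)
  }
  structure(
    list(flux = flux, on_duration = on_duration,
         off_duration = off_duration, n_cycles = as.integer(n_cycles),
         ambient = ambient, absorption_efficiency = absorption_efficiency,
         absorbing_area = absorbing_area,
         heat_capacity_eff = heat_capacity_eff,
         loss_coefficient = loss_coefficient, tau = tau),
    class = "thermal_protocol")
}

#' Calibrate the lumped thermal parameters to a measured cycle shape
#'
#' Solves for `(heat_capacity_eff, loss_coefficient)` such that one on-stage
#' of `rise_time` seconds produces a peak rise of `target_rise` kelvin and
#' the following off-stage returns to within `return_within` kelvin of
#' ambient after `return_time` seconds (defaults reproduce the reported
#' cycle: ~10 K rise in 70 s, back to ambient within 100 s). The off-stage
#' condition fixes the time constant `tau` (root of
#' `target_rise * exp(-return_time/tau) - return_within`, found by
#' bisection); the on-stage condition then fixes the steady-state rise and
#' hence the loss coefficient from the absorbed power.
#'
#' @inheritParams thermal_protocol
#' @param target_rise Peak on-stage temperature rise, K (default 10).
#' @param rise_time On-stage duration used for the rise condition, s.
#' @param return_within Residual above ambient after cooling, K.
#' @param return_time Off-stage duration used for the return condition, s.
#' @return A calibrated `thermal_protocol`.
#' @export
calibrate_thermal_protocol <- function(target_rise = 10, rise_time = 70,
                                       return_within = 0.5,
                                       return_time = 100,
                                       flux = 1.0, on_duration = 70,
                                       off_duration = 100, n_cycles = 2,
                                       ambient = 308.15,
                                       absorption_efficiency = 1,
                                       absorbing_area = (3000e-9)^2) {
  stopifnot(target_rise > 0, return_within > 0,
            return_within < target_rise, flux > 0)
  cool <- function(tau) target_rise * exp(-return_time / tau) - return_within
  lo <- 1e-3; hi <- 1e4
  if (cool(lo) > 0 || cool(hi) < 0) {
    stop("no thermal time constant satisfies the cooling condition",
         call. = FALSE)
  }
  for (i in 1:200) {  # bisection
    mid <- 0.5 * (lo + hi)
    if (cool(mid) > 0) hi <- mid else lo <- mid
  }
  tau <- 0.5 * (lo + hi)
  steady_rise <- target_rise / (1 - exp(-rise_time / tau))
  p_abs <- absorption_efficiency * flux * 1e4 * absorbing_area  # W
  loss <- p_abs / steady_rise
  thermal_protocol(flux = flux, on_duration = on_duration,
                   off_duration = off_duration, n_cycles = n_cycles,
                   ambient = ambient,
                   absorption_efficiency = absorption_efficiency,
                   absorbing_area = absorbing_area,
                   heat_capacity_eff = loss * tau,
                   loss_coefficient = loss)
}

#' Simulate photothermal heating/cooling cycles
#'
#' Stitches the closed-form exponential on/off segments of a
#' [thermal_protocol()] into a temperature-time trace. The trace is exact at
#' the sample times; segment boundaries are continuous by construction.
#'
#' @param protocol A `thermal_protocol`.
#' @param dt_sample Output sampling interval, s (default 0.5).
#' @return A `thermal_trace` data frame: `time` (s), `temperature` (K),
#'   `stage` (`"on"`/`"off"`), `cycle`; the protocol is attached as an
#'   attribute.
#' @export
simulate_thermal_cycles <- function(protocol, dt_sample = 0.5) {
  stopifnot(inherits(protocol, "thermal_protocol"), dt_sample > 0)
  tau <- protocol$tau
  t_ss <- protocol$ambient + protocol$absorption_efficiency *
    protocol$flux * 1e4 * protocol$absorbing_area /
    protocol$loss_coefficient
  rows <- list()
  t0 <- 0
  temp0 <- protocol$ambient
  for (cyc in seq_len(protocol$n_cycles)) {
    for (stage in c("on", "off")) {
      dur <- if (stage == "on") protocol$on_duration else
        protocol$off_duration
      target <- if (stage == "on") t_ss else protocol$ambient
      tt <- seq(0, dur, by = dt_sample)
      if (tt[length(tt)] < dur) tt <- c(tt, dur)
      temp <- target - (target - temp0) * exp(-tt / tau)
      rows[[length(rows) + 1L]] <-
        data.frame(time = t0 + tt, temperature = temp, stage = stage,
                   cycle = cyc)
      t0 <- t0 + dur
      temp0 <- temp[length(temp)]
    }
  }
  out <- do.call(rbind, rows)
  # drop duplicated boundary samples (segment starts repeat segment ends)
  out <- out[!duplicated(out$time), ]
  rownames(out) <- NULL
  attr(out, "protocol") <- protocol
  class(out) <- c("thermal_trace", class(out))
  out
}

#' Pyroelectric device parameters
#'
#' @param p Pyroelectric coefficient, uC m^-2 K^-1 (default 400, the
#'   device-simulation value).
#' @param eps_r Relative permittivity (default 2400); the `eps` in the
#'   lumped potential formula is the absolute permittivity `eps_r * eps0`.
#' @param a Characteristic size in m (default 3000 nm, the simulation-cell
#'   cube edge).
#' @param electrode_area Electrode area in m^2 (needed for currents and
#'   charges; default NULL).
#' @return A `pyro_device` object.
#' @export
pyro_device <- function(p = 400, eps_r = 2400, a = 3000e-9,
                        electrode_area = NULL) {
  stopifnot(eps_r > 1, a > 0)
  structure(list(p = p, eps_r = eps_r, a = a,
                 electrode_area = electrode_area),
            class = "pyro_device")
}

#' Lumped pyroelectric potential V = p dT a / (eps_r eps0)
#'
#' Open-circuit potential developed across a particle of characteristic
#' size `a` for a temperature excursion `delta_T`; linear in `delta_T`.
#'
#' @param params A [pyro_device()].
#' @param delta_T Temperature change, K.
#' @return Potential in volts.
#' @examples
#' pyro_potential(pyro_device(), 10)  # ~0.565 V
#' @export
pyro_potential <- function(params, delta_T) {
  stopifnot(inherits(params, "pyro_device"))
  (params$p * 1e-6) * delta_T * params$a / (params$eps_r * EPS0)
}

#' Pyroelectric current i = p A dT/dt
#'
#' @param params A [pyro_device()] with `electrode_area` set.
#' @param dT_dt Heating/cooling rate, K/s (signed).
#' @return Current in amperes (signed).
#' @export
pyro_current <- function(params, dT_dt) {
  stopifnot(inherits(params, "pyro_device"))
  if (is.null(params$electrode_area)) {
    stop("electrode_area must be set to compute a pyroelectric current",
         call. = FALSE)
  }
  (params$p * 1e-6) * params$electrode_area * dT_dt
}

#' Pyroelectric current along a thermal trace
#'
#' Central finite differences of the trace temperature feed
#' [pyro_current()]; the current is positive while heating and negative
#' while cooling, and its time integral over a closed cycle vanishes.
#'
#' @param params A [pyro_device()] with `electrode_area` set.
#' @param trace A `thermal_trace`.
#' @return Data frame `time`, `current` (A).
#' @export
trace_current <- function(params, trace) {
  tt <- trace$time
  temp <- trace$temperature
  n <- length(tt)
  dTdt <- numeric(n)
  dTdt[1] <- (temp[2] - temp[1]) / (tt[2] - tt[1])
  dTdt[n] <- (temp[n] - temp[n - 1]) / (tt[n] - tt[n - 1])
  dTdt[2:(n - 1)] <- (temp[3:n] - temp[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  data.frame(time = tt, current = pyro_current(params, dTdt))
}

#' Exact released charge along a thermal trace
#'
#' Because `i = p A dT/dt`, the time integral of the pyroelectric current
#' between two trace samples is exactly `p A (T_b - T_a)`, independent of
#' the path; for any trace returning to its start temperature the net
#' released charge is therefore exactly zero.
#'
#' @param params A [pyro_device()] with `electrode_area` set.
#' @param trace A `thermal_trace`.
#' @param from,to Sample indices delimiting the integration (defaults:
#'   whole trace).
#' @return Charge in coulombs.
#' @export
trace_charge <- function(params, trace, from = 1L, to = nrow(trace)) {
  stopifnot(inherits(params, "pyro_device"))
  if (is.null(params$electrode_area)) {
    stop("electrode_area must be set to compute a released charge",
         call. = FALSE)
  }
  (params$p * 1e-6) * params$electrode_area *
    (trace$temperature[to] - trace$temperature[from])
}

#' Released charge over one monotone half-cycle, Q = p A dT
#'
#' Time integral of the pyroelectric current over a monotone heating or
#' cooling stage.
#'
#' @param params A [pyro_device()] with `electrode_area` set.
#' @param delta_T Temperature excursion of the stage, K.
#' @return Charge in coulombs.
#' @export
charge_per_halfcycle <- function(params, delta_T) {
  stopifnot(inherits(params, "pyro_device"))
  if (is.null(params$electrode_area)) {
    stop("electrode_area must be set to compute a released charge",
         call. = FALSE)
  }
  (params$p * 1e-6) * params$electrode_area * delta_T
}
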