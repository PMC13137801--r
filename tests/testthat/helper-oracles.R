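# Independent oracles used across the suite.

# 0-D single-domain relaxation dP/dt* = -f_bulk'(P)/alpha0, integrated with
# an adaptive high-order ODE solver (independent of the spectral stepper).
ode_relax <- function(material, temperature, p0, t_end, alpha0 = 1e7) {
  co <- coefficients_at(material, temperature)
  rhs <- function(t, y, parms) {
    gr <- pyrofield:::bulk_energy_grad(y[1], y[2], y[3], co)
    list(-c(gr[[1]], gr[[2]], gr[[3]]) / alpha0)
  }
  sol <- deSolve::ode(p0, c(0, t_end), rhs, NULL,
                      rtol = 1e-12, atol = 1e-14)
  unname(sol[2, 2:4])
}

# Brute-force 1-D grid search of the on-line bulk energy (including the
# paraelectric endpoint p = 0), the oracle for minimize_phase.
grid_search_min <- function(phase, coeffs, p_max = 0.6, step = 1e-4) {
  n <- switch(phase, T = 1, O = 2, R = 3)
  p <- seq(0, p_max, by = step)
  P <- matrix(0, length(p), 3)
  P[, seq_len(n)] <- p
  e <- bulk_energy(P, coeffs)
  i <- which.min(e)
  list(p = p[i], energy = e[i])
}

# Signed permutation group of the cube (48 elements) for symmetry checks.
signed_permutations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  out <- list()
  for (pr in perms) for (r in seq_len(nrow(signs))) {
    out[[length(out) + 1L]] <- list(perm = pr, sign = unlist(signs[r, ]))
  }
  out
}

# Analytic pyroelectric current of a calibrated protocol's first on-stage,
# from the closed-form exponential temperature segment.
analytic_on_current <- function(protocol, device, t) {
  t_ss_rise <- protocol$absorption_efficiency * protocol$flux * 1e4 *
    protocol$absorbing_area / protocol$loss_coefficient
  dTdt <- (t_ss_rise / protocol$tau) * exp(-t / protocol$tau)
  (device$p * 1e-6) * device$electrode_area * dTdt
}
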