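#' Short-term synaptic depression parameters
#'
#' Tsodyks-Markram depression in its rate-based form: the available resource
#' fraction `x` recovers toward 1 with time constant `tau_x` and is consumed
#' at rate `U * x * r` by presynaptic activity `r`,
#' `dx/dt = (1 - x)/tau_x - U x r`. `U` is the release (utilization) fraction.
#' Defaults (`U = 0.5`, `tau_x = 1.5` s) put the synapse in a
#' depression-dominated regime; `dt = 0.25` s matches one stimulus frame.
#'
#' @param U release fraction in (0, 1]
#' @param tau_x recovery time constant, seconds
#' @param dt integration timestep, seconds
#' @return an `stp_params` list
#' @export
stp_params <- function(U = 0.5, tau_x = 1.5, dt = 0.25) {
  stop_if(!is.numeric(U) || length(U) != 1L || is.na(U) || U <= 0 || U > 1,
          "`U` must lie in (0, 1]")
  check_pos(tau_x, "tau_x")
  check_pos(dt, "dt")
  structure(list(U = U, tau_x = tau_x, dt = dt), class = "stp_params")
}

#' One backward-Euler step of the depression dynamics
#'
#' The depression ODE is linear in `x`, so the implicit (backward Euler)
#' update has the closed form
#' `x' = (x + dt/tau_x) / (1 + dt/tau_x + U * dt * r)`,
#' evaluated elementwise over presynaptic units. The update maps (0, 1] into
#' (0, 1], is monotone decreasing in `r`, and relaxes to 1 when `r = 0`. Its
#' fixed point under constant drive coincides with the continuous steady
#' state, see [stp_steady_state()].
#'
#' @param x resource fraction vector, entries in (0, 1]
#' @param r non-negative presynaptic activity vector (recycled if scalar)
#' @param params an [stp_params()] object
#' @return the updated resource fraction vector
#' @examples
#' step_depression(1, 0, stp_params())            # rest is a fixed point
#' step_depression(0.5, 0, stp_params())          # relaxation: 4/7
#' @export
step_depression <- function(x, r, params = stp_params()) {
  stop_if(!inherits(params, "stp_params"), "`params` must be stp_params")
  stop_if(any(!is.finite(x)), "non-finite synapse state")
  stop_if(any(x <= 0) || any(x > 1), "synapse state outside (0, 1]")
  stop_if(any(!is.finite(r)) || any(r < 0), "activity must be >= 0 and finite")
  k <- params$dt / params$tau_x
  (x + k) / (1 + k + params$U * params$dt * r)
}

#' Steady-state resource fraction under constant drive
#'
#' `x* = (1/tau_x) / (1/tau_x + U * r)`; also the exact fixed point of the
#' backward-Euler update.
#'
#' @inheritParams step_depression
#' @return steady-state `x` for each entry of `r`
#' @export
stp_steady_state <- function(r, params = stp_params()) {
  stop_if(any(!is.finite(r)) || any(r < 0), "activity must be >= 0 and finite")
  (1 / params$tau_x) / (1 / params$tau_x + params$U * r)
}

#' Depression-gated postsynaptic drive
#'
#' Total input to the postsynaptic layer, `W %*% (x * r)`: synaptic efficacy
#' scaled by the presynaptic resource fraction. All synapses from one
#' presynaptic unit share that unit's `x`.
#'
#' @param W weight matrix, one column per presynaptic unit
#' @param x resource fraction vector, length `ncol(W)`
#' @param r non-negative presynaptic activity vector, length `ncol(W)`
#' @return postsynaptic drive vector
#' @export
effective_input <- function(W, x, r) {
  W <- as.matrix(W)
  stop_if(length(x) != ncol(W) || length(r) != ncol(W),
          "shape mismatch: ncol(W)=%d, length(x)=%d, length(r)=%d",
          ncol(W), length(x), length(r))
  stop_if(any(!is.finite(r)) || any(r < 0), "activity must be >= 0 and finite")
  drop(W %*% (x * r))
}
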