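#' Cell-model parameters for a cardiac subdomain
#'
#' Returns the published adjustment parameters, electrical properties and
#' initial conditions of the modified FitzHugh-Nagumo membrane model for one
#' of the seven conduction-system subdomains.  `a`, `b`, `d`, `e` are
#' dimensionless; `c1`, `c2` are the ionic-current gains; `k` is the rate
#' constant (1/s); `A` (mV) is the action-potential amplitude scale and `B`
#' (mV) the resting potential; `sigma_e`/`sigma_i` are the extracellular and
#' intracellular conductivities (mS/m); `Ve0`, `Vi0` (mV) and `u0` are the
#' initial conditions.
#'
#' @param subdomain one of `"SAN"`, `"ATR"`, `"AVN"`, `"HIS"`, `"BNL"`,
#'   `"PKJ"`, `"VTR"`.
#' @return a named list of parameters (class `cell_params`).
#' @export
#' @examples
#' cell_params("SAN")$a  # -0.6: the destabilized rest that makes it pace
cell_params <- function(subdomain = c("SAN", "ATR", "AVN", "HIS", "BNL",
                                      "PKJ", "VTR")) {
  subdomain <- match.arg(subdomain)
  p <- as.list(.cell_param_table[, subdomain])
  p$subdomain <- subdomain
  class(p) <- "cell_params"
  p
}

# Reaction terms, expressed on the normalized excursion v = (Vm - B)/A.
#
# Non-pacemaker tissue follows the cubic-with-voltage-gated-recovery form
#   dv/dt = k [ c1 v (v - a) (1 - v) - c2 u v ]
# (the recovery current carries the (Vm - B) factor), while the sinoatrial
# node uses the ungated recovery current k c2 u, expressed in membrane-
# potential units (hence the 1/A), with its printed c1 absorbing the rate
# constant:
#   dv/dt = c1 v (v - a) (1 - v) - k c2 u / A.
# With the published parameters, rest (v = 0) is stable wherever a > 0 and
# unstable for the node's a = -0.6, which is what makes it self-oscillate.
.reaction_dv <- function(v, u, p) {
  cubic <- v * (v - p$a) * (1 - v)
  if (identical(p$subdomain, "SAN")) {
    p$c1 * cubic - p$k * p$c2 * u / p$A
  } else {
    p$k * (p$c1 * cubic - p$c2 * u * v)
  }
}

#' Ionic current of the modified FitzHugh-Nagumo membrane
#'
#' Evaluates the ionic-current term of the membrane model, returned as the
#' rate it removes from the membrane potential (mV/s), so that the local
#' membrane equation reads \eqn{dV_m/dt = diffusion - i_{ion}}.  The cubic
#' has roots at \eqn{V_m - B \in \{0, aA, A\}}; the sinoatrial node uses the
#' recovery term \eqn{k c_2 u} while every other subdomain gates it with
#' \eqn{(V_m - B)}.
#'
#' @param Vm membrane potential, mV.
#' @param u recovery variable, dimensionless.
#' @param params a `cell_params` list from [cell_params()].
#' @return ionic current expressed as a membrane-potential rate, mV/s.
#' @export
ionic_current <- function(Vm, u, params) {
  stopifnot(inherits(params, "cell_params"))
  v <- (Vm - params$B) / params$A
  -params$A * .reaction_dv(v, u, params)
}

#' Recovery-variable rate of the membrane model
#'
#' \eqn{du/dt = k e [ (V_m - B)/A - d u - b ]}, in 1/s.
#'
#' @inheritParams ionic_current
#' @return du/dt in 1/s.
#' @export
#' @examples
#' recovery_rate(-22, 0, cell_params("SAN"))  # 19.8 /s
recovery_rate <- function(Vm, u, params) {
  stopifnot(inherits(params, "cell_params"))
  params$k * params$e * ((Vm - params$B) / params$A - params$d * u - params$b)
}

#' Integrate a single cell of the membrane model
#'
#' Zero-dimensional test harness for the membrane dynamics: integrates
#' \eqn{(V_m, u)} from the published initial conditions, optionally with a
#' square stimulus pulse added to \eqn{dV_m/dt}.
#'
#' @param params a `cell_params` list, or a subdomain name.
#' @param duration simulated time, s.
#' @param dt output sampling step, s.
#' @param stimulus optional list with `onset` (s), `duration` (s) and
#'   `amplitude` (mV/s) describing a square current pulse.
#' @return data frame with columns `time` (s), `Vm` (mV), `u`.
#' @export
#' @examples
#' tr <- simulate_cell_0d("SAN", duration = 3)
#' range(tr$Vm)  # sustained pacemaker oscillation
simulate_cell_0d <- function(params, duration = 5, dt = 5e-4,
                             stimulus = NULL) {
  if (is.character(params)) params <- cell_params(params)
  stopifnot(inherits(params, "cell_params"))
  v0 <- (params$Vi0 - params$Ve0 - params$B) / params$A
  deriv <- function(t, y, parms) {
    stim <- 0
    if (!is.null(stimulus) &&
        t >= stimulus$onset && t < stimulus$onset + stimulus$duration)
      stim <- stimulus$amplitude / params$A
    list(c(.reaction_dv(y[1], y[2], params) + stim,
           params$k * params$e * (y[1] - params$d * y[2] - params$b)))
  }
  times <- seq(0, duration, by = dt)
  hmax <- if (is.null(stimulus)) Inf else stimulus$duration / 2
  sol <- deSolve::ode(c(v = v0, u = params$u0), times, deriv, parms = NULL,
                      method = "lsoda", hmax = min(hmax, 1e-2))
  if (any(!is.finite(sol[, "v"]))) {
    bad <- sol[which(!is.finite(sol[, "v"]))[1], "time"]
    stop(sprintf("cell integration diverged at t = %.4f s", bad))
  }
  data.frame(time = sol[, "time"],
             Vm = params$B + params$A * sol[, "v"],
             u = sol[, "u"])
}
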