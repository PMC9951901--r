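# Synthetic kinetic inputs: noisy observed-rate-constant series from the
# pseudophase forward model, and two-phase (lag -> propagation) oxidation
# curves from a mass-action radical scheme.

#' Generate a noisy observed-rate-constant series
#'
#' `k_obs = forward_model * (1 + eps)`, `eps ~ Normal(0, noise_cv)`,
#' redrawn per point until positive.  `noise_cv = 0` gives points exactly on
#' the model curve.  Deterministic given `seed`.
#'
#' @inheritParams predict_kobs
#' @param phi_oil oil volume fraction.
#' @param phi_list surfactant volume fractions (nonempty).
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return a [kobs_series()].
#' @examples
#' generate_kobs_series(93, 1e4, 1e-4, 0.10, seq(0.005, 0.04, length.out = 8))
#' @export
generate_kobs_series <- function(p_wi, k_i, ao_total, phi_oil, phi_list,
                                 noise_cv = 0.05, seed = 1L) {
  if (length(phi_list) == 0L)
    stop("insufficient data: phi_list is empty", call. = FALSE)
  stopifnot(noise_cv >= 0, all(phi_list > 0), all(phi_list + phi_oil < 1))
  mu <- kobs_model(p_wi, k_i, ao_total, phi_list, phi_oil)
  kobs <- local_rng(seed, function() {
    vapply(mu, function(m) {
      for (i in 1:1000) {
        k <- m * (1 + stats::rnorm(1L, 0, noise_cv))
        if (k > 0) return(k)
      }
      stop("could not draw a positive k_obs; noise_cv too large?",
           call. = FALSE)
    }, numeric(1L))
  })
  kobs_series(phi_list, kobs, ao_total = ao_total, phi_oil = phi_oil)
}

#' Parameters of the mass-action lipid-oxidation scheme
#'
#' Rate parameters for the radical chain: initiation (RH -> R at rate
#' `r_init`, with the alkyl -> peroxyl step treated as instantaneous in
#' excess oxygen), propagation (ROO + RH -> ROOH + R, `k_prop`), termination
#' (2 ROO -> products, `k_term`) and inhibition (ROO + AOH -> ROOH + AO,
#' `k_inh`), with `n_stoich` peroxyl radicals trapped per antioxidant.
#'
#' The defaults give a visible induction period of tens of hours at the
#' accelerated-assay scale: slow initiation, an inhibition rate constant
#' well above the propagation one, and a trace antioxidant dose.
#'
#' @param r_init initiation rate, M/h.
#' @param k_prop propagation rate constant, 1/(M h).
#' @param k_term termination rate constant, 1/(M h).
#' @param k_inh inhibition rate constant, 1/(M h).
#' @param rh0 initial oxidizable lipid, M.
#' @param aoh0 initial antioxidant, M.
#' @param n_stoich radicals trapped per antioxidant molecule.
#' @param signal_coef linear map from hydroperoxide concentration to the
#'   conjugated-diene absorbance signal, AU/M.
#' @return object of class `kinetic_scheme_params`.
#' @export
kinetic_scheme_params <- function(r_init = 2e-8, k_prop = 1e2, k_term = 1e6,
                                  k_inh = 1e7, rh0 = 0.1, aoh0 = 1e-7,
                                  n_stoich = 2, signal_coef = 1e4) {
  p <- list(r_init = r_init, k_prop = k_prop, k_term = k_term,
            k_inh = k_inh, rh0 = rh0, aoh0 = aoh0, n_stoich = n_stoich,
            signal_coef = signal_coef)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1L))
  if (any(bad))
    stop("all scheme parameters must be finite nonnegative scalars: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  if (n_stoich <= 0) stop("n_stoich must be positive", call. = FALSE)
  structure(p, class = "kinetic_scheme_params")
}

#' Conjugated-diene oxidation curve
#'
#' @param time time points, strictly increasing (h).
#' @param signal conjugated-diene signal (absorbance at 233 nm, AU, or
#'   percent increase).
#' @param label curve label, e.g. `"control"` or `"antioxidant"`.
#' @param true_induction_time optional generator ground truth (h).
#' @return object of class `oxidation_curve` (a data.frame with attributes).
#' @export
oxidation_curve <- function(time, signal, label = "curve",
                            true_induction_time = NA_real_) {
  stopifnot(length(time) == length(signal), all(is.finite(time)),
            all(is.finite(signal)))
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(data.frame(time = time, signal = signal),
            label = label, true_induction_time = true_induction_time,
            class = c("oxidation_curve", "data.frame"))
}

#' Simulate a lipid-oxidation curve from the mass-action scheme
#'
#' Integrates the peroxyl-radical scheme (deSolve, `lsoda`) under the
#' fast-oxygen assumption: alkyl radicals are converted to peroxyl radicals
#' instantaneously, so propagation regenerates the peroxyl pool and its net
#' balance is initiation minus termination minus inhibition:
#' \deqn{d[ROO]/dt = r_{init} - 2 k_{term}[ROO]^2 - k_{inh}[AOH][ROO]}
#' \deqn{d[ROOH]/dt = k_{prop}[RH][ROO] + k_{inh}[AOH][ROO]}
#' \deqn{d[AOH]/dt = -k_{inh}[AOH][ROO] / n}
#' \deqn{d[RH]/dt = -k_{prop}[RH][ROO]}
#' The curve signal is `signal_coef * [ROOH]`.  With `aoh0 > 0` the curve
#' shows a lag ending near the antioxidant-depletion time; with `aoh0 = 0`
#' there is no antioxidant-driven lag.
#'
#' @param params a [kinetic_scheme_params()].
#' @param t_grid strictly increasing time points (h), starting at 0.
#' @param label curve label.
#' @return an [oxidation_curve()]; its `true_induction_time` attribute is
#'   the time at which the antioxidant falls below 1 percent of its initial
#'   concentration (NA when `aoh0 = 0` or no depletion inside `t_grid`).
#'   The solver states are attached as attribute `states` (matrix with
#'   columns ROO, ROOH, AOH, RH, consumed).
#' @examples
#' p <- kinetic_scheme_params(aoh0 = 1e-7)
#' curve <- simulate_oxidation(p, seq(0, 100, by = 0.5))
#' @export
simulate_oxidation <- function(params, t_grid, label = "curve") {
  stopifnot(inherits(params, "kinetic_scheme_params"))
  if (any(diff(t_grid) <= 0) || length(t_grid) < 2L)
    stop("t_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  rhs <- function(t, y, p) {
    roo <- y[["ROO"]]; aoh <- y[["AOH"]]; rh <- y[["RH"]]
    v_prop <- p$k_prop * rh * roo
    v_inh <- p$k_inh * aoh * roo
    list(c(ROO = p$r_init - 2 * p$k_term * roo^2 - v_inh,
           ROOH = v_prop + v_inh,
           AOH = -v_inh / p$n_stoich,
           RH = -v_prop,
           consumed = v_prop))
  }
  y0 <- c(ROO = 0, ROOH = 0, AOH = params$aoh0, RH = params$rh0,
          consumed = 0)
  sol <- tryCatch(
    deSolve::lsoda(y0, t_grid, rhs, params, rtol = 1e-10, atol = 1e-14),
    warning = function(w) stop("stiff-integration failure: ",
                               conditionMessage(w), " (r_init = ",
                               params$r_init, ", k_term = ", params$k_term,
                               ")", call. = FALSE))
  states <- sol[, -1L, drop = FALSE]
  tau_true <- NA_real_
  if (params$aoh0 > 0) {
    dep <- which(states[, "AOH"] < 0.01 * params$aoh0)
    if (length(dep)) tau_true <- t_grid[dep[1L]]
  }
  out <- oxidation_curve(t_grid, params$signal_coef * states[, "ROOH"],
                         label = label, true_induction_time = tau_true)
  attr(out, "states") <- states
  out
}

#' Piecewise-linear two-phase curve with a known breakpoint
#'
#' Constructs a lag/propagation curve with exact induction time `tau`, for
#' validating breakpoint extraction: signal grows at `slope_lag` before
#' `tau` and at `slope_prop` after, continuous at the break, with optional
#' additive gaussian noise.
#'
#' @param t_grid strictly increasing time points (h).
#' @param tau breakpoint time (h), strictly inside `t_grid`.
#' @param slope_lag,slope_prop signal slopes before/after the break.
#' @param intercept signal at `t_grid[1]`.
#' @param noise_sd additive noise standard deviation.
#' @param seed seed used when `noise_sd > 0`.
#' @param label curve label.
#' @return an [oxidation_curve()] with `true_induction_time = tau`.
#' @export
piecewise_linear_curve <- function(t_grid, tau, slope_lag = 0.001,
                                   slope_prop = 0.05, intercept = 0,
                                   noise_sd = 0, seed = 1L,
                                   label = "synthetic") {
  stopifnot(tau > min(t_grid), tau < max(t_grid), slope_prop > slope_lag)
  base <- intercept + slope_lag * (pmin(t_grid, tau) - t_grid[1L]) +
    slope_prop * pmax(t_grid - tau, 0)
  if (noise_sd > 0)
    base <- base + local_rng(seed, function()
      stats::rnorm(length(t_grid), 0, noise_sd))
  oxidation_curve(t_grid, base, label = label, true_induction_time = tau)
}
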