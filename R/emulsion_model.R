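# Pseudophase kinetic model of antioxidant distribution in oil-in-water
# emulsions.  The emulsion is treated as three notional phases (oil,
# interfacial, aqueous) in dynamic equilibrium.  For an oil-insoluble
# antioxidant the distribution is described by a single partition constant
#   P_w^i = (AO_i) / (AO_w)
# between the aqueous and interfacial pseudophases, and the observed rate
# constant of a probe reaction varies with the surfactant volume fraction as
#   k_obs = [AO_T] k_i P / (Phi_i P + Phi_w).

#' Emulsion pseudophase composition
#'
#' Volume fractions of the three pseudophases.  By default the aqueous
#' fraction is the complement `1 - phi_oil - phi_interfacial`, matching a
#' formulation where the surfactant volume counts against the aqueous phase.
#'
#' @param phi_oil oil volume fraction (1:9 v:v oil-in-water gives 0.10).
#' @param phi_interfacial surfactant (interfacial) volume fraction,
#'   `Phi_i = V_surf / V_emulsion`.
#' @param phi_water aqueous volume fraction; defaults to the complement.
#' @return object of class `emulsion_composition`.
#' @examples
#' emulsion_composition(phi_oil = 0.10, phi_interfacial = 0.04)
#' @export
emulsion_composition <- function(phi_oil, phi_interfacial,
                                 phi_water = 1 - phi_oil - phi_interfacial) {
  stopifnot(length(phi_oil) == 1L, length(phi_interfacial) == 1L,
            length(phi_water) == 1L)
  fr <- c(oil = phi_oil, interfacial = phi_interfacial, water = phi_water)
  if (any(!is.finite(fr)) || any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop("volume fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-12)
    stop("volume fractions must sum to 1 (got ", format(sum(fr), digits = 15),
         ")", call. = FALSE)
  structure(list(phi_oil = phi_oil, phi_interfacial = phi_interfacial,
                 phi_water = phi_water),
            class = "emulsion_composition")
}

#' @export
print.emulsion_composition <- function(x, ...) {
  cat(sprintf("<emulsion_composition> oil %.4g | interfacial %.4g | water %.4g\n",
              x$phi_oil, x$phi_interfacial, x$phi_water))
  invisible(x)
}

#' Observed rate-constant series for partition fitting
#'
#' Bundles (Phi_i, k_obs) pairs with the stoichiometric antioxidant
#' concentration and the oil fraction they were measured at.
#'
#' @param phi_interfacial numeric vector of surfactant volume fractions (> 0).
#' @param k_obs observed rate constants (same length, > 0), 1/time.
#' @param ao_total stoichiometric antioxidant concentration, mol/L.
#' @param phi_oil oil volume fraction.
#' @param sigma_kobs optional per-point uncertainties.
#' @return object of class `kobs_series` (a data.frame with attributes).
#' @export
kobs_series <- function(phi_interfacial, k_obs, ao_total, phi_oil,
                        sigma_kobs = NULL) {
  stopifnot(length(phi_interfacial) == length(k_obs),
            is.numeric(ao_total), length(ao_total) == 1L, ao_total > 0,
            is.numeric(phi_oil), length(phi_oil) == 1L,
            phi_oil >= 0, phi_oil < 1)
  if (any(phi_interfacial <= 0) || any(k_obs <= 0) ||
      any(!is.finite(phi_interfacial)) || any(!is.finite(k_obs)))
    stop("phi_interfacial and k_obs must be finite and positive",
         call. = FALSE)
  if (any(phi_interfacial + phi_oil >= 1))
    stop("phi_interfacial + phi_oil must be < 1", call. = FALSE)
  if (length(unique(phi_interfacial)) < 3L)
    stop("insufficient data: at least 3 distinct phi_interfacial values ",
         "are required for fitting", call. = FALSE)
  df <- data.frame(phi_interfacial = phi_interfacial, k_obs = k_obs)
  if (!is.null(sigma_kobs)) {
    stopifnot(length(sigma_kobs) == length(k_obs), all(sigma_kobs > 0))
    df$sigma_kobs <- sigma_kobs
  }
  structure(df, ao_total = ao_total, phi_oil = phi_oil,
            class = c("kobs_series", "data.frame"))
}

#' Predict the observed rate constant from the pseudophase model
#'
#' Forward model `k_obs = ao_total * k_i * p_wi / (Phi_i * p_wi + Phi_w)`.
#' Only the composite `ao_total * k_i` is identifiable from a k_obs series,
#' so `k_i` is interpreted relative to the supplied `ao_total`.
#'
#' @param p_wi partition constant water -> interface (dimensionless, >= 0).
#' @param k_i interfacial rate parameter.
#' @param ao_total stoichiometric antioxidant concentration, mol/L.
#' @param comp an [emulsion_composition()].
#' @return predicted observed rate constant (1/time).
#' @examples
#' comp <- emulsion_composition(0.10, 0.04)
#' predict_kobs(93, 1e4, 1e-4, comp)  # 93/4.58 = 20.3...
#' @export
predict_kobs <- function(p_wi, k_i, ao_total, comp) {
  stopifnot(inherits(comp, "emulsion_composition"),
            is.numeric(p_wi), p_wi >= 0)
  denom <- comp$phi_interfacial * p_wi + comp$phi_water
  if (denom <= 0)
    stop("degenerate composition: Phi_i * P + Phi_w must be positive",
         call. = FALSE)
  ao_total * k_i * p_wi / denom
}

# vectorized internal version used by the fitters and generators
kobs_model <- function(p_wi, k_i, ao_total, phi_i, phi_oil) {
  phi_w <- 1 - phi_oil - phi_i
  ao_total * k_i * p_wi / (phi_i * p_wi + phi_w)
}

#' Percentage of antioxidant in the interfacial region
#'
#' `%AO_i = 100 * Phi_i * P / (Phi_w + Phi_i * P)`.
#'
#' @inheritParams predict_kobs
#' @return percentage in \[0, 100\].
#' @examples
#' percent_interfacial(93, emulsion_composition(0.10, 0.04))   # 81.2
#' percent_interfacial(93, emulsion_composition(0.10, 0.005))  # 34.2
#' @export
percent_interfacial <- function(p_wi, comp) {
  stopifnot(inherits(comp, "emulsion_composition"),
            is.numeric(p_wi), p_wi >= 0)
  denom <- comp$phi_water + comp$phi_interfacial * p_wi
  if (denom <= 0)
    stop("degenerate composition: Phi_w + Phi_i * P must be positive",
         call. = FALSE)
  100 * comp$phi_interfacial * p_wi / denom
}

#' Antioxidant distribution between aqueous and interfacial pseudophases
#'
#' Percentages in each region and the effective (local) concentrations
#' referred to each region's own volume:
#' `(AO_i) = ao_total * (%AO_i / 100) / Phi_i` and analogously for the
#' aqueous region.  Because the interfacial volume is small, `(AO_i)` can
#' exceed `ao_total` by orders of magnitude.
#'
#' @inheritParams predict_kobs
#' @return object of class `distribution_result`: percentages, effective
#'   concentrations (mol per liter of the region's volume) and the inputs.
#' @examples
#' distribution(93, 1e-4, emulsion_composition(0.10, 0.005))
#' @export
distribution <- function(p_wi, ao_total, comp) {
  stopifnot(is.numeric(ao_total), ao_total > 0)
  if (comp$phi_interfacial <= 0)
    stop("degenerate composition: effective interfacial concentration ",
         "undefined at Phi_i = 0", call. = FALSE)
  pct_i <- percent_interfacial(p_wi, comp)
  pct_w <- 100 - pct_i
  conc_i <- ao_total * (pct_i / 100) / comp$phi_interfacial
  conc_w <- if (comp$phi_water > 0)
    ao_total * (pct_w / 100) / comp$phi_water else NA_real_
  structure(list(percent_interfacial = pct_i,
                 percent_aqueous = pct_w,
                 effective_conc_interfacial = conc_i,
                 effective_conc_aqueous = conc_w,
                 p_wi = p_wi, ao_total = ao_total, comp = comp),
            class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  cat(sprintf("<distribution_result> %%interfacial = %.2f | %%aqueous = %.2f\n",
              x$percent_interfacial, x$percent_aqueous))
  cat(sprintf("  (AO_i) = %.4g M | (AO_w) = %.4g M | [AO_T] = %.4g M\n",
              x$effective_conc_interfacial, x$effective_conc_aqueous,
              x$ao_total))
  invisible(x)
}

#' Distribution table over a grid of surfactant volume fractions
#'
#' One row per `Phi_i`: percentages and effective concentrations.  Along an
#' increasing `Phi_i` grid the interfacial percentage increases while the
#' effective interfacial concentration decreases (the dilution effect of the
#' growing interfacial volume).
#'
#' @inheritParams predict_kobs
#' @param phi_oil oil volume fraction shared by all rows.
#' @param phi_list numeric vector of surfactant volume fractions.
#' @return data.frame with columns `phi_interfacial`, `phi_water`,
#'   `pct_interfacial`, `pct_aqueous`, `conc_interfacial_M`, `conc_aqueous_M`.
#' @examples
#' distribution_table(93, 1e-4, 0.10, c(0.005, 0.04))
#' @export
distribution_table <- function(p_wi, ao_total, phi_oil, phi_list) {
  stopifnot(length(phi_list) >= 1L)
  rows <- lapply(phi_list, function(phi_i) {
    d <- distribution(p_wi, ao_total,
                      emulsion_composition(phi_oil, phi_i))
    data.frame(phi_interfacial = phi_i,
               phi_water = d$comp$phi_water,
               pct_interfacial = d$percent_interfacial,
               pct_aqueous = d$percent_aqueous,
               conc_interfacial_M = d$effective_conc_interfacial,
               conc_aqueous_M = d$effective_conc_aqueous)
  })
  do.call(rbind, rows)
}

#' Fit the partition constant from a k_obs series
#'
#' Two routes to `(P, k_i)` from (Phi_i, k_obs) pairs:
#'
#' * `"nonlinear"` (default) — unweighted nonlinear least squares of the
#'   forward model on the k_obs scale (Levenberg–Marquardt), initialized at
#'   the reciprocal-linear estimates with up to five seeded multiplicative
#'   restarts of the start point on failure.
#' * `"reciprocal-linear"` — ordinary least squares of
#'   `1/k_obs = (1 - phi_oil)/(A k_i P) + Phi_i (P - 1)/(A k_i P)` on
#'   `Phi_i` (with `A = ao_total`), back-transformed to `(P, k_i)`.  The
#'   reciprocal transform reweights the noise, so both routes are reported.
#'
#' Standard errors are asymptotic: from the fit Jacobian (nonlinear) or by
#' the delta method from the regression covariance (reciprocal-linear).
#'
#' @param series a [kobs_series()].
#' @param method `"nonlinear"` or `"reciprocal-linear"`.
#' @return object of class `partition_fit` with elements `p_wi`, `k_i`,
#'   `se_p_wi`, `se_k_i`, `method`, `residual_sum_squares` (on the scale the
#'   method fits on), `n`.
#' @examples
#' s <- generate_kobs_series(93, 1e4, 1e-4, 0.10,
#'                           seq(0.005, 0.04, length.out = 8), noise_cv = 0)
#' fit_partition(s)
#' @export
fit_partition <- function(series, method = c("nonlinear", "reciprocal-linear")) {
  stopifnot(inherits(series, "kobs_series"))
  method <- match.arg(method)
  ao_total <- attr(series, "ao_total")
  phi_oil <- attr(series, "phi_oil")
  phi_i <- series$phi_interfacial
  kobs <- series$k_obs

  lin <- reciprocal_linear_fit(phi_i, kobs, ao_total, phi_oil)
  if (method == "reciprocal-linear") return(lin)

  df <- data.frame(phi_i = phi_i, kobs = kobs)
  fit <- NULL
  start <- list(p = max(lin$p_wi, 1e-6), ki = max(lin$k_i, 1e-12))
  perturb <- local_rng(104729L, function() {
    matrix(exp(stats::rnorm(10L, 0, 0.3)), ncol = 2L)
  })
  for (attempt in 0:5) {
    st <- if (attempt == 0L) start else
      list(p = start$p * perturb[attempt, 1L],
           ki = start$ki * perturb[attempt, 2L])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        kobs ~ ao_total * ki * p / (phi_i * p + (1 - phi_oil - phi_i)),
        data = df, start = st,
        lower = c(p = 0, ki = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("nonlinear fit failed to converge after 5 seeded restarts ",
         "(start: P = ", signif(start$p, 4), ", k_i = ", signif(start$ki, 4),
         ")", call. = FALSE)
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(p = NA_real_, ki = NA_real_))
  partition_fit(p_wi = unname(cf["p"]), k_i = unname(cf["ki"]),
                se_p_wi = unname(se["p"]), se_k_i = unname(se["ki"]),
                method = "nonlinear",
                rss = sum(stats::resid(fit)^2), n = length(kobs))
}

reciprocal_linear_fit <- function(phi_i, kobs, ao_total, phi_oil) {
  y <- 1 / kobs
  lm_fit <- stats::lm(y ~ phi_i)
  a <- unname(stats::coef(lm_fit)[1L])   # (1 - phi_oil) / (A k_i P)
  b <- unname(stats::coef(lm_fit)[2L])   # (P - 1) / (A k_i P)
  if (a <= 0)
    stop("reciprocal-linear fit gave a nonpositive intercept; ",
         "the series is inconsistent with the pseudophase model",
         call. = FALSE)
  om <- 1 - phi_oil
  p <- 1 + om * b / a
  cc <- a + om * b                       # = (1 - 1/P) * a * P ... = om/(A k_i)
  k_i <- om / (ao_total * cc)
  V <- suppressWarnings(stats::vcov(lm_fit))  # noiseless series: zero RSS
  # delta method: P = 1 + om*b/a ; k_i = om / (A*(a + om*b))
  gP <- c(-om * b / a^2, om / a)
  gk <- c(-om / (ao_total * cc^2), -om^2 / (ao_total * cc^2))
  se_p <- sqrt(drop(t(gP) %*% V %*% gP))
  se_k <- sqrt(drop(t(gk) %*% V %*% gk))
  if (p <= 0 || k_i <= 0)
    stop("reciprocal-linear fit produced nonpositive parameters (P = ",
         signif(p, 4), ", k_i = ", signif(k_i, 4), ")", call. = FALSE)
  partition_fit(p_wi = p, k_i = k_i, se_p_wi = se_p, se_k_i = se_k,
                method = "reciprocal-linear",
                rss = sum(stats::resid(lm_fit)^2), n = length(kobs))
}

partition_fit <- function(p_wi, k_i, se_p_wi, se_k_i, method, rss, n) {
  structure(list(p_wi = p_wi, k_i = k_i, se_p_wi = se_p_wi, se_k_i = se_k_i,
                 method = method, residual_sum_squares = rss, n = n),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit> method: %s (n = %d)\n", x$method, x$n))
  cat(sprintf("  P_w^i = %.6g +/- %.3g\n", x$p_wi, x$se_p_wi))
  cat(sprintf("  k_i   = %.6g +/- %.3g\n", x$k_i, x$se_k_i))
  cat(sprintf("  RSS   = %.4g\n", x$residual_sum_squares))
  invisible(x)
}

# Run `fn` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  Keeps internal randomness (fit restarts) from
# disturbing user-level reproducibility.
local_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
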