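# Induction-time extraction from conjugated-diene kinetic curves: the curve
# is modeled as two straight lines (lag and propagation) and the induction
# time is the abscissa of their intersection; the breakpoint is chosen by
# exhaustive search minimizing the total residual sum of squares.

#' Relative conjugated-diene increase
#'
#' Operational percent-increase transform
#' `100 * (A_t - A_ref) / A_ref`.  As an affine map of the signal it leaves
#' the extracted induction time unchanged.
#'
#' @param signal absorbance series.
#' @param reference reference absorbance (default: first point; must be
#'   positive).
#' @return percent-increase series.
#' @export
percent_delta_cd <- function(signal, reference = signal[1L]) {
  stopifnot(is.numeric(signal), length(signal) >= 1L)
  if (!is.finite(reference) || reference <= 0)
    stop("normalization error: reference absorbance must be positive",
         call. = FALSE)
  100 * (signal - reference) / reference
}

#' Induction time by two-straight-line intersection
#'
#' Fits, for every admissible breakpoint `k` (at least `min_segment` points
#' per side), a lag line to points `1..k` and a propagation line to points
#' `k+1..n` by ordinary least squares; keeps the `k` minimizing the total
#' residual sum of squares; and returns the abscissa of the intersection of
#' the two lines as the induction time.  The search is exhaustive, so the
#' global two-segment optimum is always found.
#'
#' @param curve an [oxidation_curve()] (or data.frame with `time`,
#'   `signal`).
#' @param min_segment minimum points per segment (default 3: two for a
#'   slope plus one for residual estimation).
#' @return object of class `induction_result`: `tau_ind` (h), `lag_line`
#'   and `prop_line` (intercept/slope pairs), `breakpoint_index`,
#'   `residual_sum_squares`, `n`.
#' @examples
#' curve <- piecewise_linear_curve(seq(0, 60, by = 2), tau = 30)
#' induction_time(curve)$tau_ind
#' @export
induction_time <- function(curve, min_segment = 3L) {
  stopifnot(is.data.frame(curve), all(c("time", "signal") %in% names(curve)),
            min_segment >= 2L)
  t <- curve$time; y <- curve$signal
  n <- length(t)
  if (n < 2L * min_segment)
    stop("insufficient data: need at least ", 2L * min_segment,
         " points for two segments of ", min_segment, call. = FALSE)
  if (any(diff(t) <= 0))
    stop("time must be strictly increasing", call. = FALSE)

  ks <- seq.int(min_segment, n - min_segment)
  best <- NULL
  for (k in ks) {
    f1 <- stats::lm.fit(cbind(1, t[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, t[(k + 1L):n]), y[(k + 1L):n])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, sse = sse, c1 = f1$coefficients,
                   c2 = f2$coefficients)
  }
  dslope <- best$c2[2L] - best$c1[2L]
  scale <- max(abs(best$c1[2L]), abs(best$c2[2L]), 1e-300)
  if (!is.finite(dslope) || abs(dslope) < 1e-9 * scale)
    stop("no breakpoint: lag and propagation lines are parallel",
         call. = FALSE)
  tau <- (best$c1[1L] - best$c2[1L]) / dslope
  if (tau < t[1L] || tau > t[n])
    stop("no breakpoint: line intersection at ", signif(tau, 6),
         " falls outside the observed time range [", t[1L], ", ", t[n], "]",
         call. = FALSE)
  structure(list(tau_ind = unname(tau),
                 lag_line = c(intercept = unname(best$c1[1L]),
                              slope = unname(best$c1[2L])),
                 prop_line = c(intercept = unname(best$c2[1L]),
                               slope = unname(best$c2[2L])),
                 breakpoint_index = best$k,
                 residual_sum_squares = best$sse,
                 n = n),
            class = "induction_result")
}

#' @export
print.induction_result <- function(x, ...) {
  cat(sprintf("<induction_result> tau_ind = %.4g h (breakpoint after point %d of %d)\n",
              x$tau_ind, x$breakpoint_index, x$n))
  cat(sprintf("  lag slope %.4g | propagation slope %.4g | SSE %.4g\n",
              x$lag_line[["slope"]], x$prop_line[["slope"]],
              x$residual_sum_squares))
  invisible(x)
}

#' Antioxidant effectiveness ratio
#'
#' Ratio of induction times with and without antioxidant,
#' `tau_ind(antioxidant) / tau_ind(control)`; values above 1 indicate
#' inhibition of the oxidation chain.
#'
#' @param curve_ao,curve_control [oxidation_curve()] objects.
#' @param min_segment passed to [induction_time()].
#' @return dimensionless ratio.
#' @export
effectiveness_ratio <- function(curve_ao, curve_control, min_segment = 3L) {
  tau_ao <- induction_time(curve_ao, min_segment)$tau_ind
  tau_ctrl <- induction_time(curve_control, min_segment)$tau_ind
  tau_ao / tau_ctrl
}
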