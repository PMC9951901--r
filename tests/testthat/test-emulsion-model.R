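# Pseudophase model: forward prediction, distribution and partition fitting.

test_that("predict_kobs matches hand-evaluated forward model", {
  comp_hi <- emulsion_composition(0.10, 0.04)
  comp_lo <- emulsion_composition(0.10, 0.005)
  # composite ao_total * k_i = 1
  expect_equal(predict_kobs(93, 1, 1, comp_hi), 93 / 4.58, tolerance = 1e-12)
  expect_equal(predict_kobs(93, 1, 1, comp_lo), 93 / 1.36, tolerance = 1e-12)
  expect_identical(predict_kobs(0, 5, 2, comp_hi), 0)
  # strictly decreasing in phi_I for P > 1 at fixed phi_oil
  phis <- seq(0.002, 0.2, length.out = 30)
  k <- vapply(phis, function(p)
    predict_kobs(93, 1, 1, emulsion_composition(0.10, p)), numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("degenerate and invalid compositions are rejected", {
  expect_error(emulsion_composition(0.5, 0.3, 0.3), "sum to 1")
  expect_error(emulsion_composition(0.5, 0.6), "\\[0, 1\\]")
  expect_error(emulsion_composition(-0.1, 0.2, 0.9), "\\[0, 1\\]")
  comp0 <- emulsion_composition(1, 0, 0)
  expect_error(predict_kobs(93, 1, 1, comp0), "degenerate")
  expect_error(percent_interfacial(93, comp0), "degenerate")
  expect_error(distribution(93, 1e-4, comp0), "degenerate")
})

test_that("interfacial percentage reproduces the reference distribution", {
  expect_equal(percent_interfacial(93, emulsion_composition(0.10, 0.04)),
               81.2, tolerance = 0.0005)
  expect_equal(percent_interfacial(93, emulsion_composition(0.10, 0.005)),
               34.2, tolerance = 0.0005)
  expect_identical(percent_interfacial(0, emulsion_composition(0.10, 0.04)),
                   0)
})

test_that("interfacial percentage is monotone in P and phi_I", {
  ps <- c(0.5, 2, 10, 50, 93, 300)
  pct_p <- vapply(ps, percent_interfacial,
                  comp = emulsion_composition(0.10, 0.02), numeric(1))
  expect_true(all(diff(pct_p) > 0))
  phis <- seq(0.001, 0.1, length.out = 25)
  pct_phi <- vapply(phis, function(p)
    percent_interfacial(93, emulsion_composition(0.10, p)), numeric(1))
  expect_true(all(diff(pct_phi) > 0))
})

test_that("distribution obeys mass balance and the partition identity", {
  grid <- expand.grid(p = c(0.5, 10, 93, 400),
                      phi_i = c(0.002, 0.01, 0.04, 0.08),
                      ao = c(1e-5, 1e-4, 1e-2))
  for (i in seq_len(nrow(grid))) {
    comp <- emulsion_composition(0.10, grid$phi_i[i])
    d <- distribution(grid$p[i], grid$ao[i], comp)
    mass <- comp$phi_interfacial * d$effective_conc_interfacial +
      comp$phi_water * d$effective_conc_aqueous
    expect_equal(mass, grid$ao[i], tolerance = 1e-10)
    expect_equal(d$effective_conc_interfacial / d$effective_conc_aqueous,
                 grid$p[i], tolerance = 1e-10)
    expect_equal(d$percent_interfacial + d$percent_aqueous, 100,
                 tolerance = 1e-12)
  }
})

test_that("effective interfacial concentration shows the enhancement and dilution effects", {
  d_lo <- distribution(93, 1e-4, emulsion_composition(0.10, 0.005))
  # ~70-fold enhancement over the stoichiometric concentration
  expect_equal(d_lo$effective_conc_interfacial / 1e-4, 68.38235,
               tolerance = 1e-6)
  expect_equal(signif(d_lo$effective_conc_interfacial / 1e-4, 1), 70)
  d_hi <- distribution(93, 1e-4, emulsion_composition(0.10, 0.04))
  expect_equal(d_hi$effective_conc_interfacial, 2.0305677e-3,
               tolerance = 1e-7)
  # whole-emulsion-is-interface limit: effective conc -> stoichiometric
  d_lim <- distribution(93, 1e-4, emulsion_composition(0, 0.9999))
  expect_equal(d_lim$effective_conc_interfacial, 1e-4, tolerance = 1e-3)
})

test_that("distribution table is monotone and consistent with single calls", {
  phis <- seq(0.002, 0.08, length.out = 20)
  tab <- distribution_table(93, 1e-4, 0.10, phis)
  expect_equal(nrow(tab), 20L)
  expect_true(all(diff(tab$pct_interfacial) > 0))
  expect_true(all(diff(tab$conc_interfacial_M) < 0))
  one <- distribution_table(93, 1e-4, 0.10, 0.02)
  d <- distribution(93, 1e-4, emulsion_composition(0.10, 0.02))
  expect_equal(one$pct_interfacial, d$percent_interfacial)
  expect_equal(one$conc_interfacial_M, d$effective_conc_interfacial)
  # dilution ratio between the lowest and highest surfactant loads
  tab2 <- distribution_table(93, 1e-4, 0.10, c(0.005, 0.04))
  ratio <- tab2$conc_interfacial_M[1] / tab2$conc_interfacial_M[2]
  expect_equal(ratio, 3.367646, tolerance = 1e-6)
  expect_equal(round(ratio, 2), 3.37)
})

test_that("both fitting routes invert noiseless synthetic series exactly", {
  phis <- seq(0.005, 0.04, length.out = 8)
  ser <- generate_kobs_series(93, 1e4, 1e-4, 0.10, phis, noise_cv = 0)
  for (m in c("nonlinear", "reciprocal-linear")) {
    fit <- fit_partition(ser, method = m)
    expect_equal(fit$p_wi, 93, tolerance = 1e-7)
    expect_equal(fit$k_i, 1e4, tolerance = 1e-7)
  }
  # other generating values, including P < 1
  for (ptrue in c(0.4, 7, 250)) {
    ser2 <- generate_kobs_series(ptrue, 500, 2e-3, 0.10, phis, noise_cv = 0)
    fit2 <- fit_partition(ser2)
    expect_equal(fit2$p_wi, ptrue, tolerance = 1e-7)
    expect_equal(fit2$k_i, 500, tolerance = 1e-7)
  }
})

test_that("nonlinear and reciprocal-linear estimates agree on noisy data", {
  ser <- generate_kobs_series(93, 1e4, 1e-4, 0.10,
                              seq(0.005, 0.04, length.out = 10),
                              noise_cv = 0.03, seed = 5)
  f1 <- fit_partition(ser, "nonlinear")
  f2 <- fit_partition(ser, "reciprocal-linear")
  expect_lt(abs(f1$p_wi - f2$p_wi), 2 * (f1$se_p_wi + f2$se_p_wi))
  expect_gt(f1$se_p_wi, 0)
  expect_gt(f2$se_p_wi, 0)
})

test_that("fit_partition requires at least three distinct surfactant levels", {
  expect_error(kobs_series(c(0.01, 0.01, 0.02), c(1, 1.1, 0.9),
                           ao_total = 1e-4, phi_oil = 0.10),
               "at least 3 distinct")
  expect_error(kobs_series(c(0.01, 0.02, 0.03), c(1, -1, 0.9),
                           ao_total = 1e-4, phi_oil = 0.10),
               "positive")
})

test_that("nonlinear fit matches a dense grid-search oracle", {
  # brute-force oracle: iteratively refined 2-D SSE grid over (P, k_i)
  grid_oracle <- function(ser, p_range, k_range) {
    ao <- attr(ser, "ao_total"); po <- attr(ser, "phi_oil")
    sse <- function(p, k) {
      mu <- ao * k * p / (ser$phi_interfacial * p +
                            (1 - po - ser$phi_interfacial))
      sum((ser$k_obs - mu)^2)
    }
    for (pass in 1:6) {
      ps <- exp(seq(log(p_range[1]), log(p_range[2]), length.out = 41))
      ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = 41))
      val <- outer(ps, ks, Vectorize(sse))
      ix <- which(val == min(val), arr.ind = TRUE)[1, ]
      best <- c(ps[ix[1]], ks[ix[2]])
      span_p <- ps[min(ix[1] + 1, 41)] / ps[max(ix[1] - 1, 1)]
      span_k <- ks[min(ix[2] + 1, 41)] / ks[max(ix[2] - 1, 1)]
      p_range <- best[1] * c(1 / span_p, span_p)
      k_range <- best[2] * c(1 / span_k, span_k)
      if (max(span_p, span_k) < 1.001) break  # 0.1% spacing reached
    }
    best
  }
  ser <- generate_kobs_series(93, 1e4, 1e-4, 0.10,
                              seq(0.005, 0.04, length.out = 8),
                              noise_cv = 0.08, seed = 17)
  fit <- fit_partition(ser)
  oracle <- grid_oracle(ser, c(5, 2000), c(1e3, 1e5))
  expect_equal(fit$p_wi, oracle[1], tolerance = 2e-3)
  expect_equal(fit$k_i, oracle[2], tolerance = 2e-3)
})

test_that("replicated noisy fits recover the generating partition constant", {
  phis <- seq(0.005, 0.04, length.out = 8)
  est <- vapply(1:200, function(s) {
    ser <- generate_kobs_series(93, 1e4, 1e-4, 0.10, phis,
                                noise_cv = 0.05, seed = s)
    fit_partition(ser)$p_wi
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 93), se)
  expect_lt(abs(mean(est) - 93) / 93, 0.02)
})
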