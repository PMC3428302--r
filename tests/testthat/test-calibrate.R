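P <- synthetic_params()

test_that("replicate outlier test eliminates three-sigma deviants", {
  # (100, 102, 200): remaining pair mean 101, sd ~1.41; 200 is eliminated
  keep <- outlier_filter(c(100, 102, 200))
  expect_identical(keep, c(TRUE, TRUE, FALSE))
  expect_identical(outlier_filter(c(100, 101, 102)), rep(TRUE, 3))
  # never fewer than two replicates survive
  expect_gte(sum(outlier_filter(c(0, 1000, 2000))), 2L)
  expect_identical(outlier_filter(c(100, 110)), c(TRUE, TRUE))
})

test_that("preprocessing subtracts background with error propagation", {
  raw <- data.frame(
    probe = rep(c("p1", "Nonsense"), each = 6),
    fa = rep(rep(c(0, 5), each = 3), 2),
    intensity = c(1000, 1010, 1020, 600, 610, 620,   # p1
                  100, 100, 100, 50, 50, 50))        # background
  prof <- preprocess_intensities(raw)
  expect_identical(unique(prof$probe), "p1")
  expect_equal(prof$mean[prof$fa == 0], 1010 - 100)
  expect_equal(prof$mean[prof$fa == 5], 610 - 50)
  # sd in quadrature: background replicates identical, so sd unchanged
  expect_equal(prof$sd[prof$fa == 0], sd(c(1000, 1010, 1020)))
  expect_equal(prof$i_max, rep(910, 2))
  # with zero background the means pass through unchanged
  raw2 <- raw[raw$probe == "p1", ]
  prof2 <- preprocess_intensities(raw2)
  expect_equal(prof2$mean, c(1010, 610))
  # quadrature itself
  m_sd <- 10; b_sd <- 4
  raw3 <- data.frame(probe = rep(c("p", "Nonsense"), each = 2),
                     fa = 0, intensity = c(500 - m_sd, 500 + m_sd,
                                           100 - b_sd, 100 + b_sd))
  prof3 <- preprocess_intensities(raw3)
  expect_equal(prof3$sd, sqrt(sd(c(500 - m_sd, 500 + m_sd))^2 +
                                sd(c(100 - b_sd, 100 + b_sd))^2))
})

test_that("probe filters apply the published intensity thresholds", {
  mk <- function(probe, i0, i5) {
    data.frame(probe = probe, fa = c(0, 5), mean = c(i0, i5), sd = 0,
               n_used = 3L, i_max = max(i0, i5))
  }
  prof <- rbind(mk("pm_dim", 999, 800), mk("pm_ok", 1000, 800),
                mk("mm_dim", 499, 300), mk("mm_ok", 500, 400),
                mk("mm_drop", 1000, 400),   # 60% first-increment drop
                mk("mm_edge", 1000, 500))   # exactly 50%: retained
  classes <- c(pm_dim = "perfect", pm_ok = "perfect", mm_dim = "mismatched",
               mm_ok = "mismatched", mm_drop = "mismatched", mm_edge = "mismatched")
  kept <- unique(filter_probes(prof, classes)$probe)
  expect_setequal(kept, c("pm_ok", "mm_ok", "mm_edge"))
})

test_that("left-of-plateau trimming masks sub-80% points before the maximum", {
  # monotone decreasing profile: nothing masked
  expect_identical(trim_left_of_plateau(c(0, 5, 10), c(10, 8, 5)), rep(TRUE, 3))
  # rising start below 80% of the maximum is masked
  expect_identical(trim_left_of_plateau(c(0, 5, 10), c(0.7, 1.0, 0.5)),
                   c(FALSE, TRUE, TRUE))
  # pointwise oracle on random profiles
  set.seed(91)
  for (i in 1:30) {
    y <- runif(8)
    fa <- fa_series_default()
    got <- trim_left_of_plateau(fa, y)
    am <- which.max(y)
    want <- !(seq_along(y) < am & y < 0.8 * max(y))
    expect_identical(got, want)
  }
})

test_that("experimental half-denaturation interpolates the bracketing pair", {
  # normalized profile with points 0.6 and 0.4 bracketing half-maximum
  expect_equal(fa_half_exp(c(0, 10, 15), c(1.0, 0.6, 0.4)), 12.5)
  # constructed piecewise-linear crossings are recovered exactly
  set.seed(92)
  fa <- fa_series_default()
  for (i in 1:25) {
    true_half <- runif(1, 12, 30)  # keeps both bracketing points on the ramp
    imax <- runif(1, 1000, 30000)
    y <- imax * pmin(1, pmax(0, 1 - (fa - true_half + 10) / 20))  # linear ramp
    if (max(y) < imax) next  # plateau must reach the true maximum exactly
    got <- fa_half_exp(fa, y)
    # the ramp crosses half-maximum at true_half
    expect_equal(got, true_half, tolerance = 1e-9)
  }
  # no crossing: undefined marker
  expect_true(is.na(fa_half_exp(fa, rep(1000, 8))))
})

test_that("gamma policies agree on full plateaus and differ as defined on truncated ones", {
  fa <- fa_series_default()
  eff_full <- hyb_efficiency(-9, fa, P)   # plateau ~1 at 0%
  y <- eff_full / max(eff_full)
  g_fit <- gamma_factor(y, eff_full, "fitted")
  expect_equal(g_fit, 1, tolerance = 0.01)
  expect_equal(gamma_factor(y, eff_full, "unity"), 1)
  expect_equal(gamma_factor(y, eff_full, "inverse_max_eff"), 1 / eff_full[1],
               tolerance = 1e-12)
  # truncated sigmoid with efficiency(0) = 0.5: inverse-max-efficiency gamma = 2
  rt <- P$gas_constant * P$temperature
  dg_half <- rt * log(P$effective_probe_conc)
  eff_tr <- hyb_efficiency(dg_half, fa, P)
  expect_equal(gamma_factor(rep(1, 8), eff_tr, "inverse_max_eff"), 2,
               tolerance = 1e-9)
  # fitted gamma equals the closed-form least-squares ratio
  set.seed(93)
  y2 <- 1.7 * eff_tr
  expect_equal(gamma_factor(y2, eff_tr, "fitted"),
               sum(eff_tr * y2) / sum(eff_tr^2))
})

test_that("gamma factors do not change the melting point of the theoretical curve", {
  set.seed(94)
  fa_grid <- seq(0, 60, by = 0.05)
  for (i in 1:10) {
    dg <- runif(1, -10, -3)
    g <- runif(1, 0.2, 5)
    eff <- hyb_efficiency(dg, fa_grid, P)
    expect_equal(fa_half_exp(fa_grid, eff), fa_half_exp(fa_grid, g * eff),
                 tolerance = 1e-9)
  }
})

test_that("fit statistics define the degrees of freedom and error squares", {
  st <- fit_statistics(ssr = 0.01 * 100, y = NULL, n = 100, n_probes = 10,
                       n_global = 2)
  expect_identical(st$nu, 88)
  expect_equal(st$s2, 1 / 88)
  expect_gte(st$s2, st$mean_sq_resid)  # s2 >= sum r^2 / n always
  # zero residuals give R^2 = 1
  st0 <- fit_statistics(ssr = 0, y = c(1, 2, 3), n = 3, n_probes = 1, n_global = 1)
  expect_equal(st0$r2, 1)
})

test_that("the bi-level fit recovers parameters from noiseless profiles", {
  set.seed(95)
  n_pr <- 40
  dg <- setNames(runif(n_pr, -9, -4), paste0("p", seq_len(n_pr)))
  gam <- setNames(runif(n_pr, 0.8, 1.2), names(dg))
  fa <- fa_series_default()
  prof <- do.call(rbind, lapply(names(dg), function(nm) {
    data.frame(probe = nm, fa = fa,
               y = gam[[nm]] * hyb_efficiency(dg[[nm]], fa, P))
  }))
  fit <- bilevel_fit(prof, dg, P, start = c(m = 0.15, log10_po = -2.5))
  expect_equal(fit$global[["m"]], P$m_value, tolerance = 0.01 * P$m_value)
  expect_equal(fit$global[["log10_po"]], log10(P$effective_probe_conc),
               tolerance = 0.01)
  expect_equal(unname(fit$gammas[names(gam)]), unname(gam), tolerance = 0.01)
  expect_lt(fit$stats$mean_sq_resid, 1e-8)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-6)
  expect_equal(fit$stats$nu, nrow(prof) - (n_pr + 2L))
  # deterministic: same inputs, same result
  fit2 <- bilevel_fit(prof, dg, P, start = c(m = 0.15, log10_po = -2.5))
  expect_identical(fit$global, fit2$global)
})

test_that("missing free energies and bad inputs are reported", {
  prof <- data.frame(probe = "p1", fa = c(0, 5), y = c(1, 0.8))
  expect_error(bilevel_fit(prof, c(px = -5), P), "no free energy")
})
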