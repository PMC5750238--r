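# Ratiometric FRET equations, spectral corrections, flow-cytometry
# quantification, enhancement, dose-response fitting and overlap metrics.

test_that("fret_ratio computes the two-channel ratio with guards", {
  expect_equal(fret_ratio(fret_channels(100, 0)), 0)
  expect_equal(fret_ratio(fret_channels(50, 50)), 0.5)
  expect_equal(fret_ratio(fret_channels(81, 19)), 0.19)
  expect_error(fret_ratio(fret_channels(0, 0)), class = "aptafret_undefined_ratio")
  expect_error(fret_channels(-1, 10))
  # strictly increasing in the sensitized channel at fixed donor channel
  f <- vapply(seq(1, 200, by = 5),
              function(y) fret_ratio(fret_channels(80, y)), numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("correction factors are estimated from the controls", {
  ch <- fret_channels(1, 1, I_Y_exD_emY = 1.5, I_Y_exY_emY = 100,
                      I_D_exD_emY = 7.4, I_D_exD_emD = 100)
  cf <- estimate_corrections(ch)
  expect_equal(cf$a_dir, 0.015)
  expect_equal(cf$d_leak, 0.074)
  expect_false(cf$implausible)
  # compatibility flag reproduces the reciprocal printed orientation
  # (and a factor >= 1 is rightly flagged implausible)
  expect_warning(cfp <- estimate_corrections(ch, printed_orientation = TRUE),
                 "implausible")
  expect_equal(cfp$d_leak, 100 / 7.4)
  # zero-leak controls give zero factors
  ch0 <- fret_channels(1, 1, I_Y_exD_emY = 0, I_Y_exY_emY = 100,
                       I_D_exD_emY = 0, I_D_exD_emD = 100)
  cf0 <- estimate_corrections(ch0)
  expect_equal(c(cf0$a_dir, cf0$d_leak), c(0, 0))
  expect_warning(estimate_corrections(
    fret_channels(1, 1, I_Y_exD_emY = 120, I_Y_exY_emY = 100,
                  I_D_exD_emY = 7, I_D_exD_emD = 100)), "implausible")
})

test_that("corrected FRET reduces to the ratio and clamps overcorrection", {
  ch <- fret_channels(81, 19, I_DY_exY_emY = 50)
  expect_equal(corrected_fret(ch, correction_factors(0, 0))$fret, fret_ratio(ch))
  over <- fret_channels(100, 5, I_DY_exY_emY = 1000)
  res <- corrected_fret(over, correction_factors(0.05, 0.074))
  expect_true(res$clamped)
  expect_equal(res$fret, 0)
})

test_that("noiseless generator reads invert exactly over the factor grid", {
  for (f in seq(0, 0.6, by = 0.1)) for (a in c(0, 0.015, 0.05))
    for (d in c(0, 0.074, 0.15)) {
      s <- sim_spectro_reads(f, correction_factors(a, d), cv = 0)
      est <- estimate_corrections(s$channels)
      expect_equal(est$a_dir, a, tolerance = 1e-12)
      expect_equal(est$d_leak, d, tolerance = 1e-12)
      expect_equal(corrected_fret(s$channels, est)$fret, f, tolerance = 1e-9)
    }
  # corrected <= raw ratio when factors are positive and nothing clamps
  s <- sim_spectro_reads(0.3, correction_factors(0.015, 0.074), cv = 0)
  expect_lt(corrected_fret(s$channels, correction_factors(0.015, 0.074))$fret,
            fret_ratio(s$channels))
})

test_that("noisy spectro reads stay unbiased within a hundredth", {
  est <- vapply(1:100, function(s)
    corrected_fret(sim_spectro_reads(0.3, cv = 0.05, seed = s)$channels,
                   correction_factors(0.015, 0.074))$fret, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.01)
})

test_that("flow-cytometry leak estimation and FRET match the event model", {
  # a donor-only population with FL3/FL1 geometric means 9.15:100
  ev <- data.frame(sample = rep(c("DY", "D_only", "Y_only",
                                  "background_construct"), each = 4),
                   FL1 = c(rep(150, 4), rep(150, 4), rep(50, 4), rep(50, 4)),
                   FL3 = c(rep(100, 4), rep(20 + 9.15, 4), rep(20, 4),
                           rep(20, 4)))
  res <- flow_fret(ev)
  expect_equal(res$d_leak, 9.15 / 100)
  # zero corrected numerator reports FRET = 0
  ev0 <- ev
  ev0$FL3[ev0$sample == "DY"] <- 20 + 0.0915 * 100
  expect_equal(flow_fret(ev0)$fret, 0)
  # degenerate (zero-variance) events recover truth exactly
  s <- sim_flow(0.3, n_events = 50, sdlog = 0, sdlog_chan = 0, seed = 1)
  expect_equal(flow_fret(s$events)$fret, 0.3, tolerance = 1e-12)
  # nonpositive events are excluded, empty gates rejected
  ev$gate <- ev$sample != "DY"
  expect_error(flow_fret(ev), class = "aptafret_empty_gate")
})

test_that("geometric means of log-normal samples converge to the median", {
  set.seed(5)
  x <- rlnorm(50000, meanlog = log(200), sdlog = 0.5)
  g <- aptafret:::geometric_mean(x)
  expect_lt(abs(g$gmean - 200) / 200, 0.02)
  g2 <- aptafret:::geometric_mean(c(x[1:100], -1, 0))
  expect_equal(g2$n_excluded, 2L)
})

test_that("enhancement is the fold ratio with a positive off state", {
  expect_equal(enhancement(5, 5), 1)
  expect_equal(enhancement(500, 5), 100)
  expect_error(enhancement(500, 0), class = "aptafret_invalid")
})

test_that("dose-response fit recovers noiseless truth and flags degeneracy", {
  s <- sim_titration(340e-9, top = 1000, bottom = 50, cv = 0, seed = 1)
  fit <- fit_dose_response(s$series)
  expect_true(fit$converged)
  expect_lt(abs(fit$EC50_M - 340e-9) / 340e-9, 1e-6)
  expect_lt(abs(fit$top - 1000) / 1000, 1e-6)
  expect_true(fit$ec50_in_span)
  # constant response: degenerate, not an exception
  flat <- sim_titration(1e-7, top = 500, bottom = 500, cv = 0, seed = 2)
  expect_true(fit_dose_response(flat$series)$degenerate)
  expect_error(titration_series(c(1e-9, 1e-8, 1e-7), 1, 1:3, 0))
})

test_that("dose-response fit is scale-equivariant", {
  s <- sim_titration(2e-7, top = 800, bottom = 40, cv = 0.03, seed = 9)
  f1 <- fit_dose_response(s$series)
  ts2 <- s$series
  ts2$response <- ts2$response * 7
  ts2$background <- ts2$background * 7
  f2 <- fit_dose_response(ts2)
  expect_equal(f2$EC50_M, f1$EC50_M, tolerance = 1e-6)
  expect_equal(f2$top, 7 * f1$top, tolerance = 1e-6)
  expect_equal(f2$bottom, 7 * f1$bottom, tolerance = 1e-6)
})

test_that("overlap metrics behave on disjoint, identical and Gaussian pairs", {
  grid <- seq(380, 780, by = 0.5)
  g <- function(mu, s) exp(-0.5 * ((grid - mu) / s)^2)
  expect_error(spectral_overlap(spectrum_pair(grid, 0 * grid, g(580, 20))),
               class = "aptafret_invalid")
  dis <- spectrum_pair(grid, g(420, 6), g(740, 6))
  ov <- spectral_overlap(dis)
  expect_lt(ov$overlap_area, 1e-12)
  expect_lt(ov$J / spectral_overlap(spectrum_pair(grid, g(580, 20),
                                                  g(580, 20)))$J, 1e-10)
  same <- spectral_overlap(spectrum_pair(grid, g(503, 15), g(503, 15)))
  expect_equal(same$overlap_area, 1, tolerance = 1e-6)
  # equal-width Gaussian pair: min-overlap has the closed form
  # 2 * pnorm(-|mu1 - mu2| / (2 * sigma))
  mu1 <- 503; mu2 <- 580; s <- 25
  num <- spectral_overlap(spectrum_pair(grid, g(mu1, s), 1e5 * g(mu2, s)))
  expect_lt(abs(num$overlap_area - 2 * pnorm(-abs(mu2 - mu1) / (2 * s))), 1e-4)
  # relative overlap of a pair against itself is 1
  sp <- sim_spectra()
  expect_equal(relative_overlap(sp, sp), 1)
})
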