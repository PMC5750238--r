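## Seeded synthetic-data generators. Every generator is deterministic
## under a fixed seed, returns its ground truth alongside the data, and
## is exactly inverted by its paired analysis operation in the noiseless
## limit. Noise regimes: multiplicative Gaussian for cuvette reads,
## log-normal for flow events, Poisson + Gaussian read noise for images.

## run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  assert_that(is_count(seed), "seed must be an integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate Gaussian-peaked excitation/emission spectra
#'
#' Emulates the dye pair's spectra: Gaussian curves with the measurement
#' wavelengths as defaults (donor DFHBI-1T emission peak 503 nm, acceptor
#' YO3-biotin excitation peak 580 nm). The acceptor curve is scaled to a
#' peak molar extinction so that overlap integrals have spectroscopic
#' units.
#'
#' @param donor_em_peak_nm,acceptor_ex_peak_nm peak wavelengths, nm.
#' @param donor_em_width_nm,acceptor_ex_width_nm Gaussian sd, nm (> 0).
#' @param acceptor_peak_extinction peak molar extinction, M^-1 cm^-1.
#' @param grid_nm wavelength grid (must contain the peaks).
#' @return a [spectrum_pair()].
#' @export
sim_spectra <- function(donor_em_peak_nm = 503, acceptor_ex_peak_nm = 580,
                        donor_em_width_nm = 18, acceptor_ex_width_nm = 22,
                        acceptor_peak_extinction = 1e5,
                        grid_nm = seq(380, 780, by = 1)) {
  assert_that(donor_em_width_nm > 0 && acceptor_ex_width_nm > 0,
              "spectrum widths must be > 0")
  assert_that(donor_em_peak_nm >= min(grid_nm) &&
                donor_em_peak_nm <= max(grid_nm) &&
                acceptor_ex_peak_nm >= min(grid_nm) &&
                acceptor_ex_peak_nm <= max(grid_nm),
              "peaks must lie within the wavelength grid")
  fd <- exp(-0.5 * ((grid_nm - donor_em_peak_nm) / donor_em_width_nm)^2)
  ga <- acceptor_peak_extinction *
    exp(-0.5 * ((grid_nm - acceptor_ex_peak_nm) / acceptor_ex_width_nm)^2)
  spectrum_pair(grid_nm, fd, ga)
}

#' Simulate a three-parameter logistic titration
#'
#' Responses follow `3PL(c) + bg(c)` with multiplicative Gaussian noise
#' `(1 + eps)`, `eps ~ N(0, cv)`; matched background wells (fluorophore
#' without RNA) carry `bg(c)` with the same noise model, emulating
#' triplicate serial dilutions. Defaults: 8 log-spaced doses spanning
#' 1 nM - 2 uM, triplicates.
#'
#' @param ec50_M true EC50, molar (must lie within the dose span).
#' @param top,bottom true plateaus (response units).
#' @param doses_M dose grid, molar.
#' @param n_rep replicates per dose.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param bg0,bg_slope background intercept and per-molar slope.
#' @param seed RNG seed.
#' @return list with `series` (a [titration_series()]) and `truth`
#'   (list `ec50_M`, `log10_EC50`, `top`, `bottom`).
#' @export
sim_titration <- function(ec50_M = 340e-9, top = 1000, bottom = 50,
                          doses_M = 10^seq(log10(1e-9), log10(2e-6),
                                           length.out = 8),
                          n_rep = 3, cv = 0.05,
                          bg0 = 0.02 * top, bg_slope = 0.08 * top / max(doses_M),
                          seed = 1) {
  assert_that(ec50_M >= min(doses_M) && ec50_M <= max(doses_M),
              "true EC50 must lie within the dose span")
  assert_that(cv >= 0, "cv must be >= 0")
  with_seed(seed, {
    grid <- expand.grid(concentration_M = doses_M, replicate = seq_len(n_rep))
    mu <- bottom + (top - bottom) /
      (1 + 10^(log10(ec50_M) - log10(grid$concentration_M)))
    bg <- bg0 + bg_slope * grid$concentration_M
    resp <- (mu + bg) * (1 + stats::rnorm(nrow(grid), 0, cv))
    bgw <- bg * (1 + stats::rnorm(nrow(grid), 0, cv))
    list(series = titration_series(grid$concentration_M, grid$replicate,
                                   resp, bgw),
         truth = list(ec50_M = ec50_M, log10_EC50 = log10(ec50_M),
                      top = top, bottom = bottom))
  })
}

#' Simulate spectrofluorometer reads with known truth
#'
#' Forward model inverted exactly by [corrected_fret()]: with true FRET
#' `f` and scale `S`, donor emission is `(1 - f) * S`, true sensitized
#' emission `f * S`, and the measured acceptor-window channel adds the
#' direct-excitation (`a_dir`) and donor-leak (`d_leak`) contributions.
#' Donor-only and acceptor-only control reads consistent with the same
#' factors are generated alongside. Multiplicative Gaussian noise `cv`.
#'
#' @param f true FRET output in [0, 1).
#' @param cf true [correction_factors()].
#' @param scale donor-excitation intensity scale.
#' @param acceptor_scale direct acceptor-excitation intensity scale.
#' @param cv coefficient of variation (0 = noiseless).
#' @param seed RNG seed.
#' @return list with `channels` (a [fret_channels()]) and `truth`.
#' @export
sim_spectro_reads <- function(f, cf = correction_factors(0.015, 0.074),
                              scale = 1000, acceptor_scale = 800, cv = 0,
                              seed = 1) {
  assert_that(is.numeric(f) && f >= 0 && f < 1, "true FRET must be in [0, 1)")
  with_seed(seed, {
    noisy <- function(x) x * (1 + stats::rnorm(length(x), 0, cv))
    I_dd <- (1 - f) * scale
    I_yy <- acceptor_scale
    I_dy <- f * scale + cf$a_dir * I_yy + cf$d_leak * I_dd
    ch <- fret_channels(
      I_DY_exD_emD = noisy(I_dd),
      I_DY_exD_emY = noisy(I_dy),
      I_DY_exY_emY = noisy(I_yy),
      I_D_exD_emD = noisy(scale),
      I_D_exD_emY = noisy(cf$d_leak * scale),
      I_Y_exD_emY = noisy(cf$a_dir * acceptor_scale),
      I_Y_exY_emY = noisy(acceptor_scale))
    list(channels = ch, truth = list(f = f, a_dir = cf$a_dir,
                                     d_leak = cf$d_leak, scale = scale))
  })
}

#' Simulate flow-cytometry event tables with known truth
#'
#' Log-normal per-event FL1/FL3 intensities around the channel medians
#' implied by true FRET `f` and donor leak: after background subtraction
#' the DY sample has `FL1 = (1 - f) * S` and
#' `FL3 = f * S + d_leak * FL1 + A` where `A` is the directly excited
#' acceptor signal shared with the Y-only sample. Events share a
#' per-event log-normal size factor (sd `sdlog`) with channel-specific
#' log-normal noise (sd `sdlog_chan`); geometric means converge to the
#' medians, so [flow_fret()] recovers `f`. A background-construct
#' population provides the subtraction baseline.
#'
#' @param f true FRET output in [0, 1).
#' @param n_events events per sample (default 50,000 ungated cells).
#' @param scale donor-channel intensity scale S.
#' @param acceptor_signal directly excited acceptor FL3 signal A.
#' @param d_leak true donor leak fraction into FL3.
#' @param bg_FL1,bg_FL3 background-construct channel medians.
#' @param sdlog,sdlog_chan log-normal sds (event size, channel noise).
#' @param seed RNG seed.
#' @return list with `events` (data.frame sample/FL1/FL3/gate) and `truth`.
#' @export
sim_flow <- function(f, n_events = 50000, scale = 1000, acceptor_signal = 300,
                     d_leak = 0.0915, bg_FL1 = 40, bg_FL3 = 25,
                     sdlog = 0.5, sdlog_chan = 0.1, seed = 1) {
  assert_that(is.numeric(f) && f >= 0 && f < 1, "true FRET must be in [0, 1)")
  assert_that(is_count(n_events) && n_events >= 1, "n_events must be >= 1")
  assert_that(sdlog >= 0 && sdlog_chan >= 0, "log-normal sds must be >= 0")
  with_seed(seed, {
    one_sample <- function(label, fl1_med, fl3_med) {
      size <- exp(stats::rnorm(n_events, 0, sdlog))
      data.frame(sample = label,
                 FL1 = fl1_med * size * exp(stats::rnorm(n_events, 0, sdlog_chan)),
                 FL3 = fl3_med * size * exp(stats::rnorm(n_events, 0, sdlog_chan)))
    }
    fl1_dy <- (1 - f) * scale
    fl3_dy <- f * scale + d_leak * fl1_dy + acceptor_signal
    ev <- rbind(
      one_sample("DY", bg_FL1 + fl1_dy, bg_FL3 + fl3_dy),
      one_sample("D_only", bg_FL1 + scale, bg_FL3 + d_leak * scale),
      one_sample("Y_only", bg_FL1, bg_FL3 + acceptor_signal),
      one_sample("background_construct", bg_FL1, bg_FL3))
    ev$gate <- TRUE
    list(events = ev,
         truth = list(f = f, d_leak = d_leak, scale = scale,
                      acceptor_signal = acceptor_signal))
  })
}
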