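## Spectral overlap between donor emission and acceptor excitation: the
## Forster overlap integral J and the area-normalized shaded-overlap
## metric, plus a relative-overlap helper for comparing dye pairs.

#' Donor-emission / acceptor-excitation spectrum pair
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param donor_emission donor emission spectrum (>= 0, arbitrary units).
#' @param acceptor_excitation acceptor excitation spectrum (>= 0;
#'   on a molar-extinction scale, M^-1 cm^-1, if `J` is to be absolute).
#' @return data.frame of class `spectrum_pair`.
#' @export
spectrum_pair <- function(wavelength_nm, donor_emission, acceptor_excitation) {
  assert_that(length(wavelength_nm) == length(donor_emission) &&
                length(wavelength_nm) == length(acceptor_excitation),
              "spectra must share one wavelength grid")
  assert_that(all(diff(wavelength_nm) > 0),
              "wavelength grid must be strictly increasing")
  assert_that(all(donor_emission >= 0) && all(acceptor_excitation >= 0),
              "spectra must be nonnegative")
  structure(data.frame(wavelength_nm = wavelength_nm,
                       donor_emission = donor_emission,
                       acceptor_excitation = acceptor_excitation),
            class = c("spectrum_pair", "data.frame"))
}

#' Spectral overlap metrics
#'
#' `J = integral f_D(l) * eps_A(l) * l^4 dl` with the donor emission
#' area-normalized (trapezoidal quadrature), in M^-1 cm^-1 nm^4 when the
#' acceptor spectrum is on a molar-extinction scale; `overlap_area =
#' integral min(f_D, g_A) dl` with both curves area-normalized, a
#' dimensionless shaded-area overlap in [0, 1].
#'
#' @param sp a [spectrum_pair()].
#' @return list with `J` and `overlap_area`.
#' @export
spectral_overlap <- function(sp) {
  stopifnot(inherits(sp, "spectrum_pair"))
  l <- sp$wavelength_nm
  fd <- sp$donor_emission
  ga <- sp$acceptor_excitation
  area_d <- trapz(l, fd)
  area_a <- trapz(l, ga)
  if (area_d <= 0 || area_a <= 0)
    abort2("all-zero spectrum: overlap undefined", "aptafret_invalid")
  fhat <- fd / area_d
  J <- trapz(l, fhat * ga * l^4)
  overlap_area <- trapz(l, pmin(fhat, ga / area_a))
  list(J = J, overlap_area = overlap_area)
}

#' Relative overlap between two dye pairs
#'
#' Ratio of an overlap metric between a candidate pair and a reference
#' pair, e.g. to quantify how much larger one pair's spectral overlap is.
#'
#' @param sp,sp_ref [spectrum_pair()] objects.
#' @param metric `"J"` or `"overlap_area"`.
#' @return ratio metric(sp) / metric(sp_ref).
#' @export
relative_overlap <- function(sp, sp_ref, metric = c("J", "overlap_area")) {
  metric <- match.arg(metric)
  spectral_overlap(sp)[[metric]] / spectral_overlap(sp_ref)[[metric]]
}
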