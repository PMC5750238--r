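## Ratiometric FRET quantification with spectral corrections.
##
## Intensity symbols follow the sample/excitation/emission convention
## I_<sample>(ex, em): sample DY carries both fluorophores, D donor only,
## Y acceptor only; excitation and emission are at the donor (D) or
## acceptor (Y) wavelength.

#' Intensity channels for ratiometric FRET
#'
#' @param I_DY_exD_emD donor emission under donor excitation, both dyes.
#' @param I_DY_exD_emY acceptor emission under donor excitation, both dyes
#'   (the sensitized-emission channel).
#' @param I_DY_exY_emY acceptor emission under acceptor excitation, both dyes.
#' @param I_D_exD_emD,I_D_exD_emY donor-only controls.
#' @param I_Y_exD_emY,I_Y_exY_emY acceptor-only controls.
#' @return object of class `fret_channels`.
#' @export
fret_channels <- function(I_DY_exD_emD, I_DY_exD_emY, I_DY_exY_emY = NA_real_,
                          I_D_exD_emD = NA_real_, I_D_exD_emY = NA_real_,
                          I_Y_exD_emY = NA_real_, I_Y_exY_emY = NA_real_) {
  ch <- list(I_DY_exD_emD = I_DY_exD_emD, I_DY_exD_emY = I_DY_exD_emY,
             I_DY_exY_emY = I_DY_exY_emY, I_D_exD_emD = I_D_exD_emD,
             I_D_exD_emY = I_D_exD_emY, I_Y_exD_emY = I_Y_exD_emY,
             I_Y_exY_emY = I_Y_exY_emY)
  for (nm in names(ch)) {
    v <- ch[[nm]]
    assert_that(is.numeric(v) && length(v) == 1L && (is.na(v) || v >= 0),
                sprintf("%s must be a single nonnegative intensity", nm))
  }
  structure(ch, class = "fret_channels")
}

#' Ratiometric FRET output
#'
#' The relative FRET value `I_DY(exD, emY) / (I_DY(exD, emY) +
#' I_DY(exD, emD))`: the fraction of donor-excited emission that appears
#' at the acceptor wavelength. A proxy for (not equal to) the physical
#' transfer efficiency.
#'
#' @param ch a [fret_channels()] object (or the two intensities).
#' @return FRET output in [0, 1].
#' @export
fret_ratio <- function(ch) {
  stopifnot(inherits(ch, "fret_channels"))
  den <- ch$I_DY_exD_emY + ch$I_DY_exD_emD
  if (!is.finite(den) || den <= 0)
    abort2("zero total emission: FRET ratio undefined", "aptafret_undefined_ratio")
  ch$I_DY_exD_emY / den
}

#' Estimate spectral correction factors from single-dye controls
#'
#' Direct acceptor excitation: `A_dir = I_Y(exD, emY) / I_Y(exY, emY)`,
#' the fraction of acceptor emission caused by exciting the acceptor at
#' the donor wavelength. Donor leak: the fraction of donor emission
#' bleeding into the acceptor detection window,
#' `D_leak = I_D(exD, emY) / I_D(exD, emD)`. The reciprocal orientation
#' (emD over emY) is available behind `printed_orientation = TRUE` for
#' compatibility; the leak-fraction orientation is the one consistent
#' with typical few-percent leak values and with how the factor enters
#' the corrected FRET equation.
#'
#' @param ch a [fret_channels()] object with single-dye controls.
#' @param printed_orientation use the reciprocal donor-leak orientation.
#' @return object of class `correction_factors`: list with `a_dir`,
#'   `d_leak`, and `implausible` flag (factor >= 1 observed).
#' @export
estimate_corrections <- function(ch, printed_orientation = FALSE) {
  stopifnot(inherits(ch, "fret_channels"))
  need <- c("I_Y_exD_emY", "I_Y_exY_emY", "I_D_exD_emY", "I_D_exD_emD")
  for (nm in need)
    assert_that(is.finite(ch[[nm]]), sprintf("control %s is missing", nm))
  assert_that(ch$I_Y_exY_emY > 0 && ch$I_D_exD_emD > 0,
              "control denominators must be positive", "aptafret_undefined_ratio")
  a_dir <- ch$I_Y_exD_emY / ch$I_Y_exY_emY
  d_leak <- if (printed_orientation) {
    assert_that(ch$I_D_exD_emY > 0, "control denominator must be positive",
                "aptafret_undefined_ratio")
    ch$I_D_exD_emD / ch$I_D_exD_emY
  } else ch$I_D_exD_emY / ch$I_D_exD_emD
  implausible <- a_dir >= 1 || d_leak >= 1
  if (implausible)
    warning("correction factor >= 1: controls look implausible", call. = FALSE)
  correction_factors(a_dir, d_leak, implausible = implausible)
}

#' @rdname estimate_corrections
#' @param a_dir direct acceptor excitation fraction in [0, 1).
#' @param d_leak donor emission leak fraction in [0, 1).
#' @param implausible logical flag carried from estimation.
#' @export
correction_factors <- function(a_dir = 0, d_leak = 0, implausible = FALSE) {
  assert_that(is.numeric(a_dir) && a_dir >= 0, "a_dir must be >= 0")
  assert_that(is.numeric(d_leak) && d_leak >= 0, "d_leak must be >= 0")
  structure(list(a_dir = a_dir, d_leak = d_leak, implausible = implausible),
            class = "correction_factors")
}

#' Spectrally corrected FRET output
#'
#' Subtracts direct acceptor excitation and donor leak from the
#' sensitized-emission channel before forming the ratio:
#' `N = I_DY(exD,emY) - a_dir * I_DY(exY,emY) - d_leak * I_DY(exD,emD)`,
#' `FRET = N / (N + I_DY(exD,emD))`. A negative corrected numerator is
#' clamped to 0 and flagged (a FRET output that is effectively zero),
#' never reported negative. Reduces exactly to [fret_ratio()] when both
#' factors are zero.
#'
#' @param ch a [fret_channels()] object (the `I_DY_exY_emY` channel is
#'   required whenever `a_dir > 0`).
#' @param cf a [correction_factors()] object.
#' @return list with `fret` in [0, 1], `numerator`, and `clamped` flag.
#' @export
corrected_fret <- function(ch, cf = correction_factors()) {
  stopifnot(inherits(ch, "fret_channels"), inherits(cf, "correction_factors"))
  direct <- if (cf$a_dir > 0) {
    assert_that(is.finite(ch$I_DY_exY_emY),
                "I_DY(exY, emY) required when a_dir > 0")
    cf$a_dir * ch$I_DY_exY_emY
  } else 0
  num <- ch$I_DY_exD_emY - direct - cf$d_leak * ch$I_DY_exD_emD
  clamped <- num < 0
  num <- max(num, 0)
  den <- num + ch$I_DY_exD_emD
  if (!is.finite(den) || den <= 0)
    abort2("zero denominator: corrected FRET undefined", "aptafret_undefined_ratio")
  list(fret = num / den, numerator = num, clamped = clamped)
}

#' Fluorescence enhancement on aptamer binding
#'
#' Fold enhancement `F_E = I_(F+R) / I_F`: fluorophore intensity with RNA
#' present over its off-state intensity alone.
#'
#' @param I_fluorophore_plus_RNA,I_fluorophore_alone intensities.
#' @return fold enhancement.
#' @export
enhancement <- function(I_fluorophore_plus_RNA, I_fluorophore_alone) {
  assert_that(is.numeric(I_fluorophore_plus_RNA) && I_fluorophore_plus_RNA >= 0,
              "intensity must be >= 0")
  if (!is.numeric(I_fluorophore_alone) || I_fluorophore_alone <= 0)
    abort2("off-state intensity must be > 0", "aptafret_invalid")
  I_fluorophore_plus_RNA / I_fluorophore_alone
}

#' Flow-cytometry FRET from gated event tables
#'
#' Computes per-sample geometric mean intensities of the FL1 (donor
#' emission) and FL3 (acceptor emission) detectors on gated events,
#' subtracts the background construct's geometric means arithmetically,
#' and evaluates
#' `FRET = (FL3_DY - FL3_Y - d_leak * FL1_DY) /
#'         (FL3_DY - FL3_Y - d_leak * FL1_DY + FL1_DY)`.
#' The donor leak into FL3 can be estimated from the donor-only sample as
#' `FL3_D / FL1_D`. Events with nonpositive intensity are excluded from
#' geometric means and counted.
#'
#' @param events data.frame with columns `sample` (one of `"DY"`,
#'   `"D_only"`, `"Y_only"`, `"background_construct"`), `FL1`, `FL3`, and
#'   optionally a logical `gate` column (default: all gated).
#' @param d_leak donor leak fraction, or `"auto"` to estimate from the
#'   `D_only` sample.
#' @return list with `fret`, `clamped`, `d_leak`, per-sample geometric
#'   mean table `summary`, and background-subtracted `FL1_DY`, `FL3_DY`,
#'   `FL3_Y`.
#' @export
flow_fret <- function(events, d_leak = "auto") {
  assert_that(is.data.frame(events) && all(c("sample", "FL1", "FL3") %in%
                                             names(events)),
              "events must have columns sample, FL1, FL3")
  ok_labels <- c("DY", "D_only", "Y_only", "background_construct")
  assert_that(all(events$sample %in% ok_labels),
              sprintf("sample labels must be among: %s",
                      paste(ok_labels, collapse = ", ")))
  assert_that(all(is.finite(events$FL1)) && all(is.finite(events$FL3)),
              "FL1/FL3 must be finite")
  gate <- if ("gate" %in% names(events)) as.logical(events$gate)
          else rep(TRUE, nrow(events))
  ev <- events[gate, ]
  need <- c("DY", "Y_only", "background_construct")
  for (s in need)
    assert_that(any(ev$sample == s), sprintf("no gated events for sample %s", s),
                "aptafret_empty_gate")

  gm <- function(s, chan) {
    g <- geometric_mean(ev[[chan]][ev$sample == s])
    g$gmean
  }
  samples <- intersect(ok_labels, unique(ev$sample))
  summary <- data.frame(
    sample = samples,
    FL1_gmean = vapply(samples, gm, numeric(1), chan = "FL1"),
    FL3_gmean = vapply(samples, gm, numeric(1), chan = "FL3"),
    n_gated = vapply(samples, function(s) sum(ev$sample == s), integer(1)),
    row.names = NULL)

  bgl1 <- gm("background_construct", "FL1")
  bgl3 <- gm("background_construct", "FL3")
  FL1_DY <- gm("DY", "FL1") - bgl1
  FL3_DY <- gm("DY", "FL3") - bgl3
  FL3_Y <- gm("Y_only", "FL3") - bgl3

  if (identical(d_leak, "auto")) {
    assert_that(any(ev$sample == "D_only"),
                "d_leak = 'auto' needs a D_only sample", "aptafret_empty_gate")
    d_leak <- (gm("D_only", "FL3") - bgl3) / (gm("D_only", "FL1") - bgl1)
  }
  assert_that(is.numeric(d_leak) && d_leak >= 0, "d_leak must be >= 0")

  num <- FL3_DY - FL3_Y - d_leak * FL1_DY
  clamped <- num < 0
  num <- max(num, 0)
  den <- num + FL1_DY
  if (!is.finite(den) || den <= 0)
    abort2("nonpositive denominator: flow FRET undefined",
           "aptafret_undefined_ratio")
  list(fret = num / den, clamped = clamped, d_leak = d_leak,
       summary = summary, FL1_DY = FL1_DY, FL3_DY = FL3_DY, FL3_Y = FL3_Y)
}
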