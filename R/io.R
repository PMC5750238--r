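## Plain-text table IO for the quantification module.

#' Read an intensity-reads CSV into FRET channels
#'
#' Expected columns: `sample` (`DY`, `D`, or `Y`), `excitation` and
#' `emission` (`donor` / `acceptor`), `intensity`. Each (sample,
#' excitation, emission) combination maps onto the corresponding
#' `I_<sample>(ex, em)` channel; replicate rows are averaged.
#'
#' @param path CSV path or a data.frame with the expected columns.
#' @return a [fret_channels()] object.
#' @export
read_intensity_csv <- function(path) {
  x <- if (is.data.frame(path)) path else utils::read.csv(path,
                                                          stringsAsFactors = FALSE)
  need <- c("sample", "excitation", "emission", "intensity")
  assert_that(all(need %in% names(x)),
              sprintf("intensity CSV needs columns: %s",
                      paste(need, collapse = ", ")), "aptafret_parse")
  code <- function(s, ex, em) {
    v <- x$intensity[x$sample == s & x$excitation == ex & x$emission == em]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  fret_channels(I_DY_exD_emD = code("DY", "donor", "donor"),
                I_DY_exD_emY = code("DY", "donor", "acceptor"),
                I_DY_exY_emY = code("DY", "acceptor", "acceptor"),
                I_D_exD_emD = code("D", "donor", "donor"),
                I_D_exD_emY = code("D", "donor", "acceptor"),
                I_Y_exD_emY = code("Y", "donor", "acceptor"),
                I_Y_exY_emY = code("Y", "acceptor", "acceptor"))
}

#' Read a flow-cytometry event CSV
#'
#' Expected columns `sample`, `FL1`, `FL3` (and optionally `gate`); an
#' optional JSON gating config of the form
#' `{"FL1": [lo, hi], "FL3": [lo, hi]}` sets the gate mask from
#' rectangular channel bounds.
#'
#' @param path CSV path or data.frame.
#' @param gating_json optional path to a JSON gating config.
#' @return data.frame ready for [flow_fret()].
#' @export
read_flow_csv <- function(path, gating_json = NULL) {
  x <- if (is.data.frame(path)) path else utils::read.csv(path,
                                                          stringsAsFactors = FALSE)
  assert_that(all(c("sample", "FL1", "FL3") %in% names(x)),
              "flow CSV needs columns sample, FL1, FL3", "aptafret_parse")
  if (!is.null(gating_json)) {
    g <- jsonlite::read_json(gating_json, simplifyVector = TRUE)
    gate <- rep(TRUE, nrow(x))
    for (chan in intersect(names(g), c("FL1", "FL3")))
      gate <- gate & x[[chan]] >= g[[chan]][1] & x[[chan]] <= g[[chan]][2]
    x$gate <- gate
  }
  x
}

#' Read a titration CSV
#'
#' Expected columns `concentration_M`, `replicate`, `response`,
#' `background`.
#'
#' @param path CSV path or data.frame.
#' @return a [titration_series()].
#' @export
read_titration_csv <- function(path) {
  x <- if (is.data.frame(path)) path else utils::read.csv(path,
                                                          stringsAsFactors = FALSE)
  need <- c("concentration_M", "replicate", "response", "background")
  assert_that(all(need %in% names(x)),
              sprintf("titration CSV needs columns: %s",
                      paste(need, collapse = ", ")), "aptafret_parse")
  titration_series(x$concentration_M, x$replicate, x$response, x$background)
}
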