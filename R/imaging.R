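## Single-cell confocal FRET pipeline: segment cells from the donor
## channel, per-cell channel means, bottom-5% acceptor filter, per-cell
## ratiometric FRET and a per-pixel FRET heatmap.

#' Three-channel co-registered image set
#'
#' Channels: `donor` (donor ex / donor em, EGFP window), `acceptor`
#' (acceptor ex / acceptor em, Texas Red window, directly excited), and
#' `fret` (donor ex / acceptor em, the sensitized-emission channel).
#'
#' @param donor,acceptor,fret numeric matrices of identical dimensions,
#'   nonnegative (16-bit counts or equivalent).
#' @param pixel_size_um pixel size, micrometers.
#' @return object of class `image_set`.
#' @export
image_set <- function(donor, acceptor, fret, pixel_size_um = 0.1) {
  chans <- list(donor = donor, acceptor = acceptor, fret = fret)
  for (nm in names(chans)) {
    assert_that(is.matrix(chans[[nm]]) && is.numeric(chans[[nm]]),
                sprintf("%s channel must be a numeric matrix", nm))
    assert_that(all(chans[[nm]] >= 0, na.rm = TRUE),
                sprintf("%s channel must be nonnegative", nm))
    assert_that(identical(dim(chans[[nm]]), dim(donor)),
                "channels must share dimensions")
  }
  structure(c(chans, list(pixel_size_um = pixel_size_um)), class = "image_set")
}

#' Segment cells from the donor channel and measure all channels
#'
#' Cells are located on the donor channel (the one reliably lit in every
#' expressing cell): Gaussian smoothing, Otsu threshold, connected-
#' component labelling, and an area filter. Per-cell mean intensities per
#' pixel are then measured on all three raw channels over each cell's
#' pixels. Optionally (default) a per-channel background -- the median
#' intensity outside the segmentation mask -- is subtracted from the
#' means, flooring at zero.
#'
#' @param imgs an [image_set()].
#' @param smooth_sigma Gaussian smoothing sd in px (0 disables).
#' @param min_area_px,max_area_px component area bounds.
#' @param subtract_background subtract the out-of-mask median per channel.
#' @return list with `cells` (data.frame `label`, `area_px`,
#'   `donor_mean`, `acceptor_mean`, `fret_mean`), `labels` (label matrix,
#'   0 outside cells), and `background` (per-channel offsets subtracted).
#' @export
segment_and_measure <- function(imgs, smooth_sigma = 1, min_area_px = 20,
                                max_area_px = 2000,
                                subtract_background = TRUE) {
  stopifnot(inherits(imgs, "image_set"))
  d <- imgs$donor
  empty <- list(cells = data.frame(label = integer(0), area_px = integer(0),
                                   donor_mean = numeric(0),
                                   acceptor_mean = numeric(0),
                                   fret_mean = numeric(0)),
                labels = matrix(0L, nrow(d), ncol(d)),
                background = c(donor = 0, acceptor = 0, fret = 0))
  if (max(d) <= 0) return(empty)

  sm <- if (smooth_sigma > 0) EBImage::gblur(d, sigma = smooth_sigma) else d
  smn <- sm / max(sm)
  th <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  mask <- smn > th
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow(d), ncol(d))
  if (max(labels) == 0) return(empty)

  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  labels[!(labels %in% keep)] <- 0L
  if (length(keep) == 0) return(empty)

  bg <- c(donor = 0, acceptor = 0, fret = 0)
  if (subtract_background && any(labels == 0))
    bg <- c(donor = stats::median(imgs$donor[labels == 0]),
            acceptor = stats::median(imgs$acceptor[labels == 0]),
            fret = stats::median(imgs$fret[labels == 0]))

  mean_in <- function(chan, lab)
    vapply(keep, function(k) mean(chan[lab == k]), numeric(1))
  cells <- data.frame(
    label = keep,
    area_px = areas[keep],
    donor_mean = pmax(mean_in(imgs$donor, labels) - bg["donor"], 0),
    acceptor_mean = pmax(mean_in(imgs$acceptor, labels) - bg["acceptor"], 0),
    fret_mean = pmax(mean_in(imgs$fret, labels) - bg["fret"], 0),
    row.names = NULL)
  list(cells = cells, labels = labels, background = bg)
}

#' Discard the lowest-acceptor-intensity cells
#'
#' Cells showing no or very low directly excited acceptor fluorescence
#' (no acceptor fluorophore taken up) are removed before FRET analysis:
#' cells are ranked by acceptor-channel mean and the lowest
#' `round(discard_fraction * n)` are marked not kept.
#'
#' @param cells the `cells` data.frame from [segment_and_measure()]
#'   (possibly pooled over an analysis batch of images).
#' @param discard_fraction fraction to discard in `[0, 1)` (default 0.05).
#' @return `cells` with a logical `kept` column; discarded rows ordered
#'   first by acceptor mean.
#' @export
select_cells <- function(cells, discard_fraction = 0.05) {
  assert_that(is.data.frame(cells) && nrow(cells) >= 1,
              "cells must be a nonempty data.frame")
  if (!is.numeric(discard_fraction) || discard_fraction < 0 ||
        discard_fraction >= 1)
    abort2("discard_fraction must be in [0, 1)", "aptafret_invalid")
  n_discard <- round(discard_fraction * nrow(cells))
  ord <- order(cells$acceptor_mean, cells$label)
  cells$kept <- TRUE
  if (n_discard > 0) cells$kept[ord[seq_len(n_discard)]] <- FALSE
  cells
}

#' Per-cell FRET values and the per-pixel FRET heatmap
#'
#' Per-cell FRET uses the ratio of channel means,
#' `fret_mean / (fret_mean + donor_mean)`; the heatmap applies the same
#' ratio per pixel inside the kept cells' boundaries (background-
#' corrected with the offsets from segmentation, components floored at
#' zero), `NA` outside.
#'
#' @param cells a [select_cells()] result (or any cells table; all rows
#'   treated as kept if no `kept` column).
#' @param labels label matrix from [segment_and_measure()].
#' @param imgs the [image_set()].
#' @param background per-channel offsets (from [segment_and_measure()]).
#' @return list with `cells` (adds `fret` and `fret_undefined` columns)
#'   and `heatmap` (matrix, `NA` outside kept cells).
#' @export
cell_fret_and_heatmap <- function(cells, labels, imgs,
                                  background = c(donor = 0, acceptor = 0,
                                                 fret = 0)) {
  stopifnot(inherits(imgs, "image_set"))
  if (!"kept" %in% names(cells)) cells$kept <- TRUE
  assert_that(any(cells$kept), "no kept cells", "aptafret_invalid")
  den <- cells$fret_mean + cells$donor_mean
  cells$fret_undefined <- den <= 0
  cells$fret <- ifelse(cells$fret_undefined, NA_real_, cells$fret_mean / den)

  heat <- matrix(NA_real_, nrow(labels), ncol(labels))
  kept_labels <- cells$label[cells$kept]
  inside <- labels %in% kept_labels
  fpx <- pmax(imgs$fret[inside] - background[["fret"]], 0)
  dpx <- pmax(imgs$donor[inside] - background[["donor"]], 0)
  denpx <- fpx + dpx
  heat[inside] <- ifelse(denpx > 0, fpx / denpx, NaN)
  list(cells = cells, heatmap = heat)
}

#' Read / write a three-channel image set as TIFF
#'
#' `read_image_set` accepts three single-channel 16-bit TIFF files or one
#' 3-page TIFF (page order donor, acceptor, fret). `write_image_set`
#' writes one 16-bit page per channel. `write_heatmap_tiff` writes the
#' FRET heatmap as a two-page 32-bit TIFF: page 1 the FRET values with
#' non-cell pixels set to 0, page 2 the kept-cell mask (TIFF storage is
#' integer-scaled, so `NA` is encoded via the mask page rather than NaN).
#'
#' @param donor,acceptor,fret TIFF paths, or `donor` alone a 3-page TIFF.
#' @param pixel_size_um pixel size, micrometers.
#' @param max_count full-scale count for the 16-bit encoding.
#' @return `read_image_set`: an [image_set()].
#' @export
read_image_set <- function(donor, acceptor = NULL, fret = NULL,
                           pixel_size_um = 0.1, max_count = 65535) {
  as_counts <- function(x) round(x * max_count)
  if (is.null(acceptor)) {
    pages <- tiff::readTIFF(donor, all = TRUE)
    assert_that(length(pages) == 3L, "expected a 3-page TIFF", "aptafret_parse")
    image_set(as_counts(pages[[1]]), as_counts(pages[[2]]),
              as_counts(pages[[3]]), pixel_size_um)
  } else {
    image_set(as_counts(tiff::readTIFF(donor)),
              as_counts(tiff::readTIFF(acceptor)),
              as_counts(tiff::readTIFF(fret)), pixel_size_um)
  }
}

#' @rdname read_image_set
#' @param imgs an [image_set()].
#' @param path output TIFF path.
#' @export
write_image_set <- function(imgs, path, max_count = 65535) {
  stopifnot(inherits(imgs, "image_set"))
  clip <- function(x) pmin(pmax(x, 0), max_count) / max_count
  tiff::writeTIFF(list(clip(imgs$donor), clip(imgs$acceptor),
                       clip(imgs$fret)), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_image_set
#' @param heatmap heatmap matrix from [cell_fret_and_heatmap()].
#' @export
write_heatmap_tiff <- function(heatmap, path) {
  vals <- heatmap
  mask <- !is.na(vals)
  vals[!mask | is.nan(vals)] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  tiff::writeTIFF(list(vals, mask * 1), path, bits.per.sample = 32L)
  invisible(path)
}
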