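## Synthetic confocal images of rod-shaped cells with known per-cell FRET.

## capsule (rod) mask: pixels within `radius` of the segment
## center +/- (len/2) * direction
capsule_mask <- function(ny, nx, center, angle, len, radius) {
  dir <- c(cos(angle), sin(angle))
  a <- center - (len / 2) * dir
  b <- center + (len / 2) * dir
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  px <- xs - a[1]; py <- ys - a[2]
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  denom <- abx^2 + aby^2
  t <- if (denom == 0) 0 else pmin(pmax((px * abx + py * aby) / denom, 0), 1)
  (px - t * abx)^2 + (py - t * aby)^2 <= radius^2
}

draw_mixture <- function(n, mix) {
  w <- mix$weights / sum(mix$weights)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::rnorm(n, mix$means[comp], mix$sds[comp])
}

#' Simulate a three-channel image of rod-shaped cells with known FRET
#'
#' Emulates the single-cell confocal regime: non-overlapping rod-shaped
#' (capsule) cells at random positions and orientations; per-cell true
#' FRET `f` drawn from a 1- or 2-component Gaussian mixture (defaults to
#' the high-FRET construct's single component centered at 0.19); a
#' log-normal donor amplitude per cell with the sensitized-emission
#' amplitude `f / (1 - f)` times it (so the ratio of channel means
#' recovers `f`); an independent log-normal directly excited acceptor
#' amplitude with a dim subpopulation (cells with little acceptor
#' fluorophore, giving the bottom-5% filter realistic work); Gaussian
#' optical blur; Poisson photon noise; Gaussian read noise on top of a
#' constant background offset.
#'
#' @param n_cells number of cells to place.
#' @param fret_mix per-cell FRET mixture: list with `means`, `sds`,
#'   `weights` (recycled to equal length).
#' @param dim_nx,dim_ny image dimensions, px.
#' @param radius_px,len_range_px rod half-width and axis length range.
#' @param donor_meanlog,donor_sdlog log-normal donor amplitude.
#' @param acceptor_meanlog,acceptor_sdlog log-normal acceptor amplitude.
#' @param dim_frac,dim_factor fraction of acceptor-dim cells and their
#'   amplitude multiplier.
#' @param background constant offset, counts.
#' @param blur_sigma optical blur sd, px (0 disables).
#' @param poisson apply Poisson photon noise.
#' @param read_noise_sd Gaussian read noise sd, counts (0 disables).
#' @param max_tries placement retries before an infeasible-packing error.
#' @param seed RNG seed.
#' @return list with `images` (an [image_set()]) and `truth` (list:
#'   `labels` matrix, `cells` data.frame with per-cell `f`, amplitudes,
#'   `dim` flag, geometry).
#' @export
sim_images <- function(n_cells = 25,
                       fret_mix = list(means = 0.19, sds = 0.03, weights = 1),
                       dim_nx = 256, dim_ny = 256,
                       radius_px = 3, len_range_px = c(10, 20),
                       donor_meanlog = log(1500), donor_sdlog = 0.3,
                       acceptor_meanlog = log(2000), acceptor_sdlog = 0.3,
                       dim_frac = 0.075, dim_factor = 0.02,
                       background = 100, blur_sigma = 1, poisson = TRUE,
                       read_noise_sd = 5, max_tries = 200 * n_cells,
                       seed = 1) {
  assert_that(is_count(n_cells) && n_cells >= 1, "n_cells must be >= 1")
  k <- max(lengths(fret_mix))
  mix <- list(means = rep(fret_mix$means, length.out = k),
              sds = rep(fret_mix$sds, length.out = k),
              weights = rep(fret_mix$weights, length.out = k))
  with_seed(seed, {
    labels <- matrix(0L, dim_ny, dim_nx)
    occupied <- matrix(FALSE, dim_ny, dim_nx)
    margin <- radius_px + 2
    geom <- list()
    tries <- 0L
    while (length(geom) < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        abort2(sprintf("could not place %d non-overlapping cells in %dx%d px",
                       n_cells, dim_nx, dim_ny), "aptafret_packing")
      len <- stats::runif(1, len_range_px[1], len_range_px[2])
      half <- len / 2 + margin
      ctr <- c(stats::runif(1, half, dim_nx - half),
               stats::runif(1, half, dim_ny - half))
      ang <- stats::runif(1, 0, pi)
      m <- capsule_mask(dim_ny, dim_nx, ctr, ang, len, radius_px)
      grown <- capsule_mask(dim_ny, dim_nx, ctr, ang, len, radius_px + 2)
      if (any(occupied & grown)) next
      id <- length(geom) + 1L
      labels[m] <- id
      occupied <- occupied | grown
      geom[[id]] <- data.frame(cell = id, center_x = ctr[1], center_y = ctr[2],
                               angle = ang, length_px = len,
                               area_px = sum(m))
    }
    cells <- do.call(rbind, geom)

    cells$f <- pmin(pmax(draw_mixture(n_cells, mix), 0), 0.95)
    cells$donor_amp <- stats::rlnorm(n_cells, donor_meanlog, donor_sdlog)
    cells$acceptor_amp <- stats::rlnorm(n_cells, acceptor_meanlog,
                                        acceptor_sdlog)
    cells$dim <- stats::runif(n_cells) < dim_frac
    cells$acceptor_amp[cells$dim] <- cells$acceptor_amp[cells$dim] * dim_factor

    paint <- function(amp) {
      img <- matrix(0, dim_ny, dim_nx)
      for (id in seq_len(n_cells)) img[labels == id] <- amp[id]
      img
    }
    donor <- paint(cells$donor_amp * (1 - cells$f))
    fretc <- paint(cells$donor_amp * cells$f)
    accep <- paint(cells$acceptor_amp)

    finish <- function(img) {
      if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma)
      img <- img + background
      if (poisson)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), dim_ny, dim_nx)
      if (read_noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, read_noise_sd)
      ## noisy output is quantized to detector counts; the noiseless limit
      ## stays real-valued so it inverts the forward model exactly
      if (poisson || read_noise_sd > 0) img <- round(img)
      pmin(pmax(img, 0), 65535)
    }
    imgs <- image_set(finish(donor), finish(accep), finish(fretc))
    list(images = imgs, truth = list(labels = labels, cells = cells))
  })
}
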