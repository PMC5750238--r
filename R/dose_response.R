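## Background-subtracted three-parameter log dose-response (EC50) fitting:
## y = bottom + (top - bottom) / (1 + 10^(log10(EC50) - log10(c))),
## the Hill slope fixed at 1 ("log(agonist) vs. response, three
## parameters"). Nonlinear least squares via minpack.lm.

#' Titration series container
#'
#' @param concentration_M ligand concentrations, molar (> 0), one per row.
#' @param replicate replicate index.
#' @param response measured response.
#' @param background matched no-RNA background response per row.
#' @return data.frame of class `titration_series`.
#' @export
titration_series <- function(concentration_M, replicate, response, background) {
  assert_that(all(concentration_M > 0), "concentrations must be > 0")
  ts <- data.frame(concentration_M = concentration_M, replicate = replicate,
                   response = response, background = background)
  n_conc <- length(unique(ts$concentration_M))
  assert_that(n_conc >= 4L,
              sprintf("need >= 4 distinct concentrations for fitting (got %d)",
                      n_conc))
  reps <- table(ts$concentration_M)
  assert_that(length(unique(as.integer(reps))) == 1L,
              "replicate counts differ across concentrations")
  structure(ts, class = c("titration_series", "data.frame"))
}

#' Fit a three-parameter log dose-response curve
#'
#' Background responses are subtracted per concentration (means over
#' replicates), the model is fitted to replicate means by least squares
#' with equal weights, and EC50 is reported in molar. A constant response
#' or an EC50 outside the tested span is flagged rather than raised.
#'
#' @param ts a [titration_series()] (or a data.frame with its columns).
#' @return object of class `dose_response_fit`: list with `log10_EC50`,
#'   `EC50_M`, `bottom`, `top`, `residual_norm`, `converged`,
#'   `degenerate`, `ec50_in_span`, and the fitted means table `data`.
#' @export
fit_dose_response <- function(ts) {
  if (!inherits(ts, "titration_series"))
    ts <- titration_series(ts$concentration_M, ts$replicate, ts$response,
                           ts$background)
  agg <- aggregate(cbind(response, background) ~ concentration_M, ts, mean)
  agg <- agg[order(agg$concentration_M), ]
  agg$y <- agg$response - agg$background
  agg$l10c <- log10(agg$concentration_M)

  out <- list(log10_EC50 = NA_real_, EC50_M = NA_real_,
              bottom = NA_real_, top = NA_real_, residual_norm = NA_real_,
              converged = FALSE, degenerate = FALSE, ec50_in_span = NA,
              data = agg)
  class(out) <- "dose_response_fit"

  span <- diff(range(agg$y))
  if (!is.finite(span) || span <= .Machine$double.eps^0.5 *
        max(abs(agg$y), 1)) {
    out$degenerate <- TRUE
    return(out)
  }

  ## start values: end plateaus and the half-rise concentration
  b0 <- min(agg$y); t0 <- max(agg$y)
  half <- (b0 + t0) / 2
  i <- which(agg$y >= half)[1]
  l0 <- if (is.na(i) || i == 1L) stats::median(agg$l10c) else
    stats::approx(agg$y[(i - 1):i], agg$l10c[(i - 1):i], xout = half,
                  ties = "ordered")$y
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^(logec50 - l10c)),
    data = agg, start = list(bottom = b0, top = t0, logec50 = l0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(out)

  cf <- stats::coef(fit)
  out$log10_EC50 <- unname(cf["logec50"])
  out$EC50_M <- 10^out$log10_EC50
  out$bottom <- unname(cf["bottom"])
  out$top <- unname(cf["top"])
  if (out$bottom > out$top) {  # falling curve: report in bottom <= top order
    tmp <- out$bottom; out$bottom <- out$top; out$top <- tmp
  }
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$converged <- isTRUE(fit$convInfo$isConv)
  out$ec50_in_span <- out$log10_EC50 >= min(agg$l10c) &&
    out$log10_EC50 <= max(agg$l10c)
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) cat("<dose_response_fit> degenerate (constant response)\n")
  else cat(sprintf(
    "<dose_response_fit> EC50 = %.3g M  [bottom %.3g, top %.3g]  converged: %s%s\n",
    x$EC50_M, x$bottom, x$top, x$converged,
    if (isFALSE(x$ec50_in_span)) "  (EC50 outside tested span)" else ""))
  invisible(x)
}
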