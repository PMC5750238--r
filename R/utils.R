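#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "aptafret_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "aptafret_invalid") {
  if (!isTRUE(ok)) abort2(msg, class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

## trapezoidal integral on an arbitrary strictly increasing grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

## geometric mean over strictly positive values; nonpositive entries are
## excluded and counted (cytometry baseline artifacts make log undefined)
geometric_mean <- function(x) {
  bad <- !is.finite(x) | x <= 0
  kept <- x[!bad]
  assert_that(length(kept) > 0, "no positive values for geometric mean",
              "aptafret_empty_gate")
  list(gmean = exp(mean(log(kept))), n_used = length(kept),
       n_excluded = sum(bad))
}
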