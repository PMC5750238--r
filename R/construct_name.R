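## The SX-MY construct nomenclature: signed stem offsets (bp) of the donor
## aptamer (Spinach or Broccoli) and of Mango from the reference crossover,
## a flip flag on the donor (S* / B*), and a kissing-loop flag.

#' Construct specification for an apta-FRET 2H-AE tile
#'
#' A construct is named `SX-MY`: `X` and `Y` are the stem lengths, in base
#' pairs, from the reference crossover (the one nearest the 5' end) to the
#' donor aptamer and to Mango. Positive offsets place the aptamer on the
#' near side of the reference crossover, negative offsets on the far side
#' (the `S(-31)-M30` no-FRET control has its fluorophores on opposite
#' sides, ~18 nm apart). A flipped donor (attached via its other flanking
#' helix, dipole pointing away from the acceptor helix) is annotated with
#' an asterisk, e.g. `S*5-M5`.
#'
#' @param spinach_offset_bp,mango_offset_bp signed, nonzero stem offsets (bp).
#' @param spinach_flipped logical; donor attached via its other flanking helix.
#' @param has_kissing_loop logical; internal KL pairs present.
#' @param donor_motif `"SPINACH"` or `"BROCCOLI"`.
#' @return object of class `construct_spec`.
#' @examples
#' construct_name(construct_spec(5, 5, spinach_flipped = TRUE))
#' parse_name("S(-31)-M30")
#' @export
construct_spec <- function(spinach_offset_bp, mango_offset_bp,
                           spinach_flipped = FALSE, has_kissing_loop = TRUE,
                           donor_motif = c("SPINACH", "BROCCOLI")) {
  donor_motif <- match.arg(donor_motif)
  assert_that(is_count(spinach_offset_bp) && spinach_offset_bp != 0,
              "spinach_offset_bp must be a nonzero integer")
  assert_that(is_count(mango_offset_bp) && mango_offset_bp != 0,
              "mango_offset_bp must be a nonzero integer")
  structure(list(spinach_offset_bp = as.integer(spinach_offset_bp),
                 mango_offset_bp = as.integer(mango_offset_bp),
                 spinach_flipped = isTRUE(spinach_flipped),
                 has_kissing_loop = isTRUE(has_kissing_loop),
                 donor_motif = donor_motif),
            class = "construct_spec")
}

fmt_offset <- function(x) if (x < 0) sprintf("(%d)", x) else sprintf("%d", x)

#' Format a construct specification as its SX-MY name
#'
#' @param spec a [construct_spec()].
#' @return the construct name, e.g. `"S*5-M5"` or `"S(-31)-M30"`.
#' @export
construct_name <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  donor_letter <- if (spec$donor_motif == "BROCCOLI") "B" else "S"
  paste0(donor_letter, if (spec$spinach_flipped) "*" else "",
         fmt_offset(spec$spinach_offset_bp), "-M",
         fmt_offset(spec$mango_offset_bp))
}

#' Parse an SX-MY construct name
#'
#' Exact inverse of [construct_name()]. Kissing-loop presence is not
#' encoded in the name and defaults to `TRUE`.
#'
#' @param name construct name, e.g. `"S*16-M16"`.
#' @inheritParams construct_spec
#' @return a [construct_spec()].
#' @export
parse_name <- function(name, has_kissing_loop = TRUE) {
  assert_that(is.character(name) && length(name) == 1L, "name must be a string")
  off <- "(\\((-\\d+)\\)|(-?\\d+))"
  pat <- paste0("^([SB])(\\*?)", off, "-M", off, "$")
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (length(m) == 0)
    abort2(sprintf("cannot parse construct name '%s'", name), "aptafret_format")
  pick <- function(paren, plain) as.integer(if (nzchar(paren)) paren else plain)
  s_off <- pick(m[5], m[6])
  m_off <- pick(m[8], m[9])
  if (is.na(s_off) || is.na(m_off) || s_off == 0 || m_off == 0)
    abort2(sprintf("offsets in '%s' must be nonzero integers", name),
           "aptafret_format")
  ## parenthesized positive offsets are not part of the nomenclature
  if ((nzchar(m[5]) && s_off > 0) || (nzchar(m[8]) && m_off > 0))
    abort2(sprintf("cannot parse construct name '%s'", name), "aptafret_format")
  construct_spec(s_off, m_off,
                 spinach_flipped = m[3] == "*",
                 has_kissing_loop = has_kissing_loop,
                 donor_motif = if (m[2] == "B") "BROCCOLI" else "SPINACH")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("<construct_spec> %s  (donor %s%s, KL %s)\n", construct_name(x),
              x$donor_motif, if (x$spinach_flipped) ", flipped" else "",
              if (x$has_kissing_loop) "present" else "absent"))
  invisible(x)
}
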