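## Sequence-design constraints for a traced construct, ready for external
## sequence-design software: the T7 initiation sequence 5'-GGGAGA at the
## 5' end, G-C "locks" on the base pair flanking every strand-exchange
## point, a GU wobble pair per every eight continuous base pairs in each
## uninterrupted duplex segment, conserved motif bases, N elsewhere.

RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Emit the per-position sequence constraints for a traced construct
#'
#' Position codes are `A`, `C`, `G`, `U` (fixed), `N` (designable) and `W`
#' (both partners of a designated GU wobble pair). Fixed positions come
#' from conserved motif bases, the 5'-GGGAGA initiation sequence (with
#' complementary bases forced on tier-1 partners), and the G-C crossover
#' locks; lock orientation alternates G-C / C-G along the trace to avoid
#' G runs. Within every maximal continuous duplex segment a GU pair is
#' designated every eighth pair from the segment's left end, shifting left
#' to the nearest designable pair when the slot is fixed; a fully fixed
#' window yields a warning record, never an altered fixed base.
#'
#' @param tr a [trace_strand()] result.
#' @param ss matching [build_structure()] result.
#' @param lib motif library.
#' @param spec optional [construct_spec()] carried as metadata.
#' @param gu_window maximal run of consecutive non-GU pairs (default 8).
#' @return a `constraint_string`: list with `n`, `string`, `chars`,
#'   `wobble` (logical per position), `source`, `gu_pairs` (data.frame),
#'   and `warnings`.
#' @export
emit_constraints <- function(tr, ss, lib = motif_library(), spec = NULL,
                             gu_window = 8L) {
  stopifnot(inherits(tr, "strand_trace"), inherits(ss, "secondary_structure"))
  n <- nrow(tr)
  assert_that(ss$n == n, "trace and structure lengths differ")
  letters <- rep("N", n)
  source <- rep("", n)
  wobble <- logical(n)
  warnings <- character(0)

  fix <- function(i, base, src) {
    if (wobble[i])
      abort2(sprintf("position %d: %s conflicts with GU designation", i, src),
             "aptafret_constraint_conflict")
    if (letters[i] != "N" && letters[i] != base)
      abort2(sprintf(
        "position %d: %s wants '%s' but '%s' already fixed by %s",
        i, src, base, letters[i], source[i]), "aptafret_constraint_conflict")
    letters[i] <<- base
    if (!nzchar(source[i])) source[i] <<- src
  }

  ## conserved motif bases
  mot <- which(tr$source == "motif")
  for (i in mot) fix(i, tr$base[i], "motif")

  ## 5' initiation sequence and its duplex partners
  t7 <- c("G", "G", "G", "A", "G", "A")
  assert_that(n >= 6L, "trace shorter than the initiation sequence")
  for (i in 1:6) {
    if (tr$source[i] == "motif" && tr$base[i] != t7[i])
      abort2(sprintf(
        "5' initiation sequence overlaps conserved motif base at position %d",
        i), "aptafret_constraint_conflict")
    fix(i, t7[i], "five_prime")
    j <- ss$pair_table[i]
    if (j > 0 && ss$tier[i] == 1L && !(j %in% 1:6))
      fix(j, RNA_COMPLEMENT[[t7[i]]], "five_prime_partner")
  }

  bp <- attr(tr, "blueprint")
  dup <- tr[tr$source == "duplex", ]
  col_idx <- function(h, cc) sort(dup$idx[dup$helix == h & dup$column == cc])

  ## G-C locks on the pair at column x+1 of each helix at each crossover;
  ## orientation alternates along the trace
  xcols <- sort(bp$crossovers$pos_a)
  locks <- list()
  for (x in xcols) for (h in c(1L, 2L)) {
    ij <- col_idx(h, x + 1L)
    if (length(ij) == 2L) locks[[length(locks) + 1L]] <- ij
  }
  if (length(locks) > 0) {
    ord <- order(vapply(locks, min, numeric(1)))
    for (r in seq_along(ord)) {
      ij <- locks[[ord[r]]]
      b5 <- if (r %% 2L == 1L) "G" else "C"
      fix(ij[1], b5, "gc_lock")
      fix(ij[2], RNA_COMPLEMENT[[b5]], "gc_lock")
    }
  }

  ## GU wobble designation per maximal continuous duplex segment
  len <- function(h) bp$helices$length_bp[bp$helices$id == h]
  gu_pairs <- list()
  for (h in c(1L, 2L)) {
    breaks <- xcols  # strand exchange between x and x+1
    klm <- bp$motifs[bp$motifs$helix == h, ]
    for (k in seq_len(nrow(klm)))
      if (lib[[klm$motif_id[k]]]$kind == "kl") breaks <- c(breaks, klm$pos[k])
    bounds <- sort(unique(c(0L, breaks, len(h))))
    for (s in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[s] + 1L):bounds[s + 1L]
      designable <- vapply(seg, function(cc) {
        ij <- col_idx(h, cc)
        length(ij) == 2L && all(letters[ij] == "N") && !any(wobble[ij])
      }, logical(1))
      last_gu <- seg[1] - 1L
      for (cc in seg) {
        if (cc - last_gu == gu_window) {
          window <- seg[seg > last_gu & seg <= cc]
          cand <- window[designable[match(window, seg)]]
          if (length(cand) > 0) {
            d <- max(cand)
            ij <- col_idx(h, d)
            wobble[ij] <- TRUE
            letters[ij] <- "W"
            source[ij] <- "gu_wobble"
            designable[match(d, seg)] <- FALSE
            gu_pairs[[length(gu_pairs) + 1L]] <-
              data.frame(helix = h, column = d, idx_5p = ij[1], idx_3p = ij[2])
            last_gu <- d
          } else {
            warnings <- c(warnings, sprintf(
              "helix %d columns %d-%d: fully fixed window, GU rule unsatisfiable",
              h, last_gu + 1L, cc))
            last_gu <- cc
          }
        }
      }
    }
  }

  structure(list(n = n, chars = letters, string = paste(letters, collapse = ""),
                 wobble = wobble, source = source,
                 gu_pairs = if (length(gu_pairs)) do.call(rbind, gu_pairs)
                            else data.frame(helix = integer(0), column = integer(0),
                                            idx_5p = integer(0), idx_3p = integer(0)),
                 warnings = warnings, spec = spec),
            class = "constraint_string")
}

#' @export
print.constraint_string <- function(x, ...) {
  cat(sprintf("<constraint_string> %d nt, %d fixed, %d GU pair(s), %d warning(s)\n",
              x$n, sum(!x$chars %in% c("N", "W")), nrow(x$gu_pairs),
              length(x$warnings)))
  invisible(x)
}
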