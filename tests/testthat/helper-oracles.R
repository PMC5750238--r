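# Independent oracles, kept deliberately separate from the package
# implementations they check.

# independent stack parser for two-tier dot-bracket strings
oracle_parse_db <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  for (br in list(c("(", ")"), c("[", "]"))) {
    st <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == br[1]) st <- c(st, i)
      else if (ch[i] == br[2]) {
        stopifnot(length(st) > 0)
        pt[i] <- st[length(st)]
        pt[st[length(st)]] <- i
        st <- st[-length(st)]
      }
    }
    stopifnot(length(st) == 0)
  }
  pt
}

# residue count implied by a blueprint + motif library, by direct counting
oracle_residue_count <- function(bp, lib) {
  n <- 2L * sum(bp$helices$length_bp)
  for (k in seq_len(nrow(bp$motifs))) {
    m <- lib[[bp$motifs$motif_id[k]]]
    n <- n + sum(vapply(m$segments, function(s) nchar(s$seq), integer(1)))
  }
  n
}

# maximal run of consecutive non-GU base-pair columns, scanned per
# continuous duplex segment straight from the blueprint records
oracle_max_canonical_run <- function(bp, tr, cs, lib) {
  xcols <- sort(bp$crossovers$pos_a)
  dup <- tr[tr$source == "duplex", ]
  worst <- 0L
  for (h in c(1L, 2L)) {
    L <- bp$helices$length_bp[bp$helices$id == h]
    breaks <- xcols
    mh <- bp$motifs[bp$motifs$helix == h, ]
    for (k in seq_len(nrow(mh)))
      if (lib[[mh$motif_id[k]]]$kind == "kl") breaks <- c(breaks, mh$pos[k])
    bounds <- sort(unique(c(0L, breaks, L)))
    for (s in seq_len(length(bounds) - 1L)) {
      run <- 0L
      for (cc in (bounds[s] + 1L):bounds[s + 1L]) {
        idx <- dup$idx[dup$helix == h & dup$column == cc]
        is_gu <- any(cs$chars[idx] == "W")
        run <- if (is_gu) 0L else run + 1L
        worst <- max(worst, run)
      }
    }
  }
  worst
}

# minimal legal 2H-AE blueprint text builders
bp_text_flagship <- function() readLines(flagship_blueprint_path(), warn = FALSE)

bp_text_plain <- function(L = 20, x1 = 5, x2 = 15) {
  c(sprintf("HELIX 1 %d", L), sprintf("HELIX 2 %d", L),
    sprintf("XOVER 1 %d 2 %d", x1, x1), sprintf("XOVER 1 %d 2 %d", x2, x2))
}

# a fully capped single-strand tile: caps at all four ends, KL mid-helix 1
bp_text_capped <- function(L = 30, x1 = 5, x2 = 24, kl = 14, end5 = "END5 2 12 bottom") {
  c("NAME capped", bp_text_plain(L, x1, x2),
    "MOTIF TETRALOOP_UUCG 1 1 normal", sprintf("MOTIF TETRALOOP_UUCG 1 %d normal", L),
    "MOTIF TETRALOOP_UUCG 2 1 normal", sprintf("MOTIF TETRALOOP_UUCG 2 %d normal", L),
    sprintf("MOTIF KL180 1 %d normal", kl), end5)
}
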