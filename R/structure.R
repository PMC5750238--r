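## Secondary structure of a traced strand: involutive pair table with a
## nested tier (1, round brackets) for duplex and motif-internal pairs and
## a pseudoknot tier (2, square brackets) for kissing-loop pairs.

#' Build the secondary structure of a traced strand
#'
#' Pairs every duplex residue with its partner across the helix (tier 1),
#' adds motif-internal pairs from the library's bracket snippets (tier 1),
#' and adds the loop-loop pairs of kissing loops on the pseudoknot tier
#' (tier 2). Tier-2 pairs are omitted when `kissing = FALSE`, which models
#' the no-KL control constructs (hairpins retained, loops not kissing).
#'
#' @param tr a [trace_strand()] result.
#' @param lib motif library.
#' @param kissing include kissing-loop pairs (default `TRUE`).
#' @return a `secondary_structure`: list with `n`, `pair_table` (partner
#'   index per position, 0 = unpaired), `tier` (0/1/2 per position) and
#'   `dot_bracket`.
#' @export
build_structure <- function(tr, lib = motif_library(), kissing = TRUE) {
  stopifnot(inherits(tr, "strand_trace"))
  n <- nrow(tr)
  pt <- integer(n)
  tier <- integer(n)

  add_pair <- function(i, j, tr_tier) {
    if (i < 1 || j < 1 || i > n || j > n)
      abort2("motif pair references residues outside the trace",
             "aptafret_consistency")
    if (pt[i] != 0 || pt[j] != 0 || i == j)
      abort2(sprintf("conflicting or self pair (%d, %d)", i, j),
             "aptafret_consistency")
    pt[i] <<- j; pt[j] <<- i
    tier[i] <<- tr_tier; tier[j] <<- tr_tier
  }

  ## duplex pairs: top/bottom residues sharing a (helix, column)
  dup <- tr[tr$source == "duplex", ]
  key <- paste(dup$helix, dup$column)
  for (cell in split(dup$idx, key)) {
    if (length(cell) != 2L)
      abort2("duplex column not visited by exactly two strands",
             "aptafret_consistency")
    add_pair(cell[1], cell[2], 1L)
  }

  ## motif-internal pairs (from each oriented fragment's bracket snippet)
  mot <- tr[tr$source == "motif", ]
  for (inst in unique(mot$motif_instance)) {
    mrows <- mot[mot$motif_instance == inst, ]
    motif <- lib[[mrows$motif_id[1]]]
    bpnt <- attr(tr, "blueprint")
    flipped <- bpnt$motifs$orientation[inst] == "flipped"
    for (seg in unique(mrows$segment)) {
      fr <- motif$segments[[seg]]
      if (motif$kind == "cap" && flipped) fr <- flip_fragment(fr)
      prs <- parse_bracket_pairs(fr$db)
      srows <- mrows[mrows$segment == seg, ]
      at <- function(p) srows$idx[match(p, srows$seg_pos)]
      if (nrow(prs) > 0)
        for (r in seq_len(nrow(prs))) add_pair(at(prs[r, 1]), at(prs[r, 2]), 1L)
    }
    ## tier-2 kissing pairs between loop_a and loop_b
    if (motif$kind == "kl" && kissing) {
      arow <- mrows[mrows$segment == "loop_a", ]
      brow <- mrows[mrows$segment == "loop_b", ]
      for (r in seq_len(nrow(motif$kl_pairs)))
        add_pair(arow$idx[match(motif$kl_pairs[r, 1], arow$seg_pos)],
                 brow$idx[match(motif$kl_pairs[r, 2], brow$seg_pos)], 2L)
    }
  }

  db <- dot_bracket_from_pairs(pt, tier)
  structure(list(n = n, pair_table = pt, tier = tier, dot_bracket = db),
            class = "secondary_structure")
}

## render + validate: tier 1 must be properly nested, tier 2 balanced
dot_bracket_from_pairs <- function(pt, tier) {
  n <- length(pt)
  ch <- rep(".", n)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j == 0) next
    if (pt[j] != i || j == i)
      abort2("pair table is not an involution", "aptafret_consistency")
    if (i < j) {
      br <- if (tier[i] == 2L) c("[", "]") else c("(", ")")
      ch[i] <- br[1]; ch[j] <- br[2]
    }
  }
  db <- paste(ch, collapse = "")
  ## a stack re-parse must reproduce the pair table exactly on each tier;
  ## crossing pairs within a tier would re-pair differently (or unbalance)
  for (tspec in list(list(t = 1L, br = c("(", ")")),
                     list(t = 2L, br = c("[", "]")))) {
    prs <- parse_bracket_pairs(db, tspec$br[1], tspec$br[2])
    pt2 <- integer(n)
    if (nrow(prs) > 0) {
      pt2[prs[, 1]] <- prs[, 2]; pt2[prs[, 2]] <- prs[, 1]
    }
    sel <- tier == tspec$t
    if (!identical(pt2[sel], pt[sel]) || any(pt2[!sel] != 0))
      abort2(sprintf("tier-%d pairs are not nested", tspec$t),
             "aptafret_consistency")
  }
  db
}

#' Parse a (possibly pseudoknotted) dot-bracket string
#'
#' Round brackets form the nested tier (1), square brackets the
#' pseudoknot tier (2). Inverse of the `dot_bracket` field produced by
#' [build_structure()].
#'
#' @param db dot-bracket string over `. ( ) [ ]`.
#' @return list with `pair_table` and `tier`.
#' @export
parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")", "[", "]"))
  if (length(bad) > 0)
    abort2(sprintf("invalid dot-bracket character(s): %s",
                   paste(bad, collapse = " ")), "aptafret_structure")
  n <- length(chars)
  pt <- integer(n); tier <- integer(n)
  for (tspec in list(list(t = 1L, br = c("(", ")")),
                     list(t = 2L, br = c("[", "]")))) {
    prs <- parse_bracket_pairs(db, tspec$br[1], tspec$br[2])
    if (nrow(prs) > 0) for (r in seq_len(nrow(prs))) {
      pt[prs[r, 1]] <- prs[r, 2]; pt[prs[r, 2]] <- prs[r, 1]
      tier[prs[r, 1]] <- tspec$t; tier[prs[r, 2]] <- tspec$t
    }
  }
  list(pair_table = pt, tier = tier)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d tier-1 and %d tier-2 pairs\n",
              x$n, sum(x$tier == 1L) / 2L, sum(x$tier == 2L) / 2L))
  invisible(x)
}
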