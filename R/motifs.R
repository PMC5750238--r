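## Packaged library of conserved RNA motifs used on 2H-AE tiles.
##
## Two motif kinds exist at blueprint level:
##  * "cap"  -- closes one end of a helix (terminal tetraloop, or an aptamer
##    whose core + terminal stem-loop caps the stem it sits on). A cap is a
##    single linear fragment inserted between the two strand ends at the
##    anchored column; its internal secondary structure is given as a
##    dot-bracket snippet over the fragment.
##  * "kl"   -- an internal kissing loop: the host helix is cut between
##    columns pos and pos+1 and each arm is closed by a hairpin loop; the
##    two loops base-pair with each other on the pseudoknot tier (tier 2).
##
## Conserved sequences: the kissing loop is the HIV-1 DIS loop (bulged
## purines flanking the self-complementary GCGCGC core); the tetraloop is
## UUCG. The aptamer cores (Spinach, Broccoli, Mango G-quadruplex, SAM-I
## riboswitch) are representative conserved cores in the style of the
## published minimal aptamers; they are internally consistent with their
## pair lists and footprints but are placeholders where no sequence is
## packaged with a deposited structure.

## stack-parse a single-tier bracket snippet into a 2-column pair matrix
parse_bracket_pairs <- function(db, open = "(", close = ")") {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == open) stack <- c(stack, i)
    else if (chars[i] == close) {
      if (length(stack) == 0)
        abort2(sprintf("unbalanced '%s' at position %d in '%s'", close, i, db),
               "aptafret_structure")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    abort2(sprintf("unbalanced '%s' in '%s'", open, db), "aptafret_structure")
  pairs
}

cap_motif <- function(id, seq, db, description) {
  stopifnot(nchar(seq) == nchar(db))
  list(id = id, kind = "cap", footprint_bp = 1L,
       segments = list(cap = list(seq = seq, db = db)),
       kl_pairs = NULL, description = description)
}

## stem-loop helper: stem + apex(UUCG) + reverse-complement stem
stem_loop <- function(stem, loop = "UUCG") {
  seq <- paste0(stem, loop, rna_revcomp(stem))
  db <- paste0(strrep("(", nchar(stem)), strrep(".", nchar(loop)),
               strrep(")", nchar(stem)))
  list(seq = seq, db = db)
}

aptamer_cap <- function(id, core5, stem, core3, description) {
  sl <- stem_loop(stem)
  cap_motif(id,
            seq = paste0(core5, sl$seq, core3),
            db = paste0(strrep(".", nchar(core5)), sl$db,
                        strrep(".", nchar(core3))),
            description = description)
}

#' The packaged motif library
#'
#' Conserved motifs placeable on 2H-AE blueprints: the Spinach, Broccoli
#' and Mango fluorogenic aptamer caps, the SAM-I riboswitch sensor cap,
#' the UUCG terminal tetraloop, the internal 180-degree kissing loop
#' (HIV-1 DIS) and its branched variant whose bulged adenines are replaced
#' by a toehold hairpin for strand-displacement switching.
#'
#' @return named list of motif definitions (class `motif_library`). Each
#'   motif carries its conserved fragment(s) 5'->3', an internal
#'   dot-bracket snippet per fragment, a footprint in bp on the host
#'   helix, and -- for kissing loops -- the tier-2 loop-loop pair list.
#' @export
motif_library <- function() {
  lib <- list(
    TETRALOOP_UUCG = cap_motif("TETRALOOP_UUCG", "UUCG", "....",
                               "UUCG terminal tetraloop"),
    SPINACH = aptamer_cap("SPINACH",
                          core5 = "GUGAAGGACGGGUCC",
                          stem = "GCUGUC",
                          core3 = "GUUGAGUAGAGUGUGAGC",
                          "Spinach minimal core (DFHBI-1T donor) capped by a terminal stem-loop"),
    BROCCOLI = aptamer_cap("BROCCOLI",
                           core5 = "GAGACGGUCGGGUCC",
                           stem = "AGAUAU",
                           core3 = "UCGAGUAGAGUGUGGGCU",
                           "Broccoli core (in vivo optimized DFHBI-1T donor) capped by a terminal stem-loop"),
    MANGO = cap_motif("MANGO",
                      seq = "GAAGGGACGGUGCGGAGAGGAGA",
                      db = strrep(".", 23),
                      "Mango G-quadruplex core (YO3-biotin acceptor); connects through a GAAA-like linker, cannot be flipped"),
    SAM_RIBOSWITCH = aptamer_cap("SAM_RIBOSWITCH",
                                 core5 = "GGCUUAUCAAGAGAGG",
                                 stem = "GGACGG",
                                 core3 = "UGGAGGGACUGGCCC",
                                 "SAM-I riboswitch aptamer domain (conformational SAM sensor)"),
    KL180 = list(
      id = "KL180", kind = "kl", footprint_bp = 2L,
      segments = list(
        loop_a = list(seq = "AAGCGCGCA", db = "........."),
        loop_b = list(seq = "AAGCGCGCA", db = ".........")),
      ## antiparallel loop-loop pairs between the GCGCGC cores (tier 2)
      kl_pairs = cbind(a = 3:8, b = 8:3),
      description = "internal 180-degree kissing loop (HIV-1 DIS); bulged adenines at loop positions 1-2"),
    KL_BRANCHED = NULL)

  ## branched KL: the two bulged adenines of one partner are exchanged for
  ## a stem-loop whose loop is the strand-displacement toehold
  hp <- list(seq = paste0("GCAGG", "UUCAGUC", rna_revcomp("GCAGG")),
             db = paste0("(((((", ".......", ")))))"))
  lib$KL_BRANCHED <- list(
    id = "KL_BRANCHED", kind = "kl", footprint_bp = 2L,
    segments = list(
      loop_a = list(seq = "AAGCGCGCA", db = "........."),
      loop_b = list(seq = paste0(hp$seq, "GCGCGC", "A"),
                    db = paste0(hp$db, "......", "."))),
    kl_pairs = cbind(a = 3:8, b = (nchar(hp$seq) + 6):(nchar(hp$seq) + 1)),
    description = "branched kissing loop: bulged adenines replaced by a toehold hairpin")

  ## validate fragment/pair consistency once, at construction
  for (m in lib) {
    for (s in m$segments) stopifnot(nchar(s$seq) == nchar(s$db))
    if (!is.null(m$kl_pairs)) {
      na <- nchar(m$segments$loop_a$seq); nb <- nchar(m$segments$loop_b$seq)
      stopifnot(all(m$kl_pairs[, 1] >= 1 & m$kl_pairs[, 1] <= na),
                all(m$kl_pairs[, 2] >= 1 & m$kl_pairs[, 2] <= nb))
    }
  }
  structure(lib, class = "motif_library")
}

## traverse a cap fragment from its other end: realizes "flipped"
## attachment (the motif joined to the host helix via its other flanking
## domain) at 2D-blueprint level
flip_fragment <- function(frag) {
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  db <- chartr("()", ")(", rev1(frag$db))
  list(seq = rev1(frag$seq), db = db)
}

motif_footprint <- function(motif, pos) pos + seq_len(motif$footprint_bp) - 1L
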