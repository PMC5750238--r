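## Single-strand tracing of a 2H-AE blueprint.
##
## Connectivity model (the package's realization of the antiparallel-even
## crossover rule): on both helices the top strand runs 5'->3' left to
## right and the bottom strand right to left. At a crossover at column x
## the helix-1 bottom strand and the helix-2 top strand exchange between
## columns x and x+1 with a reversal of travel direction (the U-turn of an
## antiparallel crossover):
##     (1, x+1, bottom) -> (2, x+1, top)   and   (2, x, top) -> (1, x, bottom).
## Cap motifs join top and bottom strands at a helix end; a kissing loop
## cuts its helix between columns pos and pos+1 and closes each arm with a
## hairpin loop. With the internal KL between the two crossovers this
## yields a single closed walk over every residue; without any motif in
## the inter-crossover region the walk splits in two and tracing fails.

node_key <- function(h, c, s) sprintf("%d:%d:%s", h, c, s)

strand_dir <- function(side) if (side == "top") 1L else -1L

#' Trace the single-strand path of a blueprint
#'
#' Walks the blueprint 5'->3' from its declared 5' end: along each strand
#' until a crossover column (helix switch under the antiparallel-even
#' rule), through terminal cap motifs at helix ends, and through kissing
#' loop hairpins at internal cuts, inlining motif residues where they are
#' anchored. Every residue of the blueprint must be visited exactly once.
#'
#' @param bp a [parse_blueprint()] result with a declared 5' end.
#' @param lib motif library.
#' @return a `strand_trace`: a data.frame with one row per residue
#'   (columns `idx`, `source` ("duplex"/"motif"), `helix`, `column`,
#'   `side`, `motif_id`, `motif_instance`, `segment`, `seg_pos`, `base`)
#'   plus attributes `blueprint` and `n`.
#' @export
trace_strand <- function(bp, lib = motif_library()) {
  validate_blueprint(bp, lib)
  assert_that(!is.null(bp$five_prime), "blueprint has no END5 record",
              "aptafret_invalid")
  len <- function(h) bp$helices$length_bp[bp$helices$id == h]

  ## --- default within-strand successors -------------------------------
  succ <- new.env(parent = emptyenv())
  payload <- new.env(parent = emptyenv())  # motif fragment on the edge OUT of a node
  set_succ <- function(from, to, frag = NULL) {
    assign(from, to, envir = succ)
    if (!is.null(frag)) assign(from, frag, envir = payload)
    else if (exists(from, envir = payload)) rm(list = from, envir = payload)
  }
  for (h in c(1L, 2L)) for (s in c("top", "bottom")) {
    d <- strand_dir(s)
    cols <- seq_len(len(h))
    for (cc in cols) if (cc + d >= 1 && cc + d <= len(h))
      set_succ(node_key(h, cc, s), node_key(h, cc + d, s))
  }

  ## --- crossovers: antiparallel exchange between x and x+1 ------------
  for (k in seq_len(nrow(bp$crossovers))) {
    x <- bp$crossovers$pos_a[k]
    set_succ(node_key(1L, x + 1L, "bottom"), node_key(2L, x + 1L, "top"))
    set_succ(node_key(2L, x, "top"), node_key(1L, x, "bottom"))
  }

  ## --- motifs ----------------------------------------------------------
  frag_of <- function(motif, segment, flipped) {
    fr <- motif$segments[[segment]]
    fr <- if (flipped) flip_fragment(fr) else fr
    fr$motif_id <- motif$id
    fr$segment <- segment
    fr
  }
  motif_cols_5p <- integer(0)  # footprint columns, for END5 validation
  for (k in seq_len(nrow(bp$motifs))) {
    m <- bp$motifs[k, ]
    motif <- lib[[m$motif_id]]
    flipped <- m$orientation == "flipped"
    if (motif$kind == "cap") {
      fr <- frag_of(motif, "cap", flipped)
      fr$instance <- k
      if (m$pos == 1L) {
        set_succ(node_key(m$helix, 1L, "bottom"), node_key(m$helix, 1L, "top"), fr)
      } else {
        set_succ(node_key(m$helix, m$pos, "top"),
                 node_key(m$helix, m$pos, "bottom"), fr)
      }
    } else {  # kissing loop: cut between pos and pos+1
      segs <- if (flipped) c("loop_b", "loop_a") else c("loop_a", "loop_b")
      fa <- frag_of(motif, segs[1], FALSE); fa$instance <- k
      fb <- frag_of(motif, segs[2], FALSE); fb$instance <- k
      set_succ(node_key(m$helix, m$pos, "top"),
               node_key(m$helix, m$pos, "bottom"), fa)
      set_succ(node_key(m$helix, m$pos + 1L, "bottom"),
               node_key(m$helix, m$pos + 1L, "top"), fb)
    }
    if (m$helix == bp$five_prime$helix)
      motif_cols_5p <- c(motif_cols_5p, motif_footprint(motif, m$pos))
  }

  if (bp$five_prime$pos %in% motif_cols_5p)
    abort2("5' end lies inside a motif footprint; the walk cannot start there",
           "aptafret_disconnected")

  ## --- walk ------------------------------------------------------------
  n_duplex <- 2L * sum(bp$helices$length_bp)
  start <- node_key(bp$five_prime$helix, bp$five_prime$pos, bp$five_prime$strand)
  rows <- vector("list", n_duplex * 2L)
  nrow_used <- 0L
  visited <- new.env(parent = emptyenv())
  emit <- function(row) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- row
  }
  node <- start
  repeat {
    if (exists(node, envir = visited))
      abort2(sprintf("walk revisits residue %s: not a simple strand", node),
             "aptafret_cycle")
    assign(node, TRUE, envir = visited)
    parts <- strsplit(node, ":", fixed = TRUE)[[1]]
    emit(list(source = "duplex", helix = as.integer(parts[1]),
              column = as.integer(parts[2]), side = parts[3],
              motif_id = NA_character_, motif_instance = NA_integer_,
              segment = NA_character_, seg_pos = NA_integer_,
              base = NA_character_))
    if (!exists(node, envir = succ))
      abort2(sprintf("strand walk dead-ends at %s (uncapped helix end?)", node),
             "aptafret_disconnected")
    if (exists(node, envir = payload)) {
      fr <- get(node, envir = payload)
      bases <- strsplit(fr$seq, "")[[1]]
      for (i in seq_along(bases))
        emit(list(source = "motif", helix = NA_integer_, column = NA_integer_,
                  side = NA_character_, motif_id = fr$motif_id,
                  motif_instance = fr$instance, segment = fr$segment,
                  seg_pos = i, base = bases[i]))
    }
    node <- get(node, envir = succ)
    if (node == start) break
  }

  n_visited <- length(ls(envir = visited))
  if (n_visited < n_duplex)
    abort2(sprintf(
      "strand walk closed after %d of %d duplex residues: blueprint is not single-stranded (is the inter-crossover region bridged by a kissing loop?)",
      n_visited, n_duplex), "aptafret_disconnected")

  tr <- do.call(rbind, lapply(rows[seq_len(nrow_used)], as.data.frame))
  tr$idx <- seq_len(nrow(tr))
  tr <- tr[, c("idx", "source", "helix", "column", "side", "motif_id",
               "motif_instance", "segment", "seg_pos", "base")]
  structure(tr, class = c("strand_trace", "data.frame"),
            blueprint = bp, n = nrow(tr))
}

#' @export
print.strand_trace <- function(x, ...) {
  cat(sprintf("<strand_trace> %d residues (%d duplex, %d motif) for blueprint '%s'\n",
              nrow(x), sum(x$source == "duplex"), sum(x$source == "motif"),
              attr(x, "blueprint")$name))
  invisible(x)
}
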