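## 2H-AE blueprint records.
##
## Blueprint dialect (*.bp, UTF-8, '#' comments, blank lines ignored):
##   NAME  <string>
##   HELIX <id> <length_bp>
##   XOVER <helix_a> <pos_a> <helix_b> <pos_b>
##   MOTIF <motif_id> <helix> <pos> <normal|flipped>
##   END5  <helix> <pos> <top|bottom>
##
## Scope is the two-helix antiparallel-even (2H-AE) family: exactly two
## helices (ids 1 and 2) and exactly two crossovers. Columns are 1-based
## bp positions measured from the helix's left end; a crossover at column
## x exchanges strands between columns x and x+1 (so the locked pair sits
## at x+1). Cap motifs anchor at column 1 or at the helix length; kissing
## loops cut the helix between pos and pos+1 (footprint pos, pos+1).

#' Parse a 2H-AE blueprint file
#'
#' Reads the line-oriented blueprint record format into a validated
#' `blueprint` object. Validation enforces the 2H-AE family (exactly two
#' helices, two crossovers), position bounds, and non-overlapping motif
#' footprints that avoid crossover columns.
#'
#' @param text blueprint file content as a single string or a character
#'   vector of lines.
#' @param lib motif library, for footprint sizes (default
#'   [motif_library()]).
#' @return an object of class `blueprint`.
#' @seealso [read_blueprint()], [trace_strand()]
#' @export
parse_blueprint <- function(text, lib = motif_library()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  name <- NULL
  helices <- data.frame(id = integer(0), length_bp = integer(0))
  xovers <- data.frame(helix_a = integer(0), pos_a = integer(0),
                       helix_b = integer(0), pos_b = integer(0))
  motifs <- data.frame(motif_id = character(0), helix = integer(0),
                       pos = integer(0), orientation = character(0))
  five_prime <- NULL

  perr <- function(i, msg)
    abort2(sprintf("blueprint line %d: %s ['%s']", i, msg, trimws(lines_raw[i])),
           "aptafret_parse")
  num <- function(i, tok, what) {
    v <- suppressWarnings(as.integer(tok))
    if (is.na(v)) perr(i, sprintf("%s must be an integer", what))
    v
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    rec <- toupper(tok[1])
    if (rec == "NAME") {
      if (length(tok) < 2) perr(i, "NAME requires a value")
      name <- paste(tok[-1], collapse = " ")
    } else if (rec == "HELIX") {
      if (length(tok) != 3) perr(i, "HELIX requires <id> <length_bp>")
      helices <- rbind(helices, data.frame(id = num(i, tok[2], "helix id"),
                                           length_bp = num(i, tok[3], "length")))
    } else if (rec == "XOVER") {
      if (length(tok) != 5) perr(i, "XOVER requires <hA> <posA> <hB> <posB>")
      xovers <- rbind(xovers, data.frame(
        helix_a = num(i, tok[2], "helix"), pos_a = num(i, tok[3], "pos"),
        helix_b = num(i, tok[4], "helix"), pos_b = num(i, tok[5], "pos")))
    } else if (rec == "MOTIF") {
      if (length(tok) < 4 || length(tok) > 5)
        perr(i, "MOTIF requires <motif_id> <helix> <pos> [normal|flipped]")
      ori <- if (length(tok) == 5) tolower(tok[5]) else "normal"
      if (!ori %in% c("normal", "flipped"))
        perr(i, "orientation must be 'normal' or 'flipped'")
      motifs <- rbind(motifs, data.frame(
        motif_id = toupper(tok[2]), helix = num(i, tok[3], "helix"),
        pos = num(i, tok[4], "pos"), orientation = ori))
    } else if (rec == "END5") {
      if (length(tok) != 4) perr(i, "END5 requires <helix> <pos> <top|bottom>")
      strand <- tolower(tok[4])
      if (!strand %in% c("top", "bottom"))
        perr(i, "strand must be 'top' or 'bottom'")
      five_prime <- list(helix = num(i, tok[2], "helix"),
                         pos = num(i, tok[3], "pos"), strand = strand)
    } else perr(i, sprintf("unknown record '%s'", tok[1]))
  }

  bp <- structure(list(name = name %||% "unnamed", helices = helices,
                       crossovers = xovers, motifs = motifs,
                       five_prime = five_prime),
                  class = "blueprint")
  validate_blueprint(bp, lib)
}

validate_blueprint <- function(bp, lib = motif_library()) {
  if (nrow(bp$helices) != 2L)
    abort2(sprintf("2H-AE blueprints require exactly 2 helices (got %d)",
                   nrow(bp$helices)), "aptafret_topology")
  if (!setequal(bp$helices$id, c(1L, 2L)))
    abort2("helix ids must be 1 and 2", "aptafret_topology")
  if (any(bp$helices$length_bp < 1))
    abort2("helix lengths must be >= 1 bp", "aptafret_invalid")
  if (nrow(bp$crossovers) != 2L)
    abort2(sprintf("2H-AE blueprints require exactly 2 crossovers (got %d)",
                   nrow(bp$crossovers)), "aptafret_topology")

  len <- function(h) bp$helices$length_bp[bp$helices$id == h]
  for (k in seq_len(nrow(bp$crossovers))) {
    x <- bp$crossovers[k, ]
    assert_that(setequal(c(x$helix_a, x$helix_b), c(1L, 2L)),
                "each crossover must join helices 1 and 2", "aptafret_topology")
    assert_that(x$pos_a == x$pos_b,
                "2H-AE crossover columns must be aligned (pos_a == pos_b)",
                "aptafret_topology")
    assert_that(x$pos_a >= 1 && x$pos_a + 1L <= min(len(1L), len(2L)),
                sprintf("crossover column %d out of range", x$pos_a),
                "aptafret_invalid")
  }
  xcols <- sort(bp$crossovers$pos_a)
  assert_that(xcols[1] != xcols[2], "crossover columns must be distinct",
              "aptafret_topology")

  ## motif placement and footprints
  occ <- list()  # per helix: occupied columns
  for (k in seq_len(nrow(bp$motifs))) {
    m <- bp$motifs[k, ]
    motif <- lib[[m$motif_id]]
    if (is.null(motif))
      abort2(sprintf("unknown motif '%s'", m$motif_id), "aptafret_invalid")
    L <- len(m$helix)
    assert_that(length(L) == 1, sprintf("motif on unknown helix %d", m$helix),
                "aptafret_invalid")
    fp <- motif_footprint(motif, m$pos)
    assert_that(all(fp >= 1 & fp <= L),
                sprintf("motif %s footprint outside helix %d (columns %s)",
                        m$motif_id, m$helix, paste(fp, collapse = ",")),
                "aptafret_invalid")
    if (motif$kind == "cap" && !(m$pos %in% c(1L, L)))
      abort2(sprintf("cap motif %s must anchor at column 1 or %d (got %d)",
                     m$motif_id, L, m$pos), "aptafret_layout")
    if (motif$kind == "kl" && (m$pos < 2L || m$pos + 1L > L - 1L))
      abort2(sprintf("kissing loop must cut strictly inside the helix (pos %d)",
                     m$pos), "aptafret_layout")
    if (any(fp %in% xcols))
      abort2(sprintf("motif %s overlaps a crossover column", m$motif_id),
             "aptafret_layout")
    key <- as.character(m$helix)
    if (any(fp %in% occ[[key]]))
      abort2(sprintf("motif %s overlaps another motif on helix %d",
                     m$motif_id, m$helix), "aptafret_layout")
    occ[[key]] <- c(occ[[key]], fp)
  }

  if (!is.null(bp$five_prime)) {
    fp5 <- bp$five_prime
    assert_that(fp5$helix %in% c(1L, 2L) && fp5$pos >= 1 &&
                  fp5$pos <= len(fp5$helix),
                "END5 outside helix bounds", "aptafret_invalid")
  }
  bp
}

#' @rdname parse_blueprint
#' @param path path to a `.bp` blueprint file.
#' @export
read_blueprint <- function(path, lib = motif_library()) {
  parse_blueprint(readLines(path, warn = FALSE), lib)
}

#' Path to the packaged flagship S*5-M5 blueprint
#'
#' The high-FRET flagship construct: flipped Spinach and Mango each 5 bp
#' from the reference crossover on sister helices, the internal kissing
#' loop between the crossovers, UUCG tetraloops at the far helix ends.
#'
#' @return file path within the installed package.
#' @export
flagship_blueprint_path <- function() {
  system.file("extdata", "S_star5-M5.bp", package = "aptafret", mustWork = TRUE)
}

#' @export
print.blueprint <- function(x, ...) {
  cat(sprintf("<blueprint> %s: helices %s bp; crossovers at columns %s; %d motif(s)\n",
              x$name, paste(x$helices$length_bp, collapse = "/"),
              paste(sort(x$crossovers$pos_a), collapse = ", "), nrow(x$motifs)))
  invisible(x)
}
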