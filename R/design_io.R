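## Design-file output: 3-line plain format (name / dot-bracket /
## constraint string) and a NUPACK-script flavored dialect. Output is
## byte-stable across runs.

#' Write a design file for external sequence design
#'
#' The plain dialect is three lines: `> name`, the dot-bracket string,
#' and the constraint string (`W` marks GU-designated pair positions).
#' The `nupack` dialect lowers `W` to `N` (no IUPAC code covers a GU
#' pair) and appends the designated pairs as comment records, with the
#' structure and constraints in a NUPACK-style script body.
#'
#' @param name construct name (nonempty).
#' @param ss [build_structure()] result.
#' @param cs [emit_constraints()] result.
#' @param path optional output path; when `NULL` the text is returned only.
#' @param dialect `"plain"` (default) or `"nupack"`.
#' @return design file text, invisibly when written to `path`.
#' @export
write_design <- function(name, ss, cs, path = NULL,
                         dialect = c("plain", "nupack")) {
  dialect <- match.arg(dialect)
  assert_that(is.character(name) && length(name) == 1L && nzchar(trimws(name)),
              "design name must be a nonempty string")
  stopifnot(inherits(ss, "secondary_structure"), inherits(cs, "constraint_string"))
  assert_that(ss$n == cs$n, "structure and constraint lengths differ")

  if (dialect == "plain") {
    text <- paste0("> ", name, "\n", ss$dot_bracket, "\n", cs$string, "\n")
  } else {
    lowered <- gsub("W", "N", cs$string, fixed = TRUE)
    gu <- cs$gu_pairs
    gu_lines <- if (nrow(gu) > 0)
      paste0("# wobble pair ", gu$idx_5p, " ", gu$idx_3p, collapse = "\n")
    else "# no wobble pairs"
    text <- paste0("# design: ", name, "\n",
                   "structure ", name, " = ", ss$dot_bracket, "\n",
                   "domain seq = ", lowered, "\n",
                   name, ".seq = seq\n",
                   gu_lines, "\n")
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # byte-stable: no platform EOL translation
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}

#' Read a plain-dialect design file
#'
#' @param path or text of a plain 3-line design file.
#' @return list with `name`, `dot_bracket`, `constraints`.
#' @export
read_design <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else strsplit(paste(path, collapse = "\n"),
                                                "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) >= 3L && startsWith(lines[1], ">"),
              "not a plain design file (expected '> name' header)",
              "aptafret_parse")
  name <- trimws(sub("^>", "", lines[1]))
  db <- lines[2]; cs <- lines[3]
  assert_that(nchar(db) == nchar(cs),
              "structure and constraint line lengths differ", "aptafret_parse")
  list(name = name, dot_bracket = db, constraints = cs)
}

#' Compile a blueprint end to end
#'
#' Convenience pipeline: parse (if given text or a path), trace, build the
#' structure, emit constraints, and render the design text.
#'
#' @param x a blueprint object, blueprint text, or path to a `.bp` file.
#' @param lib motif library.
#' @param kissing include kissing-loop tier-2 pairs (the no-KL control
#'   constructs use `FALSE`).
#' @param name design name; defaults to the blueprint's.
#' @param spec optional [construct_spec()] metadata.
#' @param dialect design output dialect, see [write_design()].
#' @return list with `blueprint`, `trace`, `structure`, `constraints`,
#'   `design_text`.
#' @export
compile_blueprint <- function(x, lib = motif_library(), kissing = TRUE,
                              name = NULL, spec = NULL,
                              dialect = c("plain", "nupack")) {
  bp <- if (inherits(x, "blueprint")) x
        else if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
          read_blueprint(x, lib)
        else parse_blueprint(x, lib)
  tr <- trace_strand(bp, lib)
  ss <- build_structure(tr, lib, kissing = kissing)
  cs <- emit_constraints(tr, ss, lib, spec = spec)
  nm <- name %||% bp$name
  list(blueprint = bp, trace = tr, structure = ss, constraints = cs,
       design_text = write_design(nm, ss, cs, dialect = match.arg(dialect)))
}
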