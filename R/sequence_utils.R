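## Small RNA sequence utilities: reverse complement, invader/anti-invader
## complementarity checks, FASTA IO. Sequence arithmetic is delegated to
## Biostrings; these wrappers add the RNA-alphabet validation and the
## match-report structure used by the strand-displacement workflow.

RNA_ALPHABET <- c("A", "C", "G", "U")

clean_rna <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  chars <- strsplit(x, "")[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0)
    abort2(sprintf("non-RNA character(s) in sequence: %s",
                   paste(bad, collapse = ", ")), "aptafret_alphabet")
  x
}

#' Reverse complement of an RNA sequence
#'
#' @param x single RNA sequence (character; whitespace is ignored).
#' @return the reverse complement, 5'->3', as a character string.
#' @examples
#' rna_revcomp("GGAAUC")
#' @export
rna_revcomp <- function(x) {
  x <- clean_rna(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' Check an invader / anti-invader pair for exact reverse complementarity
#'
#' Toehold-mediated strand displacement is reversed by an "anti-invader"
#' that must be the exact reverse complement of the invader strand; this
#' verifies that design requirement and reports per-position mismatches.
#'
#' @param invader,anti RNA sequences (character; whitespace ignored).
#' @return a list of class `invader_report` with elements `length`,
#'   `mismatch_count`, `mismatch_positions` (positions along `anti`),
#'   and `is_exact_reverse_complement`.
#' @examples
#' invader_check("GGAAUC", "GAUUCC")
#' @export
invader_check <- function(invader, anti) {
  invader <- clean_rna(invader)
  anti <- clean_rna(anti)
  expected <- rna_revcomp(invader)
  if (nchar(anti) != nchar(expected))
    abort2(sprintf("length mismatch: invader %d nt vs anti-invader %d nt",
                   nchar(expected), nchar(anti)), "aptafret_invalid")
  a <- strsplit(anti, "")[[1]]
  e <- strsplit(expected, "")[[1]]
  mism <- which(a != e)
  structure(list(length = nchar(anti),
                 mismatch_count = length(mism),
                 mismatch_positions = mism,
                 is_exact_reverse_complement = length(mism) == 0L),
            class = "invader_report")
}

#' @export
print.invader_report <- function(x, ...) {
  cat(sprintf("invader check: %d nt, %d mismatch(es), exact reverse complement: %s\n",
              x$length, x$mismatch_count, x$is_exact_reverse_complement))
  invisible(x)
}

#' Invader and anti-invader strands of the conformational switch
#'
#' The two toehold-extended invader RNAs that open the branched kissing
#' loop of the apta-FRET conformational switch, and the anti-invaders that
#' remove them and restore the FRET signal.
#'
#' @return named character vector of four RNA sequences.
#' @export
invader_sequences <- function() {
  c(invader_1      = "UAGCUUAUCAGACUGAUGUUGAUAUAAAAG",
    anti_invader_1 = "CUUUUAUAUCAACAUCAGUCUGAUAAGCUA",
    invader_2      = "CUAGACUGAAGCUCCUUGAGGGAAGUUAG",
    anti_invader_2 = "CUAACUUCCCUCAAGGAGCUUCAGUCUAG")
}

#' Read / write RNA FASTA
#'
#' @param path file path.
#' @return `read_rna_fasta`: named character vector of sequences.
#' @export
read_rna_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_rna_fasta
#' @param seqs named character vector of RNA sequences.
#' @export
write_rna_fasta <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(vapply(unname(seqs), clean_rna, character(1)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
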