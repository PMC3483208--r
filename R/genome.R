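#' Genome container
#'
#' A genome is an ordered, named character vector of uppercase nucleotide
#' sequences (A/C/G/T/N), one element per chromosome.  All coordinates used
#' throughout the package are 0-based half-open; conversion to and from
#' 1-based conventions happens only at SAM boundaries.
#'
#' @param seqs named character vector of sequences.
#' @return an object of class `sv_genome`.
#' @export
sv_genome <- function(seqs) {
  if (length(seqs) == 0) {
    g <- character(0)
    class(g) <- "sv_genome"
    return(g)
  }
  nm <- names(seqs)
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    stopf("every chromosome must have a non-empty name")
  if (anyDuplicated(nm))
    stopf("duplicated chromosome name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  empty <- nchar(seqs) == 0
  if (any(empty))
    stopf("empty sequence for record(s): %s", paste(nm[empty], collapse = ", "))
  g <- toupper(as.character(seqs))
  names(g) <- nm
  class(g) <- "sv_genome"
  g
}

#' @export
print.sv_genome <- function(x, ...) {
  cat(sprintf("<sv_genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in head(names(x), 10))
    cat(sprintf("  %-8s %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  if (length(x) > 10) cat(sprintf("  ... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome an `sv_genome`.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased; record order is preserved; names are truncated
#' at the first whitespace (standard FASTA identifier semantics).
#'
#' @param path path to a FASTA file.
#' @return an `sv_genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  nm <- sub("\\s.*$", "", names(x))
  empty <- Biostrings::width(x) == 0
  if (any(empty))
    stopf("empty sequence for FASTA record(s): %s", paste(nm[empty], collapse = ", "))
  sv_genome(setNames(as.character(x), nm))
}

#' Write a genome to a FASTA file
#' @param genome an `sv_genome`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Random nucleotide genome
#'
#' I.i.d. uniform A/C/G/T sequence.  Random sequence of a few megabases is
#' unique at k = 50 with overwhelming probability (expected number of
#' repeated 50-mers is about L^2 / 4^50), which the uniqueness-score module
#' verifies rather than assumes.
#'
#' @param lengths named integer vector of chromosome lengths.
#' @param seed optional integer seed.
#' @return an `sv_genome`.
#' @export
random_genome <- function(lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  sv_genome(seqs)
}

#' Reverse complement of DNA strings
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
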