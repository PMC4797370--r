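#' Create a locus (allele template) object
#'
#' A locus is a named DNA sequence carrying an allele label, e.g. the Habataki
#' or the non-target copy of a gene region being screened for marker design.
#' Coordinates on loci are 0-based half-open internally; all human-readable
#' reports convert to 1-based inclusive.
#'
#' @param id Unique identifier.
#' @param sequence DNA string over A/C/G/T/N (case-insensitive; stored
#'   uppercase).
#' @param allele_label Allele carried by this sequence (e.g. "Habataki",
#'   "non-target"). Defaults to `id`.
#' @return An object of class `asm_locus`.
#' @export
#' @examples
#' locus("gn1a_P", "ACGTACGT", allele_label = "positive")
locus <- function(id, sequence, allele_label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_dna(sequence, sprintf("locus '%s' sequence", id))
  structure(
    list(id = id, allele_label = allele_label, sequence = toupper(sequence)),
    class = "asm_locus"
  )
}

#' @export
print.asm_locus <- function(x, ...) {
  cat(sprintf("<asm_locus> %s [%s], %d bp\n", x$id, x$allele_label,
              nchar(x$sequence)))
  invisible(x)
}

#' @export
length.asm_locus <- function(x) nchar(x$sequence)

as_locus <- function(x, id = "locus", allele_label = id) {
  if (inherits(x, "asm_locus")) return(x)
  locus(id, x, allele_label)
}

#' Read loci from a FASTA file
#'
#' @param path FASTA file. Header is `id` or `id allele_label`.
#' @return List of [locus()] objects, named by id.
#' @export
read_loci_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    parts <- strsplit(nm, "[ \t]+")[[1]]
    locus(parts[1], as.character(set[[i]]),
          allele_label = if (length(parts) > 1) parts[2] else parts[1])
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(names(out))) {
    stop("duplicate locus ids in ", path, call. = FALSE)
  }
  out
}

#' Write loci to a FASTA file
#'
#' @param loci A list of [locus()] objects (or a single one).
#' @param path Output file.
#' @export
write_loci_fasta <- function(loci, path) {
  if (inherits(loci, "asm_locus")) loci <- list(loci)
  seqs <- Biostrings::DNAStringSet(vapply(loci, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(loci, function(l) {
    if (identical(l$id, l$allele_label)) l$id else paste(l$id, l$allele_label)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
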