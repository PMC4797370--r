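#' Create a primer object
#'
#' Primers are written 5' to 3'. Following the Table-2 dialect used throughout
#' the package, a single lowercase letter near the 3' end marks an engineered
#' (artificial) mismatch against the template, used to sharpen allele
#' specificity of ARMS primers. `sequence` is the oligo as synthesized; the
#' lowercase annotation is retained in `display_sequence`.
#'
#' @param name Primer name.
#' @param sequence 5'->3' sequence; at most one lowercase letter, which is
#'   recorded as the artificial mismatch.
#' @param strand "forward" or "reverse" with respect to the reference locus.
#' @param role One of "common_outer", "positive_allele", "non_target_allele",
#'   "inner_indel".
#' @return An object of class `asm_primer` with fields `sequence` (uppercase),
#'   `display_sequence`, `mismatch` (NULL or list with `offset_from_3prime`,
#'   `base`), and `tm`.
#' @export
primer <- function(name, sequence, strand = c("forward", "reverse"),
                   role = c("common_outer", "positive_allele",
                            "non_target_allele", "inner_indel")) {
  strand <- match.arg(strand)
  role <- match.arg(role)
  check_dna(sequence, sprintf("primer '%s'", name), allow_n = FALSE)
  n <- nchar(sequence)
  if (n < 16 || n > 30) {
    warning(sprintf("primer '%s' length %d outside the usual 16-30 nt", name, n))
  }
  lower <- which(seq_chars(sequence) %in% c("a", "c", "g", "t"))
  mism <- NULL
  if (length(lower) > 1) {
    stop(sprintf("primer '%s': more than one lowercase (mismatch) letter", name),
         call. = FALSE)
  }
  if (length(lower) == 1) {
    mism <- list(offset_from_3prime = n - lower + 1L,
                 base = toupper(substr(sequence, lower, lower)))
  }
  structure(
    list(name = name, sequence = toupper(sequence),
         display_sequence = sequence, strand = strand, role = role,
         mismatch = mism, tm = compute_tm(toupper(sequence))),
    class = "asm_primer"
  )
}

#' @export
print.asm_primer <- function(x, ...) {
  cat(sprintf("<asm_primer> %s (%s, %s) %s  Tm=%.1f\n", x$name, x$strand,
              x$role, x$display_sequence, x$tm))
  invisible(x)
}

#' Engineer an artificial mismatch near the 3' end of an allele-specific primer
#'
#' ARMS primers end on the allele base; an additional deliberate mismatch a few
#' bases in from the 3' end destabilizes extension on the wrong allele. The
#' substituted base is the complement of the original, which mispairs
#' purine-purine or pyrimidine-pyrimidine with the template strand the primer
#' anneals to (the strongest class of mispair).
#'
#' @param p An [primer()] that currently matches its allele template perfectly
#'   (no prior engineered mismatch).
#' @param allele_base The allele-discriminating base the primer must end on
#'   (as written in the primer, i.e. already complemented for reverse primers).
#' @param offset Position of the substitution counted from the 3' end
#'   (3' terminal base = 1). Offset 2 is the default.
#' @return The modified primer; the substitution is recorded in
#'   `display_sequence` as a lowercase letter.
#' @export
insert_artificial_mismatch <- function(p, allele_base, offset = 2L) {
  stopifnot(inherits(p, "asm_primer"))
  if (nchar(p$sequence) < 5) stop("primer shorter than 5 nt", call. = FALSE)
  if (!is.null(p$mismatch)) {
    stop(sprintf("primer '%s' already carries an artificial mismatch", p$name),
         call. = FALSE)
  }
  if (!offset %in% 2:4) stop("mismatch offset must be 2-4", call. = FALSE)
  n <- nchar(p$sequence)
  if (substr(p$sequence, n, n) != toupper(allele_base)) {
    stop(sprintf("primer '%s' does not end on allele base %s", p$name,
                 allele_base), call. = FALSE)
  }
  i <- n - as.integer(offset) + 1L
  orig <- substr(p$sequence, i, i)
  sub <- toupper(seq_complement(orig))
  seq2 <- p$sequence
  substr(seq2, i, i) <- sub
  disp <- seq2
  substr(disp, i, i) <- tolower(sub)
  p$sequence <- seq2
  p$display_sequence <- disp
  p$mismatch <- list(offset_from_3prime = as.integer(offset), base = sub,
                     original_base = orig)
  p$tm <- compute_tm(seq2)
  p
}
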