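# Nearest-neighbor melting temperature (SantaLucia 1998 unified parameters).
# Duplex initiation uses terminal A/T and G/C corrections; monovalent-salt
# correction is applied to the entropy as 0.368 * (N-1) * ln[Na+].

.nn_dh <- c(
  "AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
  "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0,
  # complements share the stack value
  "TT" = -7.9, "TG" = -8.5, "AC" = -8.4, "AG" = -7.8, "TC" = -8.2,
  "CC" = -8.0
)
.nn_ds <- c(
  "AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7, "GT" = -22.4,
  "CT" = -21.0, "GA" = -22.2, "CG" = -27.2, "GC" = -24.4, "GG" = -19.9,
  "TT" = -22.2, "TG" = -22.7, "AC" = -22.4, "AG" = -21.0, "TC" = -22.2,
  "CC" = -19.9
)
.init_at <- c(dh = 2.3, ds = 4.1)
.init_gc <- c(dh = 0.1, ds = -2.8)

#' Nearest-neighbor primer melting temperature
#'
#' Computes the duplex melting temperature of a primer against its perfect
#' complement under fixed default conditions (50 mM monovalent cation, 250 nM
#' of each strand), matching the single annealing program used with all the
#' package's marker designs.
#'
#' @param p Primer sequence (character) or an [primer()] object. Lowercase
#'   letters (engineered-mismatch annotation) are treated as their uppercase
#'   base: the Tm is that of the synthesized oligo against its own complement.
#' @param Na Monovalent cation concentration, mM.
#' @param conc Concentration of each primer strand, nM.
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' compute_tm("GCGCGCGCGCGCGCGC") > compute_tm("ATATATATATATATAT")
compute_tm <- function(p, Na = 50, conc = 250) {
  if (inherits(p, "asm_primer")) p <- p$sequence
  check_dna(p, "primer", allow_n = FALSE)
  s <- toupper(p)
  n <- nchar(s)
  if (n < 2) stop("primer too short for nearest-neighbor Tm", call. = FALSE)
  ch <- seq_chars(s)
  stacks <- paste0(ch[-n], ch[-1])
  dh <- sum(.nn_dh[stacks])
  ds <- sum(.nn_ds[stacks])
  for (term in c(ch[1], ch[n])) {
    if (term %in% c("A", "T")) {
      dh <- dh + .init_at["dh"]; ds <- ds + .init_at["ds"]
    } else {
      dh <- dh + .init_gc["dh"]; ds <- ds + .init_gc["ds"]
    }
  }
  ds <- ds + 0.368 * (n - 1) * log(Na / 1000)
  k <- (conc - conc / 2) * 1e-9  # effective duplex concentration, non-self-complementary
  unname(dh * 1000 / (ds + 1.987 * log(k)) - 273.15)
}
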