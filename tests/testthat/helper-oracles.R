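# Independent oracles used by the property tests. These deliberately avoid
# the package's vectorized implementations: the binding-site oracle is a
# naive character-by-character sliding window applying the same annealing
# rules.

oracle_sites <- function(primer_seq, template_seq, window = 4L,
                         max_mm_window = 1L, max_mm_total = 3L) {
  primer_seq <- toupper(primer_seq)
  template_seq <- toupper(template_seq)
  m <- nchar(primer_seq)
  n <- nchar(template_seq)
  hits <- list()
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer_seq else rc(primer_seq)
    for (s in seq_len(max(0L, n - m + 1L))) {
      mm_total <- 0L; mm_window <- 0L; term_ok <- TRUE
      for (j in seq_len(m)) {
        tb <- substr(template_seq, s + j - 1L, s + j - 1L)
        pb <- substr(pat, j, j)
        if (tb != pb) {
          off <- if (strand == "+") m - j + 1L else j
          mm_total <- mm_total + 1L
          if (off <= window) mm_window <- mm_window + 1L
          if (off == 1L) term_ok <- FALSE
        }
      }
      if (term_ok && mm_window <= max_mm_window && mm_total <= max_mm_total) {
        hits[[length(hits) + 1L]] <- c(strand = strand, start = s)
      }
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, function(h) paste(h["strand"], h["start"]), character(1)))
}

site_keys <- function(sites_df) {
  if (!nrow(sites_df)) return(character(0))
  sort(paste(sites_df$strand, sites_df$start))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

expect_design_or_failure <- function(expr) {
  tryCatch(expr, asm_design_failure = function(e) NULL)
}
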