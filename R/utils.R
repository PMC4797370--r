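# Internal string/sequence helpers. Loci are stored as plain uppercase
# character strings; primers keep a display form where lowercase marks the
# engineered mismatch, so case must survive complementation.

seq_complement <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

seq_reverse <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

seq_revcomp <- function(x) {
  seq_reverse(seq_complement(x))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTNacgtn]+$" else "^[ACGTacgt]+$"
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  }
  if (!grepl(pat, x)) {
    bad <- regmatches(x, regexpr(if (allow_n) "[^ACGTNacgtn]" else "[^ACGTacgt]", x))
    stop(sprintf("%s contains invalid character '%s'", what, bad), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
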