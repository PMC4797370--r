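#' ARMS extension-blocking mismatch model
#'
#' Annealing rules under which a primer can prime DNA synthesis. The defaults
#' admit the single engineered ARMS mismatch on the matching allele (one
#' mismatch inside the 3'-terminal window) while blocking priming from a
#' 3'-terminal mismatch on the wrong allele.
#'
#' @param terminal_match Must the 3'-terminal base pair with the template?
#' @param window Size of the 3'-proximal window (nt).
#' @param max_mm_window Maximum mismatches tolerated inside the window.
#' @param max_mm_total Maximum mismatches tolerated over the whole primer.
#' @return A list of class `asm_mismatch_model`.
#' @export
mismatch_model <- function(terminal_match = TRUE, window = 4L,
                           max_mm_window = 1L, max_mm_total = 3L) {
  structure(list(terminal_match = terminal_match, window = as.integer(window),
                 max_mm_window = as.integer(max_mm_window),
                 max_mm_total = as.integer(max_mm_total)),
            class = "asm_mismatch_model")
}

#' Find primer binding sites on a template
#'
#' Scans both strands of a template for positions where a primer may prime
#' under an [mismatch_model()]. Footprints are reported in 1-based inclusive
#' plus-strand coordinates; `strand` "+" means the primer extends rightward
#' (its 3' end at `end`), "-" leftward (3' end at `start`).
#'
#' @param p An [primer()] object or a 5'->3' sequence string.
#' @param t An [locus()] object or sequence string.
#' @param model An [mismatch_model()].
#' @return data.frame with columns primer, template, strand, start, end,
#'   n_mismatch, mm_offsets (comma-separated offsets from the 3' end),
#'   terminal_match. Zero rows when the primer cannot prime anywhere.
#' @export
find_binding_sites <- function(p, t, model = mismatch_model()) {
  if (is.character(p)) p <- primer("primer", p)
  t <- as_locus(t)
  m <- nchar(p$sequence)
  tc <- seq_chars(t$sequence)
  n <- length(tc)
  out <- list()
  if (n >= m) {
    for (orient in c("+", "-")) {
      pat <- if (orient == "+") p$sequence else seq_revcomp(p$sequence)
      pc <- seq_chars(toupper(pat))
      starts <- seq_len(n - m + 1L)
      idx <- outer(starts, seq_len(m) - 1L, `+`)
      neq <- matrix(tc[idx] != rep(pc, each = length(starts)),
                    nrow = length(starts))
      total <- rowSums(neq)
      win_cols <- if (orient == "+") seq(m - model$window + 1L, m) else
        seq_len(model$window)
      term_col <- if (orient == "+") m else 1L
      win <- rowSums(neq[, win_cols, drop = FALSE])
      term_ok <- !neq[, term_col]
      keep <- total <= model$max_mm_total & win <= model$max_mm_window &
        (!model$terminal_match | term_ok)
      if (any(keep)) {
        ks <- starts[keep]
        offs <- vapply(which(keep), function(i) {
          j <- which(neq[i, ])
          o <- if (orient == "+") m - j + 1L else j
          paste(sort(o), collapse = ",")
        }, character(1))
        out[[orient]] <- data.frame(
          primer = p$name, template = t$id, strand = orient,
          start = ks, end = ks + m - 1L,
          n_mismatch = as.integer(total[keep]),
          mm_offsets = offs, terminal_match = term_ok[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(primer = character(), template = character(),
                      strand = character(), start = integer(), end = integer(),
                      n_mismatch = integer(), mm_offsets = character(),
                      terminal_match = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR amplicons of a primer set on allele templates
#'
#' Every convergent pair of primer binding sites within `max_product` yields an
#' amplicon; product length counts both primer footprints inclusively. Within
#' each template (one reaction tube for a homozygote), a relative amplification
#' efficiency exp(-lambda * (L - L_min)) is assigned, a deliberately minimal
#' monotone model of the shorter-product advantage during cycling.
#'
#' @param primers List of [primer()] objects (or character vector of
#'   sequences).
#' @param templates List of [locus()] objects (or a single one).
#' @param max_product Longest product considered amplifiable, bp.
#' @param model An [mismatch_model()].
#' @param lambda Efficiency decay per bp of length excess.
#' @return data.frame with columns template, allele_label, forward, reverse,
#'   start, end, length, efficiency.
#' @export
amplify <- function(primers, templates, max_product = 2000,
                    model = mismatch_model(), lambda = 0.002) {
  if (inherits(primers, "asm_primer")) primers <- list(primers)
  if (is.character(primers)) {
    nms <- names(primers) %||% paste0("p", seq_along(primers))
    primers <- Map(function(s, nm) primer(nm, s), primers, nms)
  }
  if (inherits(templates, "asm_locus")) templates <- list(templates)
  res <- list()
  for (t in templates) {
    t <- as_locus(t)
    sites <- do.call(rbind, lapply(primers, find_binding_sites, t = t,
                                   model = model))
    fwd <- sites[sites$strand == "+", , drop = FALSE]
    rev <- sites[sites$strand == "-", , drop = FALSE]
    if (!nrow(fwd) || !nrow(rev)) next
    plen <- stats::setNames(vapply(primers, function(p) nchar(p$sequence),
                                   integer(1)),
                            vapply(primers, `[[`, character(1), "name"))
    for (i in seq_len(nrow(fwd))) {
      for (j in seq_len(nrow(rev))) {
        L <- rev$end[j] - fwd$start[i] + 1L
        if (L < plen[[fwd$primer[i]]] + plen[[rev$primer[j]]]) next
        if (L > max_product) next
        res[[length(res) + 1L]] <- data.frame(
          template = t$id, allele_label = t$allele_label,
          forward = fwd$primer[i], reverse = rev$primer[j],
          start = fwd$start[i], end = rev$end[j], length = L,
          efficiency = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(template = character(), allele_label = character(),
                      forward = character(), reverse = character(),
                      start = integer(), end = integer(), length = integer(),
                      efficiency = numeric(), stringsAsFactors = FALSE))
  }
  amp <- do.call(rbind, res)
  amp <- amp[order(amp$template, amp$length, amp$forward, amp$reverse), ,
             drop = FALSE]
  rownames(amp) <- NULL
  for (tid in unique(amp$template)) {
    sel <- amp$template == tid
    amp$efficiency[sel] <- exp(-lambda * (amp$length[sel] - min(amp$length[sel])))
  }
  amp
}

#' Combine amplicon sets of the two alleles of a heterozygote
#'
#' Both allele templates share one reaction tube, so efficiencies are
#' recomputed relative to the shortest product of the union. The heterozygote
#' is flagged imbalanced when the strongest diagnostic band of one allele is
#' more than `ratio_threshold` times weaker than that of the other, i.e. when
#' one allele risks being missed on the gel.
#'
#' @param a1,a2 Amplicon data.frames from [amplify()] on the two homozygous
#'   templates under the same primer set.
#' @param lambda Efficiency decay per bp (must match the [amplify()] call).
#' @param ratio_threshold Allele-intensity ratio above which the imbalance
#'   flag is raised.
#' @return List of class `asm_het`: `amplicons` (with recomputed
#'   efficiencies), `imbalance` (logical), `ratio`.
#' @export
simulate_heterozygote <- function(a1, a2, lambda = 0.002, ratio_threshold = 3) {
  amp <- rbind(a1, a2)
  if (nrow(amp)) {
    amp$efficiency <- exp(-lambda * (amp$length - min(amp$length)))
    amp <- amp[order(amp$length, amp$template), , drop = FALSE]
    rownames(amp) <- NULL
  }
  peak <- vapply(split(amp$efficiency, amp$allele_label), max, numeric(1))
  ratio <- if (length(peak) >= 1 && min(peak) > 0) max(peak) / min(peak) else Inf
  structure(list(amplicons = amp,
                 imbalance = is.finite(ratio) && ratio > ratio_threshold,
                 ratio = ratio),
            class = "asm_het")
}

#' @export
print.asm_het <- function(x, ...) {
  cat(sprintf("<asm_het> %d products, allele intensity ratio %.2f%s\n",
              nrow(x$amplicons), x$ratio,
              if (x$imbalance) " [IMBALANCED]" else ""))
  invisible(x)
}
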