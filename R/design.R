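#' Design constraints for marker construction
#'
#' @param max_product_small_indel Product-size cap (bp) for indels under
#'   20 bp, so that small size differences separate on agarose.
#' @param tetra_outer_max Maximum outer-pair product for tetra-primer assays.
#' @param min_allele_size_gap Minimum size difference (bp) engineered between
#'   allele-diagnostic products.
#' @param tri_primer_target_gap Maximum allowed gap between the short-allele
#'   product and the inner-primer product of a tri-primer design.
#' @param tm_range Acceptable primer melting-temperature interval, degrees C,
#'   around the shared 55 degree annealing program.
#' @param primer_length_range Allowed primer lengths, nt.
#' @param product_range_tetra Size window for tetra-primer and separated
#'   allele-specific products.
#' @return List of class `asm_design_constraints`.
#' @export
design_constraints <- function(max_product_small_indel = 120L,
                               tetra_outer_max = 600L,
                               min_allele_size_gap = 25L,
                               tri_primer_target_gap = 150L,
                               tm_range = c(55, 62),
                               primer_length_range = c(18L, 28L),
                               product_range_tetra = c(120L, 350L)) {
  structure(list(max_product_small_indel = max_product_small_indel,
                 tetra_outer_max = tetra_outer_max,
                 min_allele_size_gap = min_allele_size_gap,
                 tri_primer_target_gap = tri_primer_target_gap,
                 tm_range = tm_range,
                 primer_length_range = primer_length_range,
                 product_range_tetra = product_range_tetra),
            class = "asm_design_constraints")
}

design_failure <- function(msg) {
  stop(errorCondition(msg, class = c("asm_design_failure", "error",
                                     "condition")))
}

new_marker_design <- function(name, architecture, primers, reactions,
                              expected_products, positive_allele, variant,
                              templates, size_exact = TRUE) {
  names(primers) <- vapply(primers, `[[`, character(1), "name")
  d <- structure(list(name = name, architecture = architecture,
                      primers = primers, reactions = reactions,
                      expected_products = expected_products,
                      positive_allele = positive_allele,
                      recommended_gel = NA_character_, variant = variant,
                      templates = templates, size_exact = size_exact),
                 class = "asm_marker_design")
  d$recommended_gel <- recommend_gel(d)$id
  d
}

#' @export
print.asm_marker_design <- function(x, ...) {
  cat(sprintf("<asm_marker_design> %s (%s), %d primers, %d reaction(s), gel %s\n",
              x$name, x$architecture, length(x$primers), length(x$reactions),
              x$recommended_gel))
  ep <- x$expected_products
  for (a in unique(ep$allele)) {
    cat(sprintf("  %s%s: %s bp\n", a,
                if (a == x$positive_allele) " (positive)" else "",
                paste(ep$length[ep$allele == a], collapse = "/")))
  }
  invisible(x)
}

# --- candidate primer search -------------------------------------------------

# Footprint candidates with the 3' end fixed (allele-specific primers).
.cands_fixed3 <- function(seq, pos3, dir, lengths) {
  L <- seq(lengths[1], lengths[2])
  if (dir == "forward") {
    start <- pos3 - L + 1L; end <- rep(pos3, length(L))
  } else {
    start <- rep(pos3, length(L)); end <- pos3 + L - 1L
  }
  ok <- start >= 1 & end <= nchar(seq)
  data.frame(start = start[ok], end = end[ok], length = L[ok],
             stringsAsFactors = FALSE)
}

# Footprint candidates with the 3' end anywhere in a window (common primers).
.cands_window <- function(seq, pos3_range, dir, lengths) {
  p3 <- seq(pos3_range[1], pos3_range[2])
  L <- seq(lengths[1], lengths[2])
  grid <- expand.grid(pos3 = p3, length = L)
  if (dir == "forward") {
    grid$start <- grid$pos3 - grid$length + 1L; grid$end <- grid$pos3
  } else {
    grid$start <- grid$pos3; grid$end <- grid$pos3 + grid$length - 1L
  }
  grid <- grid[grid$start >= 1 & grid$end <= nchar(seq), , drop = FALSE]
  grid
}

# Rank candidates by closeness to the 58 degree sweet spot inside tm_range;
# ties resolved by leftmost position for determinism.
.rank_tm <- function(cands, seq, dir, tm_range, keep = 30L) {
  if (!nrow(cands)) return(cands)
  cands$footprint <- substring(seq, cands$start, cands$end)
  cands$primer_seq <- if (dir == "forward") cands$footprint else
    seq_revcomp(cands$footprint)
  cands$tm <- vapply(cands$primer_seq, compute_tm, numeric(1),
                     USE.NAMES = FALSE)
  cands <- cands[cands$tm >= tm_range[1] & cands$tm <= tm_range[2], ,
                 drop = FALSE]
  cands <- cands[order(abs(cands$tm - 58), cands$start, cands$length), ,
                 drop = FALSE]
  utils::head(cands, keep)
}

# Build an allele-specific ARMS primer whose 3' end sits on the SNP.
.arms_primer <- function(name, t_seq, pos1, dir, length, allele_base, role) {
  if (dir == "forward") {
    fp <- substring(t_seq, pos1 - length + 1L, pos1)
    raw <- paste0(substr(fp, 1, length - 1), toupper(allele_base))
    term <- toupper(allele_base)
  } else {
    fp <- substring(t_seq, pos1, pos1 + length - 1L)
    raw <- seq_revcomp(fp)
    term <- toupper(seq_complement(allele_base))
    raw <- paste0(substr(raw, 1, length - 1), term)
  }
  p <- primer(name, raw, strand = dir, role = role)
  insert_artificial_mismatch(p, term, offset = 2L)
}

.indel_geometry <- function(t, v, other_label) {
  t <- as_locus(t)
  if (!v$vtype %in% c("insertion", "deletion")) {
    design_failure("variant is not an indel")
  }
  if (v$length < 1) design_failure("zero-length indel")
  if (v$vtype == "deletion") {
    long <- t
    short <- apply_variants(t, v, id = paste0(t$id, "_", other_label),
                            allele_label = other_label)
    long_is_ref <- TRUE
  } else {
    long <- apply_variants(t, v, id = paste0(t$id, "_", other_label),
                           allele_label = other_label)
    short <- t
    long_is_ref <- FALSE
  }
  seg_start <- v$position + 1L          # 1-based on the long allele
  seg_end <- v$position + v$length
  list(long = long, short = short, seg_start = seg_start, seg_end = seg_end,
       long_is_ref = long_is_ref)
}

.verify_design <- function(d, max_product = 2000) {
  for (r in names(d$reactions)) {
    prs <- d$primers[d$reactions[[r]]]
    for (tp in d$templates) {
      amp <- amplify(prs, tp, max_product = max_product)
      got <- sort(amp$length)
      exp <- sort(d$expected_products$length[
        d$expected_products$allele == tp$allele_label &
          d$expected_products$reaction == r])
      if (!identical(as.integer(got), as.integer(exp))) return(FALSE)
    }
  }
  TRUE
}

# --- architectures -----------------------------------------------------------

#' Design an indel-spanning marker
#'
#' Places a forward and a reverse primer flanking the indel so the two allele
#' products differ by exactly the indel length. For indels under 20 bp the
#' product is capped (default 120 bp) so the difference separates on agarose.
#'
#' @param t Reference [locus()] carrying the allele the variant coordinates
#'   refer to (the positive/donor allele).
#' @param v An indel [variant()] on `t`.
#' @param c [design_constraints()].
#' @param name Marker name.
#' @param other_label Allele label for the reconstructed second template.
#' @return An `asm_marker_design`; its `templates` hold both reconstructed
#'   allele sequences and its `expected_products` the per-allele sizes.
#' @export
design_indel_marker <- function(t, v, c = design_constraints(),
                                name = paste0(t$id, "-indel"),
                                other_label = "non_target") {
  g <- .indel_geometry(t, v, other_label)
  lengths <- c$primer_length_range
  cap <- if (v$length < 20) c$max_product_small_indel else NA_integer_
  span <- if (is.na(cap)) 60L else 30L
  fc <- .cands_window(g$long$sequence,
                      c(max(lengths[2], g$seg_start - 1L - span),
                        g$seg_start - 1L), "forward", lengths)
  rc <- .cands_window(g$long$sequence,
                      c(g$seg_end + 1L,
                        min(nchar(g$long$sequence) - lengths[2] + 1L,
                            g$seg_end + 1L + span)), "reverse", lengths)
  fc <- .rank_tm(fc, g$long$sequence, "forward", c$tm_range)
  rc <- .rank_tm(rc, g$long$sequence, "reverse", c$tm_range)
  if (!nrow(fc) || !nrow(rc)) {
    design_failure(sprintf(
      "no flanking primer in Tm range %.0f-%.0f within %d bp of the indel",
      c$tm_range[1], c$tm_range[2], span))
  }
  pairs <- expand.grid(fi = seq_len(nrow(fc)), ri = seq_len(nrow(rc)))
  pairs$long_prod <- rc$end[pairs$ri] - fc$start[pairs$fi] + 1L
  pairs$short_prod <- pairs$long_prod - v$length
  pairs$badness <- abs(fc$tm[pairs$fi] - 58) + abs(rc$tm[pairs$ri] - 58)
  ok <- pairs$short_prod >= fc$length[pairs$fi] + rc$length[pairs$ri]
  if (!is.na(cap)) ok <- ok & pairs$long_prod <= cap
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) {
    design_failure(if (!is.na(cap))
      sprintf("no primer pair keeps both products under the %d bp cap", cap)
      else "no primer pair with non-overlapping footprints on the short allele")
  }
  pairs <- pairs[order(pairs$badness, pairs$long_prod, fc$start[pairs$fi]), ,
                 drop = FALSE]
  for (k in seq_len(min(nrow(pairs), 50L))) {
    fi <- pairs$fi[k]; ri <- pairs$ri[k]
    pf <- primer(paste0(name, "-F"), fc$primer_seq[fi], "forward",
                 "common_outer")
    pr <- primer(paste0(name, "-R"), rc$primer_seq[ri], "reverse",
                 "common_outer")
    long_lab <- g$long$allele_label; short_lab <- g$short$allele_label
    ep <- data.frame(
      allele = c(long_lab, short_lab), reaction = "main",
      length = c(pairs$long_prod[k], pairs$short_prod[k]),
      stringsAsFactors = FALSE)
    d <- new_marker_design(name, "indel", list(pf, pr),
                           list(main = c(pf$name, pr$name)), ep,
                           positive_allele = t$allele_label, variant = v,
                           templates = list(g$long, g$short))
    if (.verify_design(d)) return(d)
  }
  design_failure("candidate primer pairs bind the template at secondary sites")
}

#' Design a tetra-primer (single-tube ARMS) SNP marker
#'
#' Two common outer primers plus two inner allele-specific primers on opposite
#' strands: one reaction yields a common outer band on every allele and an
#' allele-diagnostic band whose size reveals the genotype. The inner primers
#' end on the SNP, carry an engineered destabilizing mismatch near the 3' end,
#' and are placed asymmetrically so the two allele products differ by at least
#' the resolvable gap.
#'
#' @inheritParams design_indel_marker
#' @param v A SNP [variant()]; `ref` is `t`'s (positive) base.
#' @export
design_tetra_primer <- function(t, v, c = design_constraints(),
                                name = paste0(t$id, "-SNP"),
                                other_label = "non_target") {
  t <- as_locus(t)
  if (v$vtype != "SNP") design_failure("variant is not a SNP")
  P <- v$position + 1L
  lengths <- c$primer_length_range
  alt_t <- apply_variants(t, v, id = paste0(t$id, "_", other_label),
                          allele_label = other_label)
  s1 <- 170L                                   # non-target product target
  s2 <- s1 + max(c$min_allele_size_gap + 45L, 70L)  # positive product target
  if (P - s2 < 1 || P + s2 > nchar(t$sequence)) {
    design_failure("insufficient flanking sequence around the SNP")
  }
  ic_f <- .rank_tm(.cands_fixed3(t$sequence, P, "forward", lengths),
                   t$sequence, "forward", c$tm_range, keep = 1L)
  ic_r <- .rank_tm(.cands_fixed3(t$sequence, P, "reverse", lengths),
                   t$sequence, "reverse", c$tm_range, keep = 1L)
  if (!nrow(ic_f) || !nrow(ic_r)) {
    design_failure("no inner allele-specific primer in Tm range at the SNP")
  }
  inner_f <- .arms_primer(paste0(name, "-PF"), t$sequence, P, "forward",
                          ic_f$length[1], v$ref, "positive_allele")
  inner_r <- .arms_primer(paste0(name, "-NR"), t$sequence, P, "reverse",
                          ic_r$length[1], v$alt, "non_target_allele")
  Lf <- nchar(inner_f$sequence); Lr <- nchar(inner_r$sequence)
  # outer forward: pairs with inner_r for the non-target product (s1)
  opf_start <- P + Lr - s1
  fc <- .rank_tm(.cands_window(t$sequence,
                               c(opf_start - 15L + lengths[1] - 1L,
                                 opf_start + 15L + lengths[2] - 1L),
                               "forward", lengths),
                 t$sequence, "forward", c$tm_range)
  # outer reverse: pairs with inner_f for the positive product (s2)
  opr_end <- P + s2 - Lf
  rc <- .rank_tm(.cands_window(t$sequence, c(opr_end - 15L, opr_end + 15L),
                               "reverse", lengths),
                 t$sequence, "reverse", c$tm_range)
  if (!nrow(fc) || !nrow(rc)) {
    design_failure("no outer primer in Tm range at the target distances")
  }
  for (fi in seq_len(nrow(fc))) for (ri in seq_len(nrow(rc))) {
    prod_n <- (P + Lr - 1L) - fc$start[fi] + 1L
    prod_p <- rc$end[ri] - (P - Lf + 1L) + 1L
    outer <- rc$end[ri] - fc$start[fi] + 1L
    if (abs(prod_p - prod_n) < c$min_allele_size_gap) next
    if (prod_n < c$product_range_tetra[1] || prod_n > c$product_range_tetra[2])
      next
    if (prod_p < c$product_range_tetra[1] || prod_p > c$product_range_tetra[2])
      next
    if (outer > c$tetra_outer_max) next
    opf <- primer(paste0(name, "-OPF"), fc$primer_seq[fi], "forward",
                  "common_outer")
    opr <- primer(paste0(name, "-OPR"), rc$primer_seq[ri], "reverse",
                  "common_outer")
    ep <- data.frame(
      allele = c(t$allele_label, t$allele_label, other_label, other_label),
      reaction = "main",
      length = c(outer, prod_p, outer, prod_n), stringsAsFactors = FALSE)
    d <- new_marker_design(name, "tetra_primer",
                           list(opf, opr, inner_f, inner_r),
                           list(main = c(opf$name, opr$name, inner_f$name,
                                         inner_r$name)),
                           ep, positive_allele = t$allele_label, variant = v,
                           templates = list(t, alt_t))
    if (.verify_design(d, max_product = c$tetra_outer_max + 50)) return(d)
  }
  design_failure("no outer-primer placement yields distinguishable, verified products")
}

#' Design a separated allele-specific (two-reaction ARMS) SNP marker
#'
#' Two PCR reactions share a common primer; each adds one allele-specific
#' primer ending on its allele's base with an engineered 3'-proximal mismatch.
#' Amplification in a reaction reports presence of that allele.
#'
#' @inheritParams design_tetra_primer
#' @export
design_separated_AS <- function(t, v, c = design_constraints(),
                                name = paste0(t$id, "-SNP"),
                                other_label = "non_target") {
  t <- as_locus(t)
  if (v$vtype != "SNP") design_failure("variant is not a SNP")
  if (identical(v$ref, v$alt)) design_failure("alleles are identical")
  P <- v$position + 1L
  lengths <- c$primer_length_range
  target <- 220L
  alt_t <- apply_variants(t, v, id = paste0(t$id, "_", other_label),
                          allele_label = other_label)
  ic <- .rank_tm(.cands_fixed3(t$sequence, P, "reverse", lengths),
                 t$sequence, "reverse", c$tm_range, keep = 1L)
  if (!nrow(ic)) design_failure("no allele-specific primer in Tm range at the SNP")
  r_pos <- .arms_primer(paste0(name, "-PR"), t$sequence, P, "reverse",
                        ic$length[1], v$ref, "positive_allele")
  r_neg <- .arms_primer(paste0(name, "-NR"), t$sequence, P, "reverse",
                        ic$length[1], v$alt, "non_target_allele")
  Lr <- nchar(r_pos$sequence)
  f_start <- P + Lr - target
  if (f_start < 1) design_failure("insufficient upstream flank for the common primer")
  fc <- .rank_tm(.cands_window(t$sequence,
                               c(f_start - 20L + lengths[1] - 1L,
                                 f_start + 20L + lengths[2] - 1L),
                               "forward", lengths),
                 t$sequence, "forward", c$tm_range)
  if (!nrow(fc)) design_failure("no common primer in Tm range upstream of the SNP")
  for (fi in seq_len(nrow(fc))) {
    prod <- (P + Lr - 1L) - fc$start[fi] + 1L
    if (prod < c$product_range_tetra[1] || prod > c$product_range_tetra[2])
      next
    pf <- primer(paste0(name, "-F"), fc$primer_seq[fi], "forward",
                 "common_outer")
    ep <- data.frame(allele = c(t$allele_label, other_label),
                     reaction = c("positive", "non_target"),
                     length = c(prod, prod), stringsAsFactors = FALSE)
    d <- new_marker_design(name, "separated_AS", list(pf, r_pos, r_neg),
                           list(positive = c(pf$name, r_pos$name),
                                non_target = c(pf$name, r_neg$name)),
                           ep, positive_allele = t$allele_label, variant = v,
                           templates = list(t, alt_t))
    if (.verify_design(d)) return(d)
  }
  design_failure("no common-primer placement verified for both reactions")
}

#' Design a tri-primer (gap-reduction) marker for a large indel
#'
#' For indels of 100 bp and more, a flanking outer pair alone produces allele
#' products so different in size that the long product amplifies poorly in
#' heterozygotes. A third primer annealing inside the insertion shrinks the
#' long-allele product to within `tri_primer_target_gap` of the short-allele
#' product, equalizing band intensity.
#'
#' @inheritParams design_indel_marker
#' @export
design_tri_primer <- function(t, v, c = design_constraints(),
                              name = paste0(t$id, "-indelP"),
                              other_label = "non_target") {
  g <- .indel_geometry(t, v, other_label)
  if (v$length < 100) {
    design_failure("indel under 100 bp: use design_indel_marker")
  }
  lengths <- c$primer_length_range
  fc <- .rank_tm(.cands_window(g$long$sequence,
                               c(max(lengths[2], g$seg_start - 41L),
                                 g$seg_start - 1L), "forward", lengths),
                 g$long$sequence, "forward", c$tm_range)
  rc <- .rank_tm(.cands_window(g$long$sequence,
                               c(g$seg_end + 1L,
                                 min(nchar(g$long$sequence) - lengths[2] + 1L,
                                     g$seg_end + 41L)), "reverse", lengths),
                 g$long$sequence, "reverse", c$tm_range)
  if (!nrow(fc) || !nrow(rc)) {
    design_failure("no flanking primer in Tm range next to the indel")
  }
  fc <- utils::head(fc, 5L); rc <- utils::head(rc, 5L)
  for (fi in seq_len(nrow(fc))) for (ri in seq_len(nrow(rc))) {
    long_prod <- rc$end[ri] - fc$start[fi] + 1L
    short_prod <- long_prod - v$length
    if (short_prod < fc$length[fi] + rc$length[ri]) next
    pf <- primer(paste0(name, "-F"), fc$primer_seq[fi], "forward",
                 "common_outer")
    pr <- primer(paste0(name, "-R"), rc$primer_seq[ri], "reverse",
                 "common_outer")
    # inner primer inside the insertion, aiming at a reduced gap
    for (gap_target in c(-100L, 100L, seq(-c$tri_primer_target_gap,
                                          c$tri_primer_target_gap, by = 10L))) {
      if (abs(gap_target) < c$min_allele_size_gap) next
      inner_prod <- short_prod + gap_target
      in_start <- rc$end[ri] - inner_prod + 1L
      if (in_start < g$seg_start || in_start + lengths[1] - 1L > g$seg_end)
        next
      # inner is a forward primer with fixed 5' start (its start sets the
      # product length); enumerate lengths directly
      L <- seq(lengths[1], lengths[2])
      icands <- data.frame(start = in_start, end = in_start + L - 1L,
                           length = L)
      icands <- icands[icands$end <= g$seg_end, , drop = FALSE]
      if (!nrow(icands)) next
      icands <- .rank_tm(icands, g$long$sequence, "forward", c$tm_range,
                         keep = 1L)
      if (!nrow(icands)) next
      pin <- primer(paste0(name, "-insF"), icands$primer_seq[1], "forward",
                    "inner_indel")
      inner_len <- rc$end[ri] - icands$start[1] + 1L
      gap <- abs(short_prod - inner_len)
      if (gap < c$min_allele_size_gap || gap > c$tri_primer_target_gap) next
      ep <- data.frame(
        allele = c(g$short$allele_label, g$long$allele_label,
                   g$long$allele_label),
        reaction = "main",
        length = c(short_prod, inner_len, long_prod), stringsAsFactors = FALSE)
      d <- new_marker_design(name, "tri_primer", list(pf, pr, pin),
                             list(main = c(pf$name, pr$name, pin$name)), ep,
                             positive_allele = t$allele_label, variant = v,
                             templates = list(g$long, g$short))
      if (.verify_design(d)) return(d)
    }
  }
  design_failure("no inner-primer placement satisfies the gap window")
}

#' Export a fluorescent (competitive allele-specific) SNP assay record
#'
#' Emits the 501-nt sequence context (250 bp each side of the SNP, alleles
#' bracketed) used to order fluorescence-read genotyping assays, with the
#' positive allele assigned the HEX (green) dye and the non-target allele FAM
#' (red).
#'
#' @param t Reference [locus()].
#' @param v SNP [variant()] on `t`; `ref` is taken as the positive allele
#'   unless `positive = "alt"`.
#' @param name Assay name.
#' @param positive Which allele is yield-positive, "ref" or "alt".
#' @return List with `name`, `context` (e.g. `...ACG[T/C]GCA...`),
#'   `hex_allele`, `fam_allele`.
#' @export
export_fluorescent_assay <- function(t, v, name = paste0(t$id, "-FD"),
                                     positive = c("ref", "alt")) {
  t <- as_locus(t)
  positive <- match.arg(positive)
  if (v$vtype != "SNP") stop("fluorescent assay export requires a SNP",
                             call. = FALSE)
  P <- v$position + 1L
  if (P - 250 < 1 || P + 250 > nchar(t$sequence)) {
    stop("SNP needs 250 bp of flank on each side", call. = FALSE)
  }
  up <- substring(t$sequence, P - 250L, P - 1L)
  down <- substring(t$sequence, P + 1L, P + 250L)
  pos_base <- if (positive == "ref") v$ref else v$alt
  non_base <- if (positive == "ref") v$alt else v$ref
  list(name = name,
       context = sprintf("%s[%s/%s]%s", up, v$ref, v$alt, down),
       hex_allele = pos_base, fam_allele = non_base)
}
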