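#' Create a variant
#'
#' A SNP or indel between a donor allele and a non-target allele, expressed on
#' the coordinates of a reference locus (0-based offset of the first affected
#' base). Indels are pure (no anchor base): a deletion has `alt = ""`, an
#' insertion `ref = ""` with `position` the offset at which the inserted bases
#' appear.
#'
#' @param position 0-based offset on the reference locus.
#' @param ref Reference-allele bases ("" for an insertion).
#' @param alt Alternate-allele bases ("" for a deletion).
#' @param donor_specific Is the variant present against every recipient?
#' @param label Free-text description (e.g. "16-bp indel in the 5'UTR").
#' @return An object of class `asm_variant` with derived `vtype`
#'   (SNP/insertion/deletion) and `length`.
#' @export
variant <- function(position, ref, alt, donor_specific = NA, label = "") {
  stopifnot(is.numeric(position), position >= 0)
  ref <- toupper(ref); alt <- toupper(alt)
  if (nzchar(ref)) check_dna(ref, "ref allele")
  if (nzchar(alt)) check_dna(alt, "alt allele")
  if (!nzchar(ref) && !nzchar(alt)) {
    stop("variant with empty ref and alt", call. = FALSE)
  }
  vtype <- if (nchar(ref) == 1 && nchar(alt) == 1) {
    if (ref == alt) stop("SNP with identical alleles", call. = FALSE)
    "SNP"
  } else if (nchar(ref) > nchar(alt)) {
    if (nzchar(alt)) stop("indels must be pure (one of ref/alt empty)",
                          call. = FALSE)
    "deletion"
  } else if (nchar(alt) > nchar(ref)) {
    if (nzchar(ref)) stop("indels must be pure (one of ref/alt empty)",
                          call. = FALSE)
    "insertion"
  } else stop("ref and alt have equal length > 1", call. = FALSE)
  structure(list(position = as.integer(position), vtype = vtype, ref = ref,
                 alt = alt, length = abs(nchar(ref) - nchar(alt)),
                 donor_specific = donor_specific, label = label),
            class = "asm_variant")
}

#' @export
print.asm_variant <- function(x, ...) {
  cat(sprintf("<asm_variant> %s at %d (1-based %d): %s -> %s (%d bp)%s\n",
              x$vtype, x$position, x$position + 1L,
              if (nzchar(x$ref)) x$ref else "-",
              if (nzchar(x$alt)) x$alt else "-",
              if (x$vtype == "SNP") 1L else x$length,
              if (isTRUE(x$donor_specific)) " [donor-specific]" else ""))
  invisible(x)
}

# Shift an indel to its leftmost equivalent position on the reference.
normalize_variant_left <- function(v, ref_seq) {
  if (v$vtype == "SNP") return(v)
  seq <- if (nzchar(v$ref)) v$ref else v$alt
  pos <- v$position
  while (pos > 0) {
    prev <- substr(ref_seq, pos, pos)  # 0-based pos => 1-based pos
    last <- substr(seq, nchar(seq), nchar(seq))
    if (prev != last) break
    seq <- paste0(prev, substr(seq, 1, nchar(seq) - 1))
    pos <- pos - 1L
  }
  if (pos == v$position) return(v)
  variant(pos, if (nzchar(v$ref)) seq else "", if (nzchar(v$alt)) seq else "",
          v$donor_specific, v$label)
}

#' Apply variants to a locus, reconstructing the other allele
#'
#' @param t Reference [locus()] (the allele whose coordinates the variants
#'   use).
#' @param variants List of [variant()] objects.
#' @param id,allele_label Identity of the reconstructed locus.
#' @return A new [locus()].
#' @export
apply_variants <- function(t, variants, id = paste0(t$id, "_alt"),
                           allele_label = "alt") {
  t <- as_locus(t)
  seq <- t$sequence
  if (inherits(variants, "asm_variant")) variants <- list(variants)
  ord <- order(vapply(variants, `[[`, integer(1), "position"),
               decreasing = TRUE)
  for (v in variants[ord]) {
    p <- v$position  # 0-based; substring before is seq[1..p]
    if (p + nchar(v$ref) > nchar(seq)) {
      stop("variant exceeds locus bounds", call. = FALSE)
    }
    if (nzchar(v$ref) &&
        substr(seq, p + 1, p + nchar(v$ref)) != v$ref) {
      stop(sprintf("ref mismatch at %d: locus has %s, variant says %s", p,
                   substr(seq, p + 1, p + nchar(v$ref)), v$ref), call. = FALSE)
    }
    seq <- paste0(substr(seq, 1, p), v$alt,
                  substr(seq, p + nchar(v$ref) + 1, nchar(seq)))
  }
  locus(id, seq, allele_label)
}

#' Scan a donor/recipient locus pair for polymorphisms
#'
#' Aligns the two allele sequences (global alignment with affine gap
#' penalties, appropriate for near-identical alleles of one locus) and
#' reports every SNP and indel, positioned on the donor coordinate system
#' with indels left-normalized.
#'
#' @param donor,recipient [locus()] objects (or sequences).
#' @param aligned If TRUE the two sequences are a pre-computed pairwise
#'   alignment of equal length with "-" gaps; no internal alignment is run.
#' @return List of [variant()] objects (empty when identical); ref = donor
#'   base(s), alt = recipient.
#' @export
scan_pair <- function(donor, recipient, aligned = FALSE) {
  if (aligned) {
    dal <- toupper(if (inherits(donor, "asm_locus")) donor$sequence else donor)
    ral <- toupper(if (inherits(recipient, "asm_locus")) recipient$sequence
                   else recipient)
    if (nchar(dal) != nchar(ral)) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
  } else {
    donor <- as_locus(donor, "donor")
    recipient <- as_locus(recipient, "recipient")
    if (identical(donor$sequence, recipient$sequence)) return(list())
    pa <- Biostrings::pairwiseAlignment(
      donor$sequence, recipient$sequence, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 4, gapExtension = 1)
    if (Biostrings::score(pa) < 0) {
      stop("no significant similarity between donor and recipient", call. = FALSE)
    }
    dal <- as.character(Biostrings::alignedPattern(pa))
    ral <- as.character(Biostrings::alignedSubject(pa))
  }
  dc <- seq_chars(dal); rc <- seq_chars(ral)
  if (any(dc == "-" & rc == "-")) stop("alignment has all-gap column",
                                       call. = FALSE)
  donor_plain <- gsub("-", "", dal, fixed = TRUE)
  out <- list()
  dpos <- 0L  # donor bases consumed
  i <- 1L
  n <- length(dc)
  while (i <= n) {
    if (dc[i] != "-" && rc[i] != "-") {
      if (dc[i] != rc[i]) {
        out[[length(out) + 1L]] <- variant(dpos, dc[i], rc[i])
      }
      dpos <- dpos + 1L
      i <- i + 1L
    } else if (rc[i] == "-") {            # donor has extra bases: deletion
      j <- i
      while (j <= n && rc[j] == "-") j <- j + 1L
      run <- paste(dc[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <- variant(dpos, run, "")
      dpos <- dpos + nchar(run)
      i <- j
    } else {                              # recipient extra bases: insertion
      j <- i
      while (j <= n && dc[j] == "-") j <- j + 1L
      run <- paste(rc[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <- variant(dpos, "", run)
      i <- j
    }
  }
  lapply(out, normalize_variant_left, ref_seq = donor_plain)
}

variant_key <- function(v) {
  paste(v$position, v$vtype, v$ref, v$alt, sep = "|")
}

#' Flag donor-specific variants across multiple recipients
#'
#' A variant is donor-specific when it appears in the donor-versus-recipient
#' comparison for every recipient, i.e. the donor base differs from all
#' recipient backgrounds and the marker built on it will segregate in any
#' cross.
#'
#' @param variants_per_recipient Named list: recipient id -> list of variants
#'   from [scan_pair()] against that recipient (all on donor coordinates).
#' @return The union of variants, each with `donor_specific` set.
#' @export
mark_donor_specific <- function(variants_per_recipient) {
  if (!length(variants_per_recipient)) {
    stop("at least one recipient comparison is required", call. = FALSE)
  }
  keysets <- lapply(variants_per_recipient,
                    function(vs) vapply(vs, variant_key, character(1)))
  shared <- Reduce(intersect, keysets)
  seen <- character(0)
  out <- list()
  for (vs in variants_per_recipient) {
    for (v in vs) {
      k <- variant_key(v)
      if (k %in% seen) next
      seen <- c(seen, k)
      v$donor_specific <- k %in% shared
      out[[length(out) + 1L]] <- v
    }
  }
  out[order(vapply(out, `[[`, integer(1), "position"))]
}

#' Recommend a marker architecture for a variant
#'
#' Indels shorter than 20 bp get a product-size-capped flanking-primer marker;
#' indels of 100 bp and more get the tri-primer gap-reduction architecture
#' (both allele products amplify with comparable efficiency in heterozygotes);
#' intermediate indels get a plain flanking marker. For SNPs the single-tube
#' tetra-primer assay is preferred for its convenience, with separated
#' allele-specific PCR as the fallback when tetra-primer designs prove
#' unstable.
#'
#' @param v A [variant()].
#' @return List of class `asm_strategy`: `variant`, `strategy`,
#'   `alternatives`, `rationale`, `product_cap` (bp or NA).
#' @export
recommend_strategy <- function(v) {
  stopifnot(inherits(v, "asm_variant"))
  if (v$vtype == "SNP") {
    res <- list(strategy = "snp_tetra_primer",
                alternatives = "snp_separated_AS",
                rationale = "single-tube tetra-primer assay preferred for SNPs; separated allele-specific PCR as fallback",
                product_cap = NA_integer_)
  } else if (v$length < 20) {
    res <- list(strategy = "small_indel", alternatives = character(0),
                rationale = "indel < 20 bp: flanking primers with product size capped at 120 bp for band separation",
                product_cap = 120L)
  } else if (v$length >= 100) {
    res <- list(strategy = "large_indel_tri_primer", alternatives = character(0),
                rationale = "indel >= 100 bp: tri-primer design equalizes allele amplification in heterozygotes",
                product_cap = NA_integer_)
  } else {
    res <- list(strategy = "small_indel", alternatives = character(0),
                rationale = "indel 20-99 bp: flanking primers, gap resolvable on standard agarose without a size cap",
                product_cap = NA_integer_)
  }
  structure(c(list(variant = v), res), class = "asm_strategy")
}

#' Tabulate variants for reporting
#'
#' @param variants List of [variant()] objects.
#' @param locus_id Locus name for the first column.
#' @param strategies Add a recommended-strategy column?
#' @return data.frame with 1-based positions (human-readable convention).
#' @export
variant_table <- function(variants, locus_id = "locus", strategies = TRUE) {
  if (!length(variants)) {
    return(data.frame(locus = character(), pos_1based = integer(),
                      type = character(), ref = character(), alt = character(),
                      length = integer(), donor_specific = logical(),
                      strategy = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    locus = locus_id,
    pos_1based = vapply(variants, `[[`, integer(1), "position") + 1L,
    type = vapply(variants, `[[`, character(1), "vtype"),
    ref = vapply(variants, function(v) if (nzchar(v$ref)) v$ref else "-",
                 character(1)),
    alt = vapply(variants, function(v) if (nzchar(v$alt)) v$alt else "-",
                 character(1)),
    length = vapply(variants, function(v)
      if (v$vtype == "SNP") 1L else v$length, integer(1)),
    donor_specific = vapply(variants, function(v)
      isTRUE(v$donor_specific), logical(1)),
    stringsAsFactors = FALSE)
  if (strategies) {
    df$strategy <- vapply(variants, function(v) recommend_strategy(v)$strategy,
                          character(1))
  }
  df
}
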