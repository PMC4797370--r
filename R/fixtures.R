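# Reconstruction of allele template pairs for the packaged marker set.
#
# Only the primer sequences, the variant annotations and (where printed) the
# product sizes of the markers are known; the templates themselves are
# synthetic: primer footprints are laid out with the spacing implied by the
# product sizes and the gaps are filled with seeded random sequence, rejected
# and resampled if it creates spurious primer binding. Where a product size
# was never printed, spacing was chosen once within gel constraints and the
# fixture is excluded from exact-size regression (`size_exact = FALSE`).
#
# Template placement of engineered-mismatch positions: the template carries
# the base whose pairing with the primer's substituted base is a
# purine-purine/pyrimidine-pyrimidine mispair, i.e. the complement of the
# substituted base for forward primers (primer anneals to the minus strand)
# and the substituted base itself for reverse primers.

.PAD <- 30L

# plus-strand footprint of a forward primer on its matching template
.fwd_site <- function(p, terminal = NULL) {
  s <- p$sequence
  if (!is.null(p$mismatch)) {
    i <- nchar(s) - p$mismatch$offset_from_3prime + 1L
    substr(s, i, i) <- toupper(seq_complement(p$mismatch$base))
  }
  if (!is.null(terminal)) substr(s, nchar(s), nchar(s)) <- toupper(terminal)
  s
}

# plus-strand footprint of a reverse primer on its matching template
.rev_site <- function(p, first = NULL) {
  s <- seq_revcomp(p$sequence)
  if (!is.null(p$mismatch)) {
    j <- p$mismatch$offset_from_3prime
    substr(s, j, j) <- toupper(p$mismatch$base)
  }
  if (!is.null(first)) substr(s, 1, 1) <- toupper(first)
  s
}

new_marker_fixture <- function(marker, architecture, polymorphism, primers,
                               reactions, templates, expected_products,
                               positive_allele, variant, size_exact,
                               notes = NULL) {
  names(primers) <- vapply(primers, `[[`, character(1), "name")
  names(templates) <- vapply(templates, `[[`, character(1), "allele_label")
  structure(list(marker = marker, architecture = architecture,
                 polymorphism = polymorphism, primers = primers,
                 reactions = reactions, templates = templates,
                 expected_products = expected_products,
                 positive_allele = positive_allele, variant = variant,
                 recommended_gel = NA_character_,
                 size_exact = size_exact, notes = notes),
            class = "asm_marker_fixture")
}

#' @export
print.asm_marker_fixture <- function(x, ...) {
  cat(sprintf("<asm_marker_fixture> %s (%s): %s\n", x$marker, x$architecture,
              x$polymorphism))
  ep <- x$expected_products
  for (a in unique(ep$allele)) {
    cat(sprintf("  %s%s: %s bp%s\n", a,
                if (a == x$positive_allele) " (positive)" else "",
                paste(ep$length[ep$allele == a], collapse = "/"),
                if (x$size_exact) "" else " (chosen, not printed)"))
  }
  invisible(x)
}

# Validate a candidate fixture: every primer binds each template exactly the
# intended number of times under the default ARMS model, and in-silico PCR of
# each reaction reproduces the expected products exactly.
.fixture_valid <- function(fx) {
  for (pn in names(fx$primers)) {
    for (tn in names(fx$templates)) {
      n_sites <- nrow(find_binding_sites(fx$primers[[pn]],
                                         fx$templates[[tn]]))
      if (n_sites != fx$site_counts[[pn]][[tn]]) return(FALSE)
    }
  }
  for (r in names(fx$reactions)) {
    prs <- fx$primers[fx$reactions[[r]]]
    for (tp in fx$templates) {
      amp <- amplify(prs, tp, max_product = 2000)
      exp <- sort(fx$expected_products$length[
        fx$expected_products$allele == tp$allele_label &
          fx$expected_products$reaction == r])
      if (!identical(as.integer(sort(amp$length)), as.integer(exp)))
        return(FALSE)
    }
  }
  TRUE
}

.fixture_attempts <- function(gen, max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    fx <- gen()
    if (.fixture_valid(fx)) {
      fx$site_counts <- NULL
      fx$recommended_gel <- recommend_gel(fx)$id
      return(fx)
    }
  }
  stop("could not assemble a fixture without spurious primer binding",
       call. = FALSE)
}

.set_role <- function(p, role, strand = NULL) {
  p$role <- role
  if (!is.null(strand)) p$strand <- strand
  p
}

# --- generic per-architecture builders --------------------------------------

.fx_indel <- function(marker, polymorphism, f, r, seg_len, short_size,
                      long_label, short_label, positive, size_exact,
                      notes = NULL, reaction = "main") {
  lf <- nchar(f$sequence); lr <- nchar(r$sequence)
  spac <- short_size - lf - lr
  stopifnot(spac >= 0)
  sL <- spac %/% 2L; sR <- spac - sL
  f <- .set_role(f, "common_outer", "forward")
  r <- .set_role(r, "common_outer", "reverse")
  gen <- function() {
    seg <- random_dna(seg_len)
    left <- paste0(random_dna(.PAD), .fwd_site(f), random_dna(sL))
    right <- paste0(random_dna(sR), .rev_site(r), random_dna(.PAD))
    long_t <- locus(paste0(marker, ":", long_label),
                    paste0(left, seg, right), long_label)
    short_t <- locus(paste0(marker, ":", short_label),
                     paste0(left, right), short_label)
    v <- normalize_variant_left(
      variant(nchar(left), "", seg,
              donor_specific = TRUE, label = polymorphism),
      short_t$sequence)
    fx <- new_marker_fixture(
      marker, "indel", polymorphism, list(f, r),
      stats::setNames(list(c(f$name, r$name)), reaction),
      list(long_t, short_t),
      data.frame(allele = c(long_label, short_label), reaction = reaction,
                 length = c(short_size + seg_len, short_size),
                 stringsAsFactors = FALSE),
      positive, v, size_exact, notes)
    fx$site_counts <- stats::setNames(
      list(stats::setNames(c(1L, 1L), c(long_label, short_label)),
           stats::setNames(c(1L, 1L), c(long_label, short_label))),
      c(f$name, r$name))
    fx
  }
  .fixture_attempts(gen)
}

.fx_tetra <- function(marker, polymorphism, opf, opr, inf, inr,
                      prod_inf, prod_inr, label_f, label_r, positive,
                      size_exact, notes = NULL) {
  lof <- nchar(opf$sequence); lor <- nchar(opr$sequence)
  lf <- nchar(inf$sequence); lr <- nchar(inr$sequence)
  g1 <- prod_inr - lof - lf - lr + 1L
  g2 <- prod_inf - lf - lr + 1L - lor
  stopifnot(g1 >= 0, g2 >= 0)
  outer <- prod_inf + prod_inr - (lf + lr - 1L)
  base_f <- substr(inf$sequence, lf, lf)                 # allele of inner fwd
  base_r <- seq_complement(substr(inr$sequence, lr, lr)) # allele of inner rev
  opf <- .set_role(opf, "common_outer", "forward")
  opr <- .set_role(opr, "common_outer", "reverse")
  inf <- .set_role(inf, if (label_f == positive) "positive_allele" else
    "non_target_allele", "forward")
  inr <- .set_role(inr, if (label_r == positive) "positive_allele" else
    "non_target_allele", "reverse")
  inf_site <- substr(.fwd_site(inf), 1, lf - 1L)
  inr_site <- substr(.rev_site(inr), 2, lr)
  gen <- function() {
    left <- paste0(random_dna(.PAD), .fwd_site(opf), random_dna(g1), inf_site)
    right <- paste0(inr_site, random_dna(g2), .rev_site(opr),
                    random_dna(.PAD))
    t_f <- locus(paste0(marker, ":", label_f),
                 paste0(left, base_f, right), label_f)
    t_r <- locus(paste0(marker, ":", label_r),
                 paste0(left, base_r, right), label_r)
    pos_t <- if (label_f == positive) t_f else t_r
    v <- variant(nchar(left),
                 if (label_f == positive) base_f else base_r,
                 if (label_f == positive) base_r else base_f,
                 donor_specific = TRUE, label = polymorphism)
    fx <- new_marker_fixture(
      marker, "tetra_primer", polymorphism, list(opf, opr, inf, inr),
      list(main = c(opf$name, opr$name, inf$name, inr$name)),
      list(t_f, t_r),
      data.frame(allele = c(label_f, label_f, label_r, label_r),
                 reaction = "main",
                 length = c(outer, prod_inf, outer, prod_inr),
                 stringsAsFactors = FALSE),
      positive, v, size_exact, notes)
    both1 <- stats::setNames(c(1L, 1L), c(label_f, label_r))
    fx$site_counts <- stats::setNames(
      list(both1, both1,
           stats::setNames(c(1L, 0L), c(label_f, label_r)),
           stats::setNames(c(0L, 1L), c(label_f, label_r))),
      c(opf$name, opr$name, inf$name, inr$name))
    fx
  }
  .fixture_attempts(gen)
}

# separated allele-specific PCR: common forward primer, two allele-specific
# reverse primers sharing one footprint that starts on the SNP
.fx_sep_rev <- function(marker, polymorphism, f, as_pos, as_neg, prod,
                        pos_label, neg_label, size_exact, notes = NULL) {
  stopifnot(nchar(as_pos$sequence) == nchar(as_neg$sequence))
  lf <- nchar(f$sequence); la <- nchar(as_pos$sequence)
  g <- prod - lf - la
  stopifnot(g >= 0)
  base_pos <- seq_complement(substr(as_pos$sequence, la, la))
  base_neg <- seq_complement(substr(as_neg$sequence, la, la))
  f <- .set_role(f, "common_outer", "forward")
  as_pos <- .set_role(as_pos, "positive_allele", "reverse")
  as_neg <- .set_role(as_neg, "non_target_allele", "reverse")
  tail <- substr(.rev_site(as_pos), 2, la)
  gen <- function() {
    left <- paste0(random_dna(.PAD), .fwd_site(f), random_dna(g))
    right <- paste0(tail, random_dna(.PAD))
    t_pos <- locus(paste0(marker, ":", pos_label),
                   paste0(left, base_pos, right), pos_label)
    t_neg <- locus(paste0(marker, ":", neg_label),
                   paste0(left, base_neg, right), neg_label)
    v <- variant(nchar(left), base_pos, base_neg, donor_specific = TRUE,
                 label = polymorphism)
    fx <- new_marker_fixture(
      marker, "separated_AS", polymorphism, list(f, as_pos, as_neg),
      list(positive = c(f$name, as_pos$name),
           non_target = c(f$name, as_neg$name)),
      list(t_pos, t_neg),
      data.frame(allele = c(pos_label, neg_label),
                 reaction = c("positive", "non_target"),
                 length = c(prod, prod), stringsAsFactors = FALSE),
      pos_label, v, size_exact, notes)
    fx$site_counts <- stats::setNames(
      list(stats::setNames(c(1L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(1L, 0L), c(pos_label, neg_label)),
           stats::setNames(c(0L, 1L), c(pos_label, neg_label))),
      c(f$name, as_pos$name, as_neg$name))
    fx
  }
  .fixture_attempts(gen)
}

# separated allele-specific PCR with allele-specific forward primers and one
# common reverse primer
.fx_sep_fwd <- function(marker, polymorphism, as_pos, as_neg, r, prod,
                        pos_label, neg_label, size_exact, notes = NULL) {
  stopifnot(nchar(as_pos$sequence) == nchar(as_neg$sequence))
  la <- nchar(as_pos$sequence); lr <- nchar(r$sequence)
  g <- prod - la - lr
  stopifnot(g >= 0)
  base_pos <- substr(as_pos$sequence, la, la)
  base_neg <- substr(as_neg$sequence, la, la)
  r <- .set_role(r, "common_outer", "reverse")
  as_pos <- .set_role(as_pos, "positive_allele", "forward")
  as_neg <- .set_role(as_neg, "non_target_allele", "forward")
  head_site <- substr(.fwd_site(as_pos), 1, la - 1L)
  gen <- function() {
    left <- paste0(random_dna(.PAD), head_site)
    right <- paste0(random_dna(g), .rev_site(r), random_dna(.PAD))
    t_pos <- locus(paste0(marker, ":", pos_label),
                   paste0(left, base_pos, right), pos_label)
    t_neg <- locus(paste0(marker, ":", neg_label),
                   paste0(left, base_neg, right), neg_label)
    v <- variant(nchar(left), base_pos, base_neg, donor_specific = TRUE,
                 label = polymorphism)
    fx <- new_marker_fixture(
      marker, "separated_AS", polymorphism, list(as_pos, as_neg, r),
      list(positive = c(as_pos$name, r$name),
           non_target = c(as_neg$name, r$name)),
      list(t_pos, t_neg),
      data.frame(allele = c(pos_label, neg_label),
                 reaction = c("positive", "non_target"),
                 length = c(prod, prod), stringsAsFactors = FALSE),
      pos_label, v, size_exact, notes)
    fx$site_counts <- stats::setNames(
      list(stats::setNames(c(1L, 0L), c(pos_label, neg_label)),
           stats::setNames(c(0L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(1L, 1L), c(pos_label, neg_label))),
      c(as_pos$name, as_neg$name, r$name))
    fx
  }
  .fixture_attempts(gen)
}

# SPL14-12SNP: two fully separate primer pairs bracketing one SNP — the
# C-allele forward primer ends on the SNP and pairs with a downstream common
# reverse; the A-allele reverse primer starts on the SNP and pairs with an
# upstream common forward.
.fx_spl14_12 <- function(marker, polymorphism, f, cf, ar, r,
                         prod_far, prod_cfr, pos_label, neg_label,
                         size_exact, notes = NULL) {
  lf <- nchar(f$sequence); lcf <- nchar(cf$sequence)
  lar <- nchar(ar$sequence); lr <- nchar(r$sequence)
  g1 <- prod_far - lf - lcf - lar + 1L
  g3 <- prod_cfr - lcf - lar + 1L - lr
  stopifnot(g1 >= 0, g3 >= 0)
  base_c <- substr(cf$sequence, lcf, lcf)                 # non-target (C)
  base_a <- seq_complement(substr(ar$sequence, lar, lar)) # positive (A)
  f <- .set_role(f, "common_outer", "forward")
  r <- .set_role(r, "common_outer", "reverse")
  cf <- .set_role(cf, "non_target_allele", "forward")
  ar <- .set_role(ar, "positive_allele", "reverse")
  cf_site <- substr(.fwd_site(cf), 1, lcf - 1L)
  ar_site <- substr(.rev_site(ar), 2, lar)
  gen <- function() {
    left <- paste0(random_dna(.PAD), .fwd_site(f), random_dna(g1), cf_site)
    right <- paste0(ar_site, random_dna(g3), .rev_site(r), random_dna(.PAD))
    t_pos <- locus(paste0(marker, ":", pos_label),
                   paste0(left, base_a, right), pos_label)
    t_neg <- locus(paste0(marker, ":", neg_label),
                   paste0(left, base_c, right), neg_label)
    v <- variant(nchar(left), base_a, base_c, donor_specific = TRUE,
                 label = polymorphism)
    fx <- new_marker_fixture(
      marker, "separated_AS", polymorphism, list(f, cf, ar, r),
      list(positive = c(f$name, ar$name),
           non_target = c(cf$name, r$name)),
      list(t_pos, t_neg),
      data.frame(allele = c(pos_label, neg_label),
                 reaction = c("positive", "non_target"),
                 length = c(prod_far, prod_cfr), stringsAsFactors = FALSE),
      pos_label, v, size_exact, notes)
    both1 <- stats::setNames(c(1L, 1L), c(pos_label, neg_label))
    fx$site_counts <- stats::setNames(
      list(both1,
           stats::setNames(c(0L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(1L, 0L), c(pos_label, neg_label)),
           both1),
      c(f$name, cf$name, ar$name, r$name))
    fx
  }
  .fixture_attempts(gen)
}

# TGW6-1d: a 1-bp deletion shifts the base under the 3' end of the reverse
# allele-specific primers; the non-target allele reads ...C-G-core..., the
# positive (deletion) allele ...C-core..., so the two primers NR/PR differ
# only in their terminal base.
.fx_tgw6 <- function(marker, polymorphism, f, nr, pr, prod_pos,
                     pos_label, neg_label, size_exact, notes = NULL) {
  lf <- nchar(f$sequence); la <- nchar(pr$sequence)
  g <- prod_pos - lf - la + 1L
  stopifnot(g >= 1)
  f <- .set_role(f, "common_outer", "forward")
  nr <- .set_role(nr, "non_target_allele", "reverse")
  pr <- .set_role(pr, "positive_allele", "reverse")
  core <- substr(.rev_site(pr), 2, la)   # shared 3'-side footprint tail
  gen <- function() {
    left <- paste0(random_dna(.PAD), .fwd_site(f), random_dna(g - 1L), "C")
    right <- paste0(core, random_dna(.PAD))
    t_pos <- locus(paste0(marker, ":", pos_label), paste0(left, right),
                   pos_label)
    t_neg <- locus(paste0(marker, ":", neg_label), paste0(left, "G", right),
                   neg_label)
    v <- normalize_variant_left(
      variant(nchar(left), "", "G", donor_specific = TRUE,
              label = polymorphism),
      t_pos$sequence)
    fx <- new_marker_fixture(
      marker, "separated_AS", polymorphism, list(f, nr, pr),
      list(positive = c(f$name, pr$name),
           non_target = c(f$name, nr$name)),
      list(t_pos, t_neg),
      data.frame(allele = c(pos_label, neg_label),
                 reaction = c("positive", "non_target"),
                 length = c(prod_pos, prod_pos + 1L), stringsAsFactors = FALSE),
      pos_label, v, size_exact, notes)
    fx$site_counts <- stats::setNames(
      list(stats::setNames(c(1L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(0L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(1L, 0L), c(pos_label, neg_label))),
      c(f$name, nr$name, pr$name))
    fx
  }
  .fixture_attempts(gen)
}

# DEP1-indel1P: outer pair flanking the 625-bp segment plus an inner forward
# primer annealing inside it; spacing reproduces the printed 406/1031/310
# product sizes (positive allele carries the deletion).
.fx_dep1 <- function(marker, polymorphism, f, r, f625, pos_label, neg_label,
                     notes = NULL) {
  seg_len <- 625L; sL <- 265L; sR <- 100L; inner_off <- 437L
  f <- .set_role(f, "common_outer", "forward")
  r <- .set_role(r, "common_outer", "reverse")
  f625 <- .set_role(f625, "inner_indel", "forward")
  l625 <- nchar(f625$sequence)
  gen <- function() {
    seg <- random_dna(seg_len)
    substr(seg, inner_off + 1L, inner_off + l625) <- .fwd_site(f625)
    left <- paste0(random_dna(.PAD), .fwd_site(f), random_dna(sL))
    right <- paste0(random_dna(sR), .rev_site(r), random_dna(.PAD))
    t_neg <- locus(paste0(marker, ":", neg_label), paste0(left, seg, right),
                   neg_label)
    t_pos <- locus(paste0(marker, ":", pos_label), paste0(left, right),
                   pos_label)
    v <- normalize_variant_left(
      variant(nchar(left), "", seg, donor_specific = TRUE,
              label = polymorphism),
      t_pos$sequence)
    short_prod <- nchar(f$sequence) + sL + sR + nchar(r$sequence)
    inner_prod <- (seg_len - inner_off) + sR + nchar(r$sequence)
    fx <- new_marker_fixture(
      marker, "tri_primer", polymorphism, list(f, r, f625),
      list(main = c(f$name, r$name, f625$name)),
      list(t_pos, t_neg),
      data.frame(allele = c(pos_label, neg_label, neg_label),
                 reaction = "main",
                 length = c(short_prod, inner_prod, short_prod + seg_len),
                 stringsAsFactors = FALSE),
      pos_label, v, size_exact = TRUE, notes)
    fx$site_counts <- stats::setNames(
      list(stats::setNames(c(1L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(1L, 1L), c(pos_label, neg_label)),
           stats::setNames(c(0L, 1L), c(pos_label, neg_label))),
      c(f$name, r$name, f625$name))
    fx
  }
  .fixture_attempts(gen)
}

#' Names of the packaged markers
#'
#' @return Character vector of the 14 marker names in the packaged primer
#'   table.
#' @export
paper_marker_names <- function() {
  c("Gn1a-17SNP", "Gn1a-indel3", "Gn1a-indel1", "SPL14-04SNP", "SPL14-12SNP",
    "SCM2-indel1", "Ghd7-05SNP", "DEP1-indel1P", "SPIKE-01SNP", "SPIKE-03SNP",
    "SPIKE-indel3", "GS5-indel1", "GS5-03SNP", "TGW6-1d")
}

#' Reconstruct synthetic allele-template fixtures for the packaged markers
#'
#' For each of the 14 packaged markers, builds a pair of synthetic allele
#' templates on which the marker's primers reproduce the expected product
#' sizes under the in-silico PCR model, with random filler sequence between
#' primer footprints (re-sampled until no primer binds anywhere it should
#' not). Where the literature prints the product sizes the reconstruction is
#' exact (`size_exact = TRUE`); elsewhere the sizes were chosen once within
#' gel constraints.
#'
#' @param markers Subset of [paper_marker_names()] to build.
#' @param seed Seed for the filler sequence; the same seed reproduces
#'   byte-identical templates.
#' @return Named list of `asm_marker_fixture` objects.
#' @export
build_paper_fixtures <- function(markers = paper_marker_names(),
                                 seed = 20160318L) {
  tab <- read_primer_table(system.file("extdata", "table2_primers.tsv",
                                       package = "asmarker"))
  prs <- tab$primers
  poly <- function(m) unique(tab$table$polymorphism[tab$table$marker == m])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  builders <- list(
    "Gn1a-17SNP" = function() .fx_tetra(
      "Gn1a-17SNP", poly("Gn1a-17SNP"),
      prs[["Gn1a-17SNP-OPF"]], prs[["Gn1a-17SNP-OPR"]],
      prs[["Gn1a-17SNP-AF"]], prs[["Gn1a-17SNP-GR"]],
      prod_inf = 176L, prod_inr = 105L,
      label_f = "Habataki", label_r = "non-target", positive = "Habataki",
      size_exact = FALSE,
      notes = "A assigned to the Habataki (Type 3) allele; product sizes chosen (not printed)"),
    "Gn1a-indel3" = function() .fx_indel(
      "Gn1a-indel3", poly("Gn1a-indel3"),
      prs[["Gn1a-indel3-F"]], prs[["Gn1a-indel3-R"]],
      seg_len = 70L, short_size = 150L,
      long_label = "non-target", short_label = "Habataki",
      positive = "Habataki", size_exact = FALSE,
      notes = "indel length stated as approximately 70 bp; sizes and deletion allele chosen"),
    "Gn1a-indel1" = function() .fx_indel(
      "Gn1a-indel1", poly("Gn1a-indel1"),
      prs[["Gn1a-indel1-F"]], prs[["Gn1a-indel1-R"]],
      seg_len = 16L, short_size = 99L,
      long_label = "non-target", short_label = "Habataki",
      positive = "Habataki", size_exact = TRUE),
    "SPL14-04SNP" = function() .fx_sep_rev(
      "SPL14-04SNP", poly("SPL14-04SNP"),
      prs[["SPL14-04SNP-F"]], prs[["SPL14-04SNP-TR"]],
      prs[["SPL14-04SNP-CR"]], prod = 320L,
      pos_label = "ST12", neg_label = "non-target", size_exact = FALSE,
      notes = "T is the ST12 allele; product size chosen (not printed)"),
    "SPL14-12SNP" = function() .fx_spl14_12(
      "SPL14-12SNP", poly("SPL14-12SNP"),
      prs[["SPL14-12SNP-F"]], prs[["SPL14-12SNP-CF"]],
      prs[["SPL14-12SNP-AR"]], prs[["SPL14-12SNP-R"]],
      prod_far = 180L, prod_cfr = 250L,
      pos_label = "Aikawa1", neg_label = "non-target", size_exact = FALSE,
      notes = "A is the Aikawa1 (miR156-resistant) allele; product sizes chosen"),
    "SCM2-indel1" = function() .fx_indel(
      "SCM2-indel1", poly("SCM2-indel1"),
      prs[["SCM2-indel1-F"]], prs[["SCM2-indel1-R"]],
      seg_len = 12L, short_size = 105L,
      long_label = "Habataki", short_label = "non-target",
      positive = "Habataki", size_exact = TRUE,
      notes = "117/105 bp printed; which size belongs to which allele is not stated (117 assigned to Habataki)"),
    "Ghd7-05SNP" = function() .fx_sep_rev(
      "Ghd7-05SNP", poly("Ghd7-05SNP"),
      prs[["Ghd7-05SNP-F"]], prs[["Ghd7-05SNP-TR"]],
      prs[["Ghd7-05SNP-AR"]], prod = 240L,
      pos_label = "Ghd7-1", neg_label = "non-target", size_exact = FALSE,
      notes = "T is the fully functional Ghd7-1 allele; product size chosen"),
    "DEP1-indel1P" = function() .fx_dep1(
      "DEP1-indel1P", poly("DEP1-indel1P"),
      prs[["DEP1-indel1-F"]], prs[["DEP1-indel1-R"]],
      prs[["DEP1-indel1-625F"]],
      pos_label = "Osmancik-97", neg_label = "non-target"),
    "SPIKE-01SNP" = function() .fx_sep_fwd(
      "SPIKE-01SNP", poly("SPIKE-01SNP"),
      prs[["SPIKE-01SNP-GF"]], prs[["SPIKE-01SNP-AF"]],
      prs[["SPIKE-01SNP-R"]], prod = 300L,
      pos_label = "japonica", neg_label = "indica", size_exact = FALSE,
      notes = "G assigned to the japonica (Type 5) allele; product size chosen"),
    "SPIKE-03SNP" = function() .fx_sep_rev(
      "SPIKE-03SNP", poly("SPIKE-03SNP"),
      prs[["SPIKE-03SNP-F"]], prs[["SPIKE-03SNP-GR"]],
      prs[["SPIKE-03SNP-AR"]], prod = 270L,
      pos_label = "japonica", neg_label = "indica", size_exact = FALSE,
      notes = "G assigned to the japonica (Type 5) allele; product size chosen"),
    "SPIKE-indel3" = function() .fx_indel(
      "SPIKE-indel3", poly("SPIKE-indel3"),
      prs[["SPIKE-indel3-F"]], prs[["SPIKE-indel3-R"]],
      seg_len = 20L, short_size = 130L,
      long_label = "japonica", short_label = "indica",
      positive = "japonica", size_exact = FALSE,
      notes = "20-bp promoter indel; sizes and insertion allele chosen"),
    "GS5-indel1" = function() .fx_indel(
      "GS5-indel1", poly("GS5-indel1"),
      prs[["GS5-indel1-F"]], prs[["GS5-indel1-R"]],
      seg_len = 4L, short_size = 63L,
      long_label = "WG/NG", short_label = "MG",
      positive = "MG", size_exact = TRUE,
      notes = "63 bp = MG (4-bp deletion), 67 bp = WG or NG"),
    "GS5-03SNP" = function() .fx_tetra(
      "GS5-03SNP", poly("GS5-03SNP"),
      prs[["GS5-03SNP-OPF"]], prs[["GS5-03SNP-OPR"]],
      prs[["GS5-03SNP-TF"]], prs[["GS5-03SNP-CR"]],
      prod_inf = 291L, prod_inr = 257L,
      label_f = "non-WG", label_r = "WG", positive = "WG",
      size_exact = TRUE,
      notes = "C assigned to the WG allele and 257 bp to the C reaction; the sources give the band set {257, 291} only"),
    "TGW6-1d" = function() .fx_tgw6(
      "TGW6-1d", poly("TGW6-1d"),
      prs[["TGW6-1d-F"]], prs[["TGW6-1d-NR"]], prs[["TGW6-1d-PR"]],
      prod_pos = 210L,
      pos_label = "Kasalath", neg_label = "non-target", size_exact = FALSE,
      notes = "Kasalath carries the 1-bp deletion; product size chosen")
  )
  unknown <- setdiff(markers, names(builders))
  if (length(unknown)) stop("unknown marker(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(markers, function(m) builders[[m]]())
  names(out) <- markers
  out
}

#' Generate a random donor/recipient locus pair with a planted variant
#'
#' Uniform-random background sequence (50\% GC) with one planted SNP or indel,
#' the ground truth returned as a left-normalized [variant()] on donor
#' coordinates.
#'
#' @param seed Optional seed (restores the RNG state afterwards).
#' @param length Donor locus length, bp (>= 200).
#' @param vtype "SNP", "deletion" (recipient lacks donor bases) or
#'   "insertion" (recipient gains bases).
#' @param vlen Indel length, bp (1 for SNP).
#' @param position 0-based variant position; default random in the central
#'   region.
#' @return List with `donor`, `recipient` ([locus()] objects) and `truth`
#'   (the planted [variant()]).
#' @export
random_locus_pair <- function(seed = NULL, length = 1000L,
                              vtype = c("SNP", "deletion", "insertion"),
                              vlen = 1L, position = NULL) {
  vtype <- match.arg(vtype)
  if (length < 200) stop("locus length must be >= 200", call. = FALSE)
  if (vtype != "SNP" && vlen + 150 > length) {
    stop("variant larger than the template allows", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dseq <- random_dna(length)
  if (is.null(position)) {
    lo <- 100L
    hi <- length - 100L - if (vtype == "deletion") vlen else 0L
    position <- sample(seq(lo, hi), 1L)
  }
  v <- switch(vtype,
    SNP = {
      ref <- substr(dseq, position + 1L, position + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      variant(position, ref, alt)
    },
    deletion = variant(position,
                       substr(dseq, position + 1L, position + vlen), ""),
    insertion = variant(position, "", random_dna(vlen))
  )
  donor <- locus("donor", dseq, "donor")
  recipient <- apply_variants(donor, v, id = "recipient",
                              allele_label = "recipient")
  list(donor = donor, recipient = recipient,
       truth = normalize_variant_left(v, dseq))
}
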