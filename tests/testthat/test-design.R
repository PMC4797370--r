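# Marker design engines.

test_that("indel marker design round-trips through in-silico PCR", {
  rp <- random_locus_pair(seed = 7, length = 1000, vtype = "deletion",
                          vlen = 12)
  d <- design_indel_marker(rp$donor, rp$truth)
  expect_s3_class(d, "asm_marker_design")
  lens <- sort(d$expected_products$length)
  expect_identical(diff(lens), 12L)
  expect_true(max(lens) <= 120)
  # products recovered by in-silico PCR on the reconstructed templates
  for (tp in d$templates) {
    amp <- amplify(d$primers, tp)
    expect_identical(sort(amp$length),
                     sort(d$expected_products$length[
                       d$expected_products$allele == tp$allele_label]))
  }
})

test_that("indel designs under 20 bp respect the product cap across a batch", {
  worst <- 0L
  n_ok <- 0L
  for (i in 1:25) {
    rp <- random_locus_pair(seed = 3000 + i, length = 1000,
                            vtype = "deletion", vlen = sample(2:19, 1))
    d <- expect_design_or_failure(design_indel_marker(rp$donor, rp$truth))
    if (is.null(d)) next
    n_ok <- n_ok + 1L
    worst <- max(worst, max(d$expected_products$length))
  }
  expect_gt(n_ok, 15)
  expect_lte(worst, 120)
})

test_that("degenerate indel inputs are rejected", {
  rp <- random_locus_pair(seed = 8, length = 500, vtype = "SNP")
  expect_error(design_indel_marker(rp$donor, rp$truth), "not an indel")
})

test_that("tetra-primer design yields outer + allele band per homozygote", {
  rp <- random_locus_pair(seed = 11, length = 1200, vtype = "SNP",
                          position = 400)
  d <- design_tetra_primer(rp$donor, rp$truth)
  expect_length(d$primers, 4)
  inner <- Filter(function(p) !is.null(p$mismatch), d$primers)
  expect_length(inner, 2)
  expect_setequal(vapply(inner, function(p) p$strand, character(1)),
                  c("forward", "reverse"))
  ep <- d$expected_products
  outer <- max(ep$length)
  allele_bands <- tapply(ep$length, ep$allele, min)
  expect_gte(abs(diff(allele_bands)), 25)
  # each homozygous template yields exactly {outer, its allele band}
  for (tp in d$templates) {
    amp <- amplify(d$primers, tp)
    expect_identical(sort(amp$length),
                     sort(c(outer, allele_bands[[tp$allele_label]])))
  }
})

test_that("tetra-primer design fails near the sequence end", {
  set.seed(31)
  t <- locus("t", rand_seq(600))
  v <- variant(589, substr(t$sequence, 590, 590),
               setdiff(c("A", "C", "G", "T"),
                       substr(t$sequence, 590, 590))[1])
  expect_error(design_tetra_primer(t, v), class = "asm_design_failure")
})

test_that("separated allele-specific design amplifies only the matching allele", {
  rp <- random_locus_pair(seed = 3, length = 1200, vtype = "SNP",
                          position = 500)
  d <- design_separated_AS(rp$donor, rp$truth)
  expect_length(d$reactions, 2)
  shared <- intersect(d$reactions[[1]], d$reactions[[2]])
  expect_length(shared, 1)                 # two reactions share one primer
  pos_t <- d$templates[[1]]; neg_t <- d$templates[[2]]
  expect_identical(nrow(amplify(d$primers[d$reactions$positive], pos_t)), 1L)
  expect_identical(nrow(amplify(d$primers[d$reactions$positive], neg_t)), 0L)
  expect_identical(nrow(amplify(d$primers[d$reactions$non_target], neg_t)), 1L)
  expect_identical(nrow(amplify(d$primers[d$reactions$non_target], pos_t)), 0L)
})

test_that("tri-primer design keeps the reduced gap inside the window", {
  rp <- random_locus_pair(seed = 5, length = 2000, vtype = "insertion",
                          vlen = 400)
  d <- design_tri_primer(rp$donor, rp$truth)
  ep <- d$expected_products
  short_prod <- ep$length[ep$allele == d$positive_allele]
  long_bands <- sort(ep$length[ep$allele != d$positive_allele])
  inner <- long_bands[1]
  gap <- abs(short_prod - inner)
  expect_gte(gap, 25); expect_lte(gap, 150)
  # outer-pair difference still equals the indel length
  expect_identical(long_bands[2] - short_prod, 400L)
  small <- random_locus_pair(seed = 6, length = 1000, vtype = "insertion",
                             vlen = 30)
  expect_error(design_tri_primer(small$donor, small$truth),
               class = "asm_design_failure")
})

test_that("artificial mismatch insertion substitutes one base near the 3' end", {
  p <- primer("x", "CATACCTAGCGTTCTATGCAGA")
  q <- insert_artificial_mismatch(p, "A", offset = 3)
  expect_identical(q$mismatch$offset_from_3prime, 3L)
  # exactly one substitution; rest unchanged; terminal intact
  diffs <- which(strsplit(p$sequence, "")[[1]] != strsplit(q$sequence,
                                                           "")[[1]])
  expect_identical(diffs, nchar(p$sequence) - 2L)
  expect_identical(substr(q$display_sequence, diffs, diffs),
                   tolower(substr(q$sequence, diffs, diffs)))
  # the substituted base is the complement of the original (strong mispair)
  expect_identical(q$mismatch$base,
                   chartr("ACGT", "TGCA", q$mismatch$original_base))
  expect_error(insert_artificial_mismatch(q, "A"), "already")
  expect_error(insert_artificial_mismatch(p, "C"), "does not end")
})

test_that("packaged allele-specific primers carry the mismatch 2-4 nt from the 3' end", {
  tab <- read_primer_table(system.file("extdata", "table2_primers.tsv",
                                       package = "asmarker"))
  with_mm <- Filter(function(p) !is.null(p$mismatch), tab$primers)
  expect_gt(length(with_mm), 10)
  offs <- vapply(with_mm, function(p) p$mismatch$offset_from_3prime,
                 integer(1))
  expect_true(all(offs %in% 2:4))
})

test_that("fluorescent assay export emits a centered 501-nt context", {
  set.seed(12)
  for (len in c(501, 700, 1200)) {
    t <- locus("t", rand_seq(len))
    pos <- if (len == 501) 250L else sample(250:(len - 251), 1)
    ref <- substr(t$sequence, pos + 1, pos + 1)
    v <- variant(pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
    a <- export_fluorescent_assay(t, v)
    expect_identical(nchar(gsub("\\[./.\\]", "N", a$context)), 501L)
    expect_match(a$context, sprintf("\\[%s/%s\\]", v$ref, v$alt), perl = TRUE)
    expect_identical(a$hex_allele, v$ref)
    expect_identical(a$fam_allele, v$alt)
  }
  t <- locus("t", rand_seq(400))
  v <- variant(100, substr(t$sequence, 101, 101),
               setdiff(c("A", "C", "G", "T"), substr(t$sequence, 101, 101))[1])
  expect_error(export_fluorescent_assay(t, v), "250 bp")
})
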