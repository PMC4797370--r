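# Polymorphism scanning between donor and recipient alleles.

test_that("identical sequences yield no variants", {
  rp <- random_locus_pair(seed = 1, length = 1000)
  expect_identical(scan_pair(rp$donor, rp$donor), list())
})

test_that("a planted substitution is recovered at its exact offset", {
  set.seed(42)
  dseq <- rand_seq(2000)
  expect_identical(substr(dseq, 501, 501) != "", TRUE)
  d <- locus("donor", dseq)
  # force a G at offset 500 (0-based), recipient carries A
  substr(dseq, 501, 501) <- "G"
  d <- locus("donor", dseq)
  rseq <- dseq; substr(rseq, 501, 501) <- "A"
  r <- locus("recipient", rseq)
  vs <- scan_pair(d, r)
  # character-wise diff oracle on the ungapped pair
  diff_oracle <- which(strsplit(dseq, "")[[1]] != strsplit(rseq, "")[[1]]) - 1L
  expect_length(vs, length(diff_oracle))
  expect_identical(vs[[1]]$position, diff_oracle[1])
  expect_identical(vs[[1]]$vtype, "SNP")
  expect_identical(vs[[1]]$ref, "G")
  expect_identical(vs[[1]]$alt, "A")
})

test_that("a 16-bp deletion in the recipient is reported with its length", {
  rp <- random_locus_pair(seed = 16, length = 1500, vtype = "deletion",
                          vlen = 16)
  vs <- scan_pair(rp$donor, rp$recipient)
  expect_length(vs, 1)
  expect_identical(vs[[1]]$vtype, "deletion")
  expect_identical(vs[[1]]$length, 16L)
  expect_identical(vs[[1]]$position, rp$truth$position)
})

test_that("scan_pair round trip reconstructs the recipient and is symmetric", {
  specs <- expand.grid(vtype = c("SNP", "deletion", "insertion"),
                       vlen = c(1, 4, 12, 20, 70), stringsAsFactors = FALSE)
  specs <- specs[specs$vtype != "SNP" | specs$vlen == 1, ]
  seed <- 100
  for (i in seq_len(nrow(specs))) for (rep in 1:4) {
    seed <- seed + 1
    rp <- random_locus_pair(seed = seed, length = 800,
                            vtype = specs$vtype[i], vlen = specs$vlen[i])
    vs <- scan_pair(rp$donor, rp$recipient)
    rebuilt <- apply_variants(rp$donor, vs)
    expect_identical(rebuilt$sequence, rp$recipient$sequence)
    # left-normalization is idempotent
    for (v in vs) {
      expect_identical(
        asmarker:::variant_key(
          asmarker:::normalize_variant_left(v, rp$donor$sequence)),
        asmarker:::variant_key(v))
    }
    # symmetry up to allele swap: same types/lengths, ref/alt exchanged
    vs_swap <- scan_pair(rp$recipient, rp$donor)
    expect_length(vs_swap, length(vs))
    expect_setequal(
      vapply(vs_swap, function(v) paste(v$alt, v$ref), character(1)),
      vapply(vs, function(v) paste(v$ref, v$alt), character(1)))
  }
})

test_that("pre-aligned input is accepted and gap columns parsed", {
  vs <- scan_pair("ACGTAC--GTAC", "ACGTACGTGTAC", aligned = TRUE)
  expect_length(vs, 1)
  expect_identical(vs[[1]]$vtype, "insertion")
  expect_identical(vs[[1]]$alt, "GT")
  expect_error(scan_pair("ACGT", "ACG", aligned = TRUE), "equal length")
})

test_that("alphabet violations are rejected", {
  expect_error(scan_pair("ACGT", "ACXT"), "invalid")
})

test_that("donor-specific flagging equals the set-intersection oracle", {
  # 5 variants planted on the donor; 2 appear against every recipient
  set.seed(17)
  dseq <- rand_seq(1500)
  donor <- locus("donor", dseq)
  mk <- function(positions) {
    vs <- lapply(positions, function(p) {
      ref <- substr(dseq, p + 1, p + 1)
      variant(p, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
    })
    apply_variants(donor, vs, id = "r", allele_label = "r")
  }
  universal <- c(200L, 900L)
  private <- c(400L, 600L, 1200L)
  recips <- list(r1 = mk(c(universal, private[1])),
                 r2 = mk(c(universal, private[2])),
                 r3 = mk(c(universal, private[3])))
  per_rec <- lapply(recips, function(r) scan_pair(donor, r))
  marked <- mark_donor_specific(per_rec)
  flagged <- vapply(marked, `[[`, logical(1), "donor_specific")
  pos <- vapply(marked, `[[`, integer(1), "position")
  expect_identical(sort(pos[flagged]), universal)
  expect_identical(sum(!flagged), 3L)
  expect_error(mark_donor_specific(list()), "at least one")
})

test_that("strategy recommendation follows the indel/SNP thresholds", {
  big <- variant(10, paste(rep("A", 625), collapse = ""), "")
  expect_identical(recommend_strategy(big)$strategy, "large_indel_tri_primer")
  small <- variant(10, "ACGT", "")
  s <- recommend_strategy(small)
  expect_identical(s$strategy, "small_indel")
  expect_identical(s$product_cap, 120L)
  mid <- variant(10, paste(rep("A", 70), collapse = ""), "")
  m <- recommend_strategy(mid)
  expect_identical(m$strategy, "small_indel")
  expect_true(is.na(m$product_cap))
  snp <- variant(10, "C", "T")
  st <- recommend_strategy(snp)
  expect_identical(st$strategy, "snp_tetra_primer")
  expect_identical(st$alternatives, "snp_separated_AS")
})

test_that("variant construction enforces its invariants", {
  expect_error(variant(0, "A", "A"), "identical")
  expect_error(variant(0, "", ""), "empty")
  expect_error(variant(0, "AC", "G"), "pure")
  expect_error(variant(0, "ACG", "TGA"), "equal length")
})
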