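# Synthetic fixture reconstruction.

fxs <- build_paper_fixtures()

test_that("all 14 packaged markers reconstruct", {
  expect_identical(names(fxs), paper_marker_names())
  expect_true(all(vapply(fxs, inherits, logical(1), "asm_marker_fixture")))
})

test_that("DEP1 fixture templates differ by exactly 625 bp", {
  fx <- fxs[["DEP1-indel1P"]]
  lens <- vapply(fx$templates, function(t) nchar(t$sequence), integer(1))
  expect_identical(abs(diff(lens))[[1]], 625L)
  expect_identical(fx$variant$length, 625L)
})

test_that("printed product sizes are reproduced by in-silico PCR", {
  sizes <- function(fx, allele) {
    sort(amplify(fx$primers, fx$templates[[allele]])$length)
  }
  expect_identical(sizes(fxs[["Gn1a-indel1"]], "Habataki"), 99L)
  expect_identical(sizes(fxs[["Gn1a-indel1"]], "non-target"), 115L)
  expect_identical(sizes(fxs[["SCM2-indel1"]], "Habataki"), 117L)
  expect_identical(sizes(fxs[["SCM2-indel1"]], "non-target"), 105L)
  expect_identical(sizes(fxs[["DEP1-indel1P"]], "Osmancik-97"), 406L)
  expect_identical(sizes(fxs[["DEP1-indel1P"]], "non-target"),
                   c(310L, 1031L))
  expect_identical(sizes(fxs[["GS5-indel1"]], "MG"), 63L)
  expect_identical(sizes(fxs[["GS5-indel1"]], "WG/NG"), 67L)
  expect_identical(sizes(fxs[["GS5-03SNP"]], "WG"), c(257L, 499L))
  expect_identical(sizes(fxs[["GS5-03SNP"]], "non-WG"), c(291L, 499L))
})

test_that("templates differ only at the annotated variant for SNP fixtures", {
  for (m in c("Gn1a-17SNP", "SPL14-04SNP", "Ghd7-05SNP", "SPIKE-01SNP",
              "SPIKE-03SNP", "GS5-03SNP")) {
    fx <- fxs[[m]]
    a <- strsplit(fx$templates[[1]]$sequence, "")[[1]]
    b <- strsplit(fx$templates[[2]]$sequence, "")[[1]]
    expect_identical(length(a), length(b))
    expect_identical(sum(a != b), 1L)
  }
})

test_that("fixture building is deterministic in its seed", {
  a <- build_paper_fixtures("Gn1a-indel1", seed = 123)
  b <- build_paper_fixtures("Gn1a-indel1", seed = 123)
  c <- build_paper_fixtures("Gn1a-indel1", seed = 124)
  expect_identical(a[[1]]$templates[[1]]$sequence,
                   b[[1]]$templates[[1]]$sequence)
  expect_false(identical(a[[1]]$templates[[1]]$sequence,
                         c[[1]]$templates[[1]]$sequence))
})

test_that("no primer binds a fixture template outside its intended site", {
  for (fx in fxs) {
    labels <- names(fx$templates)
    for (p in fx$primers) {
      for (lab in labels) {
        n <- nrow(find_binding_sites(p, fx$templates[[lab]]))
        expect_lte(n, 1L)
      }
      # every primer binds at least one template
      expect_gte(sum(vapply(labels, function(lab)
        nrow(find_binding_sites(p, fx$templates[[lab]])), integer(1))), 1L)
    }
  }
})

test_that("allele-specific fixture primers are blocked on the wrong allele", {
  for (fx in fxs) {
    as_primers <- Filter(function(p)
      p$role %in% c("positive_allele", "non_target_allele"), fx$primers)
    for (p in as_primers) {
      counts <- vapply(fx$templates, function(t)
        nrow(find_binding_sites(p, t)), integer(1))
      expect_identical(sort(unname(counts)), c(0L, 1L))
      match_lab <- names(counts)[counts == 1L]
      if (p$role == "positive_allele") {
        expect_identical(match_lab, fx$positive_allele)
      } else {
        expect_false(identical(match_lab, fx$positive_allele))
      }
    }
  }
})

test_that("random locus pairs are reproducible and respect their spec", {
  a <- random_locus_pair(seed = 42, length = 600, vtype = "SNP")
  b <- random_locus_pair(seed = 42, length = 600, vtype = "SNP")
  expect_identical(a$donor$sequence, b$donor$sequence)
  expect_identical(asmarker:::variant_key(a$truth),
                   asmarker:::variant_key(b$truth))
  vs <- scan_pair(a$donor, a$recipient)
  expect_length(vs, 1)
  expect_identical(asmarker:::variant_key(vs[[1]]),
                   asmarker:::variant_key(a$truth))
  expect_error(random_locus_pair(seed = 1, length = 100), ">= 200")
  expect_error(random_locus_pair(seed = 1, length = 300, vtype = "insertion",
                                 vlen = 200), "larger than")
})
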