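# In-silico PCR: binding-site search, amplification, heterozygote mixing.

test_that("an exact substring match is a single zero-mismatch site", {
  set.seed(2)
  tmpl <- locus("t", rand_seq(500))
  p <- primer("p", substr(tmpl$sequence, 101, 120))
  sites <- find_binding_sites(p, tmpl)
  plus <- sites[sites$strand == "+", ]
  expect_true(any(plus$start == 101 & plus$n_mismatch == 0))
})

test_that("ARMS blocking: terminal mismatch blocks, engineered mismatch does not", {
  set.seed(3)
  base <- rand_seq(300)
  tA <- base; substr(tA, 200, 200) <- "A"
  tG <- base; substr(tG, 200, 200) <- "G"
  p_raw <- primer("as", paste0(substr(base, 181, 199), "A"))
  p <- insert_artificial_mismatch(p_raw, "A", offset = 2)
  sA <- find_binding_sites(p, locus("tA", tA))
  sG <- find_binding_sites(p, locus("tG", tG))
  sA <- sA[sA$start == 181 & sA$strand == "+", ]
  expect_identical(nrow(sA), 1L)          # one (engineered) mismatch allowed
  expect_identical(sA$n_mismatch, 1L)
  expect_false(any(sG$start == 181 & sG$strand == "+"))  # terminal mismatch
})

test_that("binding-site search equals the brute-force oracle on random pairs", {
  set.seed(13)
  tmpl <- rand_seq(3000)
  tl <- locus("t", tmpl)
  for (i in 1:50) {
    # half the primers are template-derived with planted noise so that
    # near-matches actually occur; half are fully random
    pseq <- if (i %% 2 == 0) {
      s <- sample(2970, 1)
      sub <- substr(tmpl, s, s + 19)
      k <- sample(0:3, 1)
      if (k > 0) for (j in sample(19, k)) {
        substr(sub, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(sub, j, j)), 1)
      }
      sub
    } else rand_seq(20)
    got <- site_keys(find_binding_sites(primer("p", pseq), tl))
    expect_identical(got, oracle_sites(pseq, tmpl))
  }
})

test_that("loosening the mismatch model never removes a binding site", {
  set.seed(23)
  tmpl <- locus("t", rand_seq(2000))
  for (i in 1:10) {
    s <- sample(1950, 1)
    pseq <- substr(tmpl$sequence, s, s + 21)
    for (j in sample(22, 2)) {
      substr(pseq, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(pseq, j, j)), 1)
    }
    p <- primer("p", pseq)
    tight <- site_keys(find_binding_sites(p, tmpl))
    loose <- site_keys(find_binding_sites(
      p, tmpl, mismatch_model(max_mm_window = 2L, max_mm_total = 5L)))
    expect_true(all(tight %in% loose))
  }
})

test_that("amplify computes product length by coordinate arithmetic", {
  set.seed(9)
  bg <- rand_seq(800)
  f <- rand_seq(20)
  r_site <- rand_seq(22)
  d <- 400L  # distance between forward site start and reverse site start
  tmpl <- paste0(substr(bg, 1, 100), f,
                 substr(bg, 121, 100 + d), r_site,
                 substr(bg, 101 + d + 22, 800))
  fwd <- primer("f", f)
  rev <- primer("r", chartr("ACGT", "TGCA",
                            paste(rev(strsplit(r_site, "")[[1]]),
                                  collapse = "")))
  amp <- amplify(list(fwd, rev), locus("t", tmpl))
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, d + 22L)   # oracle: site distance + primer len
})

test_that("two same-orientation primers give no product", {
  set.seed(4)
  tmpl <- locus("t", rand_seq(400))
  f1 <- primer("f1", substr(tmpl$sequence, 51, 70))
  f2 <- primer("f2", substr(tmpl$sequence, 201, 220))
  amp <- amplify(list(f1, f2), tmpl)
  expect_identical(nrow(amp), 0L)
})

test_that("amplify is invariant to primer and template order", {
  fx <- build_paper_fixtures("DEP1-indel1P")[[1]]
  prs <- fx$primers
  a1 <- amplify(prs, fx$templates)
  a2 <- amplify(rev(prs), rev(fx$templates))
  cols <- c("template", "forward", "reverse", "length")
  expect_identical(a1[, cols], a2[, cols])
})

test_that("amplifying the reverse-complemented template preserves lengths", {
  fx <- build_paper_fixtures("Gn1a-indel1")[[1]]
  for (tp in fx$templates) {
    rc <- locus(tp$id, asmarker:::seq_revcomp(tp$sequence), tp$allele_label)
    expect_identical(sort(amplify(fx$primers, tp)$length),
                     sort(amplify(fx$primers, rc)$length))
  }
})

test_that("heterozygote of identical amplicon sets adds no bands and no flag", {
  fx <- build_paper_fixtures("Gn1a-indel1")[[1]]
  a <- amplify(fx$primers, fx$templates[[1]])
  het <- simulate_heterozygote(a, a)
  expect_false(het$imbalance)
  expect_identical(sort(unique(het$amplicons$length)), sort(unique(a$length)))
})

test_that("efficiency decays with product length within a reaction", {
  fx <- build_paper_fixtures("DEP1-indel1P")[[1]]
  amp <- amplify(fx$primers, fx$templates[["non-target"]])
  expect_identical(sort(amp$length), c(310L, 1031L))
  e <- amp$efficiency[order(amp$length)]
  expect_equal(e[1], 1)
  expect_equal(e[2], exp(-0.002 * (1031 - 310)), tolerance = 1e-9)
})
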