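# Virtual electrophoresis and genotype calling.

test_that("band merging follows each system's resolvable gap", {
  # 63/67 bp co-migrate on agarose but split on capillary
  expect_identical(nrow(resolve_bands(c(63, 67), "agarose_4")), 1L)
  expect_identical(nrow(resolve_bands(c(63, 67), "capillary")), 2L)
  expect_identical(nrow(resolve_bands(c(63, 67), "page_8")), 2L)
  # 117/105 split on 4% agarose
  expect_identical(nrow(resolve_bands(c(117, 105), "agarose_4")), 2L)
  # a single amplicon is a single band everywhere
  for (g in names(gel_models())) {
    expect_identical(nrow(resolve_bands(250, g)), 1L)
  }
})

test_that("weak products fall below the display floor; over-length flagged", {
  amp <- data.frame(length = c(300, 900), efficiency = c(1, 0.01))
  b <- resolve_bands(amp, "agarose_2.5")
  expect_identical(nrow(b), 1L)
  expect_identical(b$length, 300)
  expect_warning(b2 <- resolve_bands(c(100, 500), "agarose_4"), "unresolved")
  expect_false(all(b2$resolved))
})

test_that("gel recommendation reproduces the per-marker assignments", {
  fxs <- build_paper_fixtures(c("Gn1a-indel1", "SCM2-indel1", "SPIKE-indel3",
                                "DEP1-indel1P", "GS5-03SNP", "GS5-indel1",
                                "Gn1a-indel3"))
  rec <- vapply(fxs, function(fx) recommend_gel(fx)$id, character(1))
  expect_identical(rec[["Gn1a-indel1"]], "agarose_4")
  expect_identical(rec[["SCM2-indel1"]], "agarose_4")
  expect_identical(rec[["SPIKE-indel3"]], "agarose_4")
  expect_identical(rec[["DEP1-indel1P"]], "agarose_2.5")
  expect_identical(rec[["GS5-03SNP"]], "agarose_2.5")
  expect_true(rec[["GS5-indel1"]] %in% c("page_8", "capillary"))
  expect_identical(rec[["Gn1a-indel3"]], "agarose_2.5")
})

test_that("genotype calls cover PP/NN/PN and the invalid states", {
  fx <- build_paper_fixtures("GS5-03SNP")[[1]]
  ep <- fx$expected_products
  outer <- max(ep$length)
  pos_band <- min(ep$length[ep$allele == "WG"])
  neg_band <- min(ep$length[ep$allele == "non-WG"])
  expect_identical(call_genotype(c(outer, pos_band, neg_band), fx)$call, "PN")
  expect_identical(call_genotype(c(outer, pos_band), fx)$call, "PP")
  expect_identical(call_genotype(c(outer, neg_band), fx)$call, "NN")
  expect_identical(call_genotype(numeric(0), fx)$call, "invalid")
  # missing common outer band invalidates a tetra-primer call
  expect_identical(call_genotype(c(pos_band), fx)$call, "invalid")
  # a band matching nothing is diagnosed
  g <- call_genotype(c(outer, pos_band, 1500), fx)
  expect_identical(g$call, "invalid")
  expect_match(g$note, "unexpected")
})

test_that("calls are refined, never contradicted, as gel resolution improves", {
  fx <- build_paper_fixtures("GS5-indel1")[[1]]
  # on coarse agarose the 63/67 pair co-migrates: heterozygote is uncallable
  coarse <- call_genotype(simulate_bands(fx, "PN", g = "agarose_4"),
                          fx, g = "agarose_4")
  fine <- call_genotype(simulate_bands(fx, "PN", g = "capillary"),
                        fx, g = "capillary")
  expect_identical(coarse$call, "invalid")
  expect_identical(fine$call, "PN")
})

test_that("200 simulated samples of known genotype are all called correctly", {
  fxs <- build_paper_fixtures()
  set.seed(21)
  genotypes <- sample(c("PP", "NN", "PN"), 200, replace = TRUE)
  markers <- sample(names(fxs), 200, replace = TRUE)
  for (i in seq_along(genotypes)) {
    fx <- fxs[[markers[i]]]
    obs <- simulate_bands(fx, genotypes[i])
    expect_identical(call_genotype(obs, fx)$call, genotypes[i])
  }
})
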