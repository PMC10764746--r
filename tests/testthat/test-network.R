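test_that("background-effect deltas equal the linking epistasis terms", {
  tm <- randomTruth(31)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  et <- fitAndDecompose(tm, cat65, seed = 6)
  be <- effectInBackground(et, "Ehd1-1", "Hd3a-2")
  expect_equal(be$delta, be$effectInBackground - be$baseline, tolerance = 1e-9)
  expect_equal(be$delta, tm@dualE[["Ehd1-1/Hd3a-2"]], tolerance = 1e-9)
  # an order-2 background adds the dual terms to both loci plus the triple
  be2 <- effectInBackground(et, "Hd1-1", "Ehd1-1/Hd3a-2")
  want <- tm@dualE[["Ehd1-1/Hd1-1"]] + tm@dualE[["Hd3a-2/Hd1-1"]] +
    tm@tripleE[["Ehd1-1/Hd3a-2/Hd1-1"]]
  expect_equal(be2$delta, want, tolerance = 1e-9)
  expect_error(effectInBackground(et, "Hd3a-1", "Hd3a-2"), "already substituted")
})

test_that("zero epistasis truth yields an all-independent network", {
  tm <- TruthModel(c("A", "B"), a = c(A = 5, B = -4), d = c(A = 3, B = 2))
  cat13 <- enumerateMaterials(c("A", "B"), 2)
  et <- fitAndDecompose(tm, cat13, seed = 8)
  net <- buildNetwork(et)
  expect_true(all(net$relation == "independent"))
})

test_that("planted epistasis signs drive the promote/inhibit classification", {
  # positive epistasis pushes the positive-effect focal A further from the
  # recipient -> promoted; the same terms pull the negative-effect focal B
  # back toward zero -> inhibited
  dualE <- c("A-1/B-1" = 5, "A-1/B-2" = 5, "A-2/B-1" = 5, "A-2/B-2" = 5)
  tm <- TruthModel(c("A", "B"), a = c(A = 6, B = -8), d = c(A = 4, B = -6),
                   dualE = dualE, residSd = 1, blockSd = 0.5)
  cat13 <- enumerateMaterials(c("A", "B"), 2)
  et <- fitAndDecompose(tm, cat13, seed = 9)
  net <- buildNetwork(et)
  edge <- function(s, t) net$relation[net$source == s & net$target == t]
  expect_identical(edge("B", "A"), "promotes")
  expect_identical(edge("A", "B"), "inhibits")
  detail <- net$detail[net$source == "B" & net$target == "A"]
  expect_match(detail, "A-1:promotes")
  expect_match(detail, "A-2:promotes")
  # opposite-state responses are reported per state and tie to "ambiguous"
  dualMix <- c("A-1/B-1" = 5, "A-1/B-2" = 5, "A-2/B-1" = -5, "A-2/B-2" = -5)
  tmMix <- TruthModel(c("A", "B"), a = c(A = 6, B = 8), d = c(A = 4, B = 6),
                      dualE = dualMix, residSd = 1, blockSd = 0.5)
  etMix <- fitAndDecompose(tmMix, cat13, seed = 19)
  netMix <- buildNetwork(etMix)
  expect_identical(netMix$relation[netMix$source == "B" & netMix$target == "A"],
                   "ambiguous")
  dMix <- netMix$detail[netMix$source == "B" & netMix$target == "A"]
  expect_match(dMix, "A-1:promotes")
  expect_match(dMix, "A-2:inhibits")
})

test_that("network classification is a pure function of the table", {
  tm <- randomTruth(61, noise = TRUE)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  et <- fitAndDecompose(tm, cat65, seed = 10)
  n1 <- buildNetwork(et)
  n2 <- buildNetwork(et)
  expect_identical(n1, n2)
})

test_that("the study-like preset leaves Hd1 and Ehd1 independent", {
  tm <- hdTruthPreset()
  cat65 <- enumerateMaterials(hdLoci(), 3)
  et <- fitAndDecompose(tm, cat65, seed = 12)
  net <- buildNetwork(et)
  expect_identical(net$relation[net$source == "Hd1" & net$target == "Ehd1"],
                   "independent")
  expect_identical(net$relation[net$source == "Ehd1" & net$target == "Hd1"],
                   "independent")
  # Hd3a and Hd1 interact strongly in the preset: an edge is called
  expect_false(net$relation[net$source == "Hd3a" & net$target == "Hd1"] ==
               "independent")
})
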