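test_that("sanitization policies handle non-standard residues", {
  expect_identical(sanitizeSequence("acdE", "strict"), "ACDE")
  expect_identical(sanitizeSequence("AXC", "drop"), "AC")
  expect_error(sanitizeSequence("AXB", "strict"), "non-standard residue 'X'")
  expect_identical(sanitizeSequence("ABZUX", "impute"), "ANQC")
  expect_identical(sanitizeSequence("a c d-*e\n", "drop"), "ACDE")
  expect_error(sanitizeSequence("XX", "drop"), "empty")
  expect_error(sanitizeSequence("", "strict"), "non-empty")
})

test_that("composition is a normalized 20-vector", {
  fr <- composition("AAAA")
  expect_equal(unname(fr["A"]), 1)
  expect_equal(sum(fr), 1)
  expect_equal(unname(composition("ARND")[c("A", "R", "N", "D")]),
               rep(0.25, 4))
  set.seed(3)
  for (i in 1:10)
    expect_equal(sum(composition(randomSeq(sample(5:300, 1)))), 1,
                 tolerance = 1e-12)
})

test_that("charge counts follow the D/E and K/R convention", {
  expect_equal(unname(chargeCounts("DDEE")), c(4, 0))
  expect_equal(unname(chargeCounts("KKRR")), c(0, 4))
  expect_equal(unname(chargeCounts("GGGG")), c(0, 0))
  expect_equal(unname(chargeCounts("HHHH")), c(0, 0))  # His excluded
})

test_that("molecular weight obeys the peptide-bond identity", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecularWeight("GG"), 2 * molecularWeight("G") - 18.0153,
               tolerance = 1e-6)
  set.seed(4)
  a <- randomSeq(30); b <- randomSeq(45)
  expect_equal(molecularWeight(paste0(a, b)),
               molecularWeight(a) + molecularWeight(b) - 18.0153,
               tolerance = 1e-6)
  ## independent oracle value (biopython ProtParam), tables differ by < 0.05 Da
  expect_equal(molecularWeight("ACDEFGHIKLMNPQRSTVWY"), 2395.7134,
               tolerance = 0.05)
})

test_that("atom counts match the molecular formulas", {
  expect_equal(unname(atomCounts("G")), c(2L, 5L, 1L, 2L, 0L))  # glycine C2H5NO2
  expect_equal(atomCounts("C")[["S"]], 1L)                      # cysteine
  g2 <- atomCounts("GG")
  expect_equal(unname(g2), unname(2L * atomCounts("G") - c(0L, 2L, 0L, 1L, 0L)))
  set.seed(5)
  s <- randomSeq(60)
  expect_true(all(atomCounts(s) >= 0))
})

test_that("theoretical pI is the root of the net-charge curve", {
  set.seed(6)
  for (i in 1:5) {
    s <- randomSeq(sample(10:120, 1))
    expect_lt(abs(ProtStress:::netCharge(s, theoreticalPi(s))), 1e-4)
  }
  expect_lt(theoreticalPi("DDDDDD"), theoreticalPi("KKKKKK"))
  ## regression fixtures under the EMBOSS pKa set
  expect_equal(theoreticalPi("A"), 6.097656, tolerance = 1e-3)
  expect_equal(theoreticalPi("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
               10.62411, tolerance = 1e-3)
})

test_that("instability index reproduces the dipeptide-weight formula", {
  expect_equal(instabilityIndex("GG"), 66.7)   # 5 * DIWV(G, G) = 5 * 13.34
  n <- 12
  expect_equal(instabilityIndex(strrep("W", n)),
               10 * ((n - 1) / n) * 1)          # DIWV(W, W) = 1
  ## frozen biopython ProtParam values (same published table)
  expect_equal(instabilityIndex("ACDEFGHIKLMNPQRSTVWY"), 84.74,
               tolerance = 1e-6)
  expect_equal(instabilityIndex("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
               53.5485, tolerance = 1e-4)
  expect_error(instabilityIndex("G"), "length")
})

test_that("aliphatic index weights A, V, I, L as defined", {
  expect_equal(aliphaticIndex("AAAA"), 100)
  expect_equal(aliphaticIndex("VVVV"), 290)
  expect_equal(aliphaticIndex("GGGG"), 0)
  expect_equal(aliphaticIndex("AVIL"), 25 + 2.9 * 25 + 3.9 * 50)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("A"), 1.8)
  expect_equal(gravy("AILV"), 3.575)
  set.seed(7)
  for (i in 1:5) {
    g <- gravy(randomSeq(sample(5:200, 1)))
    expect_gte(g, -4.5); expect_lte(g, 4.5)
  }
})

test_that("PTM motif counts are deterministic and internally consistent", {
  z <- ptmMotifCounts("GGGAGGG")  # no C, Y, K
  expect_true(all(z == 0))
  expect_length(z, 12L)
  ## planted SUMO-I site in a motif-free background
  v <- ptmMotifCounts("GGGGGLKHEGGGGG")
  expect_equal(unname(v["sumoylation_I"]), 1)
  expect_equal(unname(v["sumoylation_total"]), 1)
  expect_equal(unname(v["nitrosylation_total"]), 0)
  set.seed(8)
  for (i in 1:10) {
    v <- ptmMotifCounts(randomSeq(sample(20:200, 1)))
    expect_equal(unname(v["nitrosylation_total"]),
                 sum(v[c("nitrosylation_A", "nitrosylation_B", "nitrosylation_C")]))
    expect_equal(unname(v["nitrotyrosine_total"]),
                 sum(v[c("nitrotyrosine_A", "nitrotyrosine_B", "nitrotyrosine_C")]))
    expect_equal(unname(v["sumoylation_total"]),
                 sum(v[c("sumoylation_I", "sumoylation_II", "sumoylation_III")]))
    expect_true(all(v >= 0))
  }
})

test_that("coiled-coil score detects heptad repeats and ignores noise", {
  expect_equal(coiledCoilScore("LEALEGK"), 0)           # shorter than window
  expect_equal(coiledCoilScore(strrep("G", 100)), 0)
  expect_gt(coiledCoilScore(strrep("LEALEGK", 8)), 0)   # ideal heptad
})

test_that("the feature vector has exactly 46 named values in schema order", {
  schema <- defaultFeatureSchema()
  set.seed(9)
  for (s in c("ACDEFGHIKLMNPQRSTVWY", randomSeq(80), randomSeq(150))) {
    v <- extractFeatures(s, schema)
    expect_length(v, 46L)
    expect_identical(names(v), featureNames(schema))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-12)
  }
  s <- randomSeq(60)
  expect_identical(extractFeatures(s), extractFeatures(s))
  expect_error(extractFeatures("AXB"), "sanitize")
})

test_that("permutation sensitivity is confined to order-dependent features", {
  set.seed(10)
  s <- randomSeq(100)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  a <- extractFeatures(s); b <- extractFeatures(perm)
  inv <- c(paste0("comp_", strsplit("ARNDCQEGHILKMFPTSWYV", "")[[1]]),
           "length", "n_negative", "n_positive", "molecular_weight",
           "theoretical_pI", "n_C", "n_H", "n_N", "n_O", "n_S",
           "aliphatic_index", "gravy")
  expect_equal(a[inv], b[inv], tolerance = 1e-9)
  ## order-dependent: the dipeptide statistic must differ for a designed pair
  expect_false(isTRUE(all.equal(instabilityIndex("GW"), instabilityIndex("WG"))))
  expect_false(isTRUE(all.equal(
    unname(ptmMotifCounts("GLKHEG")["sumoylation_I"]),
    unname(ptmMotifCounts("GEHKLG")["sumoylation_I"]))))
})

test_that("feature tables carry ids and schema-stable column names", {
  schema <- defaultFeatureSchema()
  seqs <- c(p1 = "ACDEFGHIKLMNPQRSTVWY", p2 = "GGGGGLKHEGGGGG")
  X <- featureTable(seqs, schema)
  expect_equal(dim(X), c(2L, 46L))
  expect_identical(rownames(X), c("p1", "p2"))
  expect_identical(colnames(X), featureNames(schema))
})

test_that("schema hash is stable and sensitive to definitions", {
  s1 <- defaultFeatureSchema()
  expect_identical(schemaHash(s1), schemaHash(defaultFeatureSchema()))
  s2 <- s1
  s2@ccThreshold <- 0.9
  expect_false(identical(schemaHash(s1), schemaHash(s2)))
})
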