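# Composition parsing and canonical serialization.

test_that("all shorthand styles of one composition parse identically", {
  styles <- list(
    c("H5N4F1A2", "Hex5HexNAc4Fuc1Neu5Ac2", "Hex5HexNAc4dHex1Neu5Ac2"),
    c("H3N2", "Hex3HexNAc2", "(Hex)3(HexNAc)2"),
    c("H5N4", "Hex5HexNAc4"),
    c("H4N3F2", "Hex4HexNAc3Fuc2", "Hex4HexNAc3dHex2"),
    c("H2N2G1", "Hex2HexNAc2Neu5Gc1", "Hex2HexNAc2NeuGc1"),
    c("H6N5A3", "Hex6HexNAc5NeuAc3"),
    c("H1N1", "Hex1HexNAc1", "(Hex)1 (HexNAc)1"),
    c("H3N4F1", "Hex3HexNAc4Fuc1"),
    c("H7N6A4F1", "Hex7HexNAc6Neu5Ac4dHex1"),
    c("H5N4A1G1", "Hex5HexNAc4Neu5Ac1Neu5Gc1"),
    c("H2N2X1", "Hex2HexNAc2Pen1", "Hex2HexNAc2Xyl1"),
    c("H5N2", "Hex5HexNAc2", "(Man)5(GlcNAc)2"),
    c("H3N3K1", "Hex3HexNAc3Kdn1"),
    c("H1N1P1", "Hex1HexNAc1Phos1"),
    c("H2N1Me2", "Hex2HexNAc1Me2"))
  for (st in styles) {
    ref <- parse_composition(st[1])
    for (v in st[-1]) {
      expect_identical(parse_composition(v)$counts, ref$counts,
                       label = paste(st[1], "vs", v))
    }
  }
})

test_that("the printed equivalence and appendix cases hold", {
  expect_identical(parse_composition("H5N4F1A2")$counts,
                   parse_composition("Hex5HexNAc4Fuc1Neu5Ac2")$counts)
  appendix <- parse_composition("(Hex)3 (HexNAc)1 (NeuAc)1 + (Man)3(GlcNAc)2")
  expect_identical(appendix$counts,
                   c(Hex = 6L, HexNAc = 3L, Neu5Ac = 1L))
  expect_identical(parse_composition("H1")$counts, c(Hex = 1L))
})

test_that("the S letter resolves by context", {
  expect_identical(parse_composition("H5N4S2")$counts[["Neu5Ac"]], 2L)
  expect_identical(parse_composition("Hex2S1")$counts[["S"]], 1L)
})

test_that("serialization uses the fixed class order and round-trips", {
  expect_identical(
    composition_to_string(glycan_composition(
      c(dHex = 1L, Neu5Ac = 2L, Hex = 5L, HexNAc = 4L))),
    "Hex5HexNAc4dHex1Neu5Ac2")
  expect_identical(composition_to_string(glycan_composition(c(Hex = 1L))),
                   "Hex1")
  expect_error(glycan_composition(integer(0)), "empty")
  set.seed(31)
  classes <- composition_classes()
  for (i in 1:50) {
    n <- sample(1:5, 1L)
    cls <- sample(classes, n)
    cts <- stats::setNames(sample(1:9, n, replace = TRUE), cls)
    c0 <- glycan_composition(cts)
    expect_identical(parse_composition(composition_to_string(c0))$counts,
                     c0$counts)
  }
})

test_that("serialization is injective (brute force, counts <= 3)", {
  classes <- c("Hex", "HexNAc", "dHex", "Neu5Ac")
  seen <- character(0)
  grid <- expand.grid(h = 0:3, n = 0:3, f = 0:3, a = 0:3)
  for (r in seq_len(nrow(grid))) {
    cts <- stats::setNames(as.integer(grid[r, ]), classes)
    if (sum(cts) == 0L) next
    s <- composition_to_string(glycan_composition(cts))
    expect_false(s %in% seen)
    seen <- c(seen, s)
  }
})

test_that("detect_composition separates sequences from compositions", {
  expect_true(detect_composition("H5N4F1A2"))
  expect_true(detect_composition("Hex5HexNAc4"))
  expect_false(detect_composition("Gal(b1-4)Glc"))
  expect_false(detect_composition("Man"))
  expect_false(detect_composition("Galb4Glc"))
  expect_error(parse_composition("H5N4junk"), "junk")
})
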