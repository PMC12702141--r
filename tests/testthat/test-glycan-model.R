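# Core tree model: IUPAC parsing, serialization, chain lengths.

test_that("namespace table covers the documented defaults", {
  tab <- monosaccharide_table()
  expect_gte(nrow(tab), 40L)
  expect_false(anyDuplicated(tab$base) > 0)
  expect_identical(tab$enantiomer[tab$base == "Fuc"], "L")
  expect_identical(tab$enantiomer[tab$base == "Rha"], "L")
  expect_identical(tab$enantiomer[tab$base == "Ara"], "L")
  expect_identical(tab$enantiomer[tab$base == "IdoA"], "L")
  expect_identical(tab$enantiomer[tab$base == "Gal"], "D")
  expect_true(all(tab$ring == "p"))
  expect_identical(default_donor("Neu5Ac"), 2L)
  expect_identical(default_donor("Kdn"), 2L)
  expect_identical(default_donor("Gal"), 1L)
})

test_that("parse_iupac_to_tree handles the reference structures", {
  t <- parse_iupac_to_tree("Gal(b1-4)Glc")
  expect_length(t$nodes, 2L)
  expect_identical(t$nodes[[t$root]]$base, "Glc")
  gal <- t$children[[t$root]][1]
  expect_identical(t$nodes[[gal]]$base, "Gal")
  expect_identical(t$links[[gal]]$anomer, "b")
  expect_identical(t$links[[gal]]$donor, 1L)
  expect_identical(t$links[[gal]]$acceptors, 4L)

  t1 <- parse_iupac_to_tree("Glc")
  expect_length(t1$nodes, 1L)
  expect_length(t1$children[[1]], 0L)

  tf <- parse_iupac_to_tree("{Neu5Ac(a2-?)}Gal(b1-4)Glc")
  expect_length(tf$floating, 1L)
  expect_identical(tf$floating[[1]]$tree$nodes[[1]]$base, "Neu5Ac")
  expect_true(is.na(tf$floating[[1]]$link$acceptors))
  expect_identical(tree_to_string(tf), "{Neu5Ac(a2-?)}Gal(b1-4)Glc")
})

test_that("serialization preserves sibling order verbatim", {
  s1 <- "Man(a1-6)[Man(a1-3)]Man"
  s2 <- "Man(a1-3)[Man(a1-6)]Man"
  expect_identical(tree_to_string(parse_iupac_to_tree(s1)), s1)
  expect_identical(tree_to_string(parse_iupac_to_tree(s2)), s2)
})

test_that("parse errors name the offending index or token", {
  expect_error(parse_iupac_to_tree("Gal(b1-4Glc"), "unbalanced")
  expect_error(parse_iupac_to_tree("Gal)b1-4(Glc"), "index 4")
  expect_error(parse_iupac_to_tree(""), "empty")
  expect_error(common_stem("Frobnose(b1-4)Glc"), "Frobnose")
})

test_that("longest_chain_length counts monosaccharide nodes only", {
  t <- parse_iupac_to_tree("Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal")
  expect_identical(longest_chain_length(t), 3L)
  lac <- parse_iupac_to_tree("Gal(b1-4)Glc")
  expect_identical(longest_chain_length(lac), 2L)
  leaf <- lac$children[[lac$root]][1]
  expect_identical(longest_chain_length(lac, leaf), 1L)
  # brute-force oracle: enumerate all root-to-leaf paths
  brute <- function(t, node) {
    kids <- t$children[[node]]
    if (!length(kids)) return(1L)
    1L + max(vapply(kids, function(k) brute(t, k), integer(1)))
  }
  set.seed(11)
  for (i in 1:25) {
    t <- random_glycan_tree(sample(2:12, 1L))
    expect_identical(longest_chain_length(t), brute(t, t$root))
  }
})

test_that("tree <-> string round-trip is the identity on serializations", {
  set.seed(42)
  for (i in 1:200) {
    t <- random_glycan_tree(sample(1:15, 1L), p_float = 0.1)
    s <- tree_to_string(t)
    t2 <- parse_iupac_to_tree(s)
    expect_identical(tree_to_string(t2), s)
  }
})

test_that("round-tripped trees are label-isomorphic to the original", {
  set.seed(43)
  for (i in 1:40) {
    t <- random_glycan_tree(sample(2:10, 1L))
    t2 <- parse_iupac_to_tree(tree_to_string(t))
    expect_true(trees_isomorphic(t, t2))
  }
})

test_that("serialized strings always have balanced brackets", {
  set.seed(44)
  for (i in 1:50) {
    s <- tree_to_string(random_glycan_tree(sample(1:15, 1L),
                                           p_float = 0.2))
    counts <- table(factor(strsplit(s, "")[[1]],
                           levels = c("(", ")", "[", "]", "{", "}")))
    expect_identical(unname(counts["("]), unname(counts[")"]))
    expect_identical(unname(counts["["]), unname(counts["]"]))
    expect_identical(unname(counts["{"]), unname(counts["}"]))
  }
})

test_that("cyclic or multi-parent edge sets are rejected", {
  t <- parse_iupac_to_tree("Gal(b1-4)Glc")
  bad <- t
  bad$children[[2]] <- 1L  # 1 -> 2 -> 1 cycle
  expect_error(tree_to_string(bad), "tree|cycl")
  dup <- t
  dup$children[[1]] <- c(2L, 2L)
  expect_error(tree_to_string(dup), "tree|cycl")
})

test_that("monosaccharide invariants hold", {
  expect_error(glycan_mono("Gal", mods = list(list(pos = 4L, tag = "S"),
                                              list(pos = 4L, tag = "P"))),
               "duplicate")
  m <- glycan_mono("Gal", mods = list(list(pos = NA, tag = "S"),
                                      list(pos = 3L, tag = "P")))
  expect_identical(mono_to_string(m), "Gal3POS")
  expect_error(glycan_link("a", 1, c(3, NA)), "singleton")
})
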