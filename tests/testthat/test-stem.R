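# Common stem: dialect homogenization and chemical-feasibility repair.

test_that("token normalization fixes synonyms, Greek letters and case", {
  expect_identical(normalize_tokens("NeuAc(a2-3)Gal(b1-4)Glc"),
                   "Neu5Ac(a2-3)Gal(b1-4)Glc")
  expect_identical(normalize_tokens("Galβ1-4Glc"), "Galb1-4Glc")
  expect_identical(normalize_tokens("Gal(b1-4)Glc"), "Gal(b1-4)Glc")
  expect_identical(normalize_tokens("GLC"), "Glc")
  expect_identical(normalize_tokens("D-Galp"), "Gal")
  expect_identical(normalize_tokens("L-Gal"), "L-Gal")
  expect_identical(normalize_tokens("L-Fuc"), "Fuc")
})

test_that("linkage normalization expands every documented dialect", {
  cases <- list(
    c("Galb4Glc", "Gal(b1-4)Glc"),
    c("Galb1-4Glc", "Gal(b1-4)Glc"),
    c("bDGalp(1-4)bDGlcp", "Gal(b1-4)Glc"),
    c("Man(a1-3)(Man(a1-6))Man", "Man(a1-3)[Man(a1-6)]Man"),
    c("Neu5Aca3Galb4Glc", "Neu5Ac(a2-3)Gal(b1-4)Glc"),
    c("Mana-Man", "Man(a1-?)Man"),
    c("Man-Man", "Man(?1-?)Man"),
    c("Mana1-Man", "Man(a1-?)Man"),
    c("ManMan", "Man(?1-?)Man"),
    c("Galb(1-4)Glc", "Gal(b1-4)Glc"),
    c("Gal(1-4)Glc", "Gal(?1-4)Glc"),
    c("Gal(b1,4)Glc", "Gal(b1-4)Glc"),
    c("Neu5Ac(a2-3/6)Gal", "Neu5Ac(a2-3/6)Gal"))
  for (cs in cases) {
    expect_identical(common_stem(cs[1]), cs[2], label = cs[1])
  }
})

test_that("modification dialects all land on the token-internal form", {
  cases <- list(
    c("[4S]Gal(b1-4)Glc", "Gal4S(b1-4)Glc"),
    c("SGal(b1-4)Glc", "GalOS(b1-4)Glc"),
    c("S-Gal(b1-4)Glc", "GalOS(b1-4)Glc"),
    c("[S]Gal(b1-4)Glc", "GalOS(b1-4)Glc"),
    c("Gal?S(b1-4)Glc", "GalOS(b1-4)Glc"),
    c("6SGal(b1-4)Glc", "Gal6S(b1-4)Glc"),
    c("[4S]Galb4GlcNAcb;", "Gal4S(b1-4)GlcNAc"),
    c("Gal6S(b1-4)GlcNAc", "Gal6S(b1-4)GlcNAc"))
  for (cs in cases) {
    expect_identical(common_stem(cs[1]), cs[2], label = cs[1])
  }
})

test_that("uncertain substituents are rewritten to floating parts", {
  expect_identical(common_stem("Gal(b1-4)Glc + Neu5Ac"),
                   "{Neu5Ac(a2-?)}Gal(b1-4)Glc")
  expect_identical(common_stem("{Neu5Ac(a2-?)}Gal(b1-4)Glc"),
                   "{Neu5Ac(a2-?)}Gal(b1-4)Glc")
  expect_identical(common_stem("{Fuc}Gal(b1-4)Glc"),
                   "{Fuc(?1-?)}Gal(b1-4)Glc")
})

test_that("chemical impossibilities are repaired, never rejected", {
  # duplicate acceptor: the later sibling in reading order is wildcarded
  expect_identical(common_stem("Gal(b1-4)[Fuc(a1-4)]GlcNAc"),
                   "Gal(b1-4)[Fuc(a1-?)]GlcNAc")
  # position 5 of a sialic acid carries the N-acetyl
  expect_identical(common_stem("Gal(b1-5)Neu5Ac"), "Gal(b1-?)Neu5Ac")
  # Lewis a is feasible and untouched
  expect_identical(common_stem("Gal(b1-3)[Fuc(a1-4)]GlcNAc"),
                   "Gal(b1-3)[Fuc(a1-4)]GlcNAc")
  # a modification blocks its position for incoming linkages
  expect_identical(common_stem("Gal(b1-6)Gal6S"), "Gal(b1-?)Gal6S")
  # acceptor beyond the backbone length
  expect_identical(common_stem("Gal(b1-8)Glc"), "Gal(b1-?)Glc")
  # narrow ambiguity drops only the blocked member
  expect_identical(common_stem("Gal(b1-4)[Fuc(a1-3/4)]GlcNAc"),
                   "Gal(b1-4)[Fuc(a1-3)]GlcNAc")
})

test_that("occupancy is sound after repair on random trees", {
  set.seed(7)
  for (i in 1:40) {
    t <- random_glycan_tree(sample(2:12, 1L))
    t2 <- enforce_chemical_feasibility(t)
    for (node in seq_along(t2$nodes)) {
      kids <- t2$children[[node]]
      acc <- unlist(lapply(kids, function(k) {
        a <- t2$links[[k]]$acceptors
        if (length(a) == 1L && !is.na(a)) a else NULL
      }))
      expect_false(anyDuplicated(acc) > 0)
      blocked <- glycanbabel:::blocked_positions(t2$nodes[[node]])
      expect_length(intersect(acc, blocked), 0L)
    }
  }
})

test_that("the stem is idempotent on dialect variants", {
  set.seed(9)
  seeds <- sample(glycan_corpus(), 12L)
  for (g in seeds) {
    for (v in generate_dialect_variants(g, seed = 5L, n = 4L)) {
      once <- common_stem(v)
      expect_identical(common_stem(once), once, label = v)
    }
  }
})

test_that("the modifications stage is inert on modification-free input", {
  for (g in glycan_corpus()[1:20]) {
    s <- normalize_linkages_and_brackets(normalize_tokens(g))
    expect_identical(normalize_modifications_and_floating(s), s)
  }
})

test_that("each normalization stage is itself idempotent", {
  probes <- c("Galb4Glc", "[4S]Gal(b1-4)Glc", "NeuAca3Galb4Glc",
              "bDGalp(1-4)bDGlcp", "Man(a1-3)(Man(a1-6))Man")
  for (p in probes) {
    t1 <- normalize_tokens(p)
    expect_identical(normalize_tokens(t1), t1)
    l1 <- normalize_linkages_and_brackets(t1)
    expect_identical(normalize_linkages_and_brackets(l1), l1)
    m1 <- normalize_modifications_and_floating(l1)
    expect_identical(normalize_modifications_and_floating(m1), m1)
  }
})
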