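# Branch canonicalization: one serialized string per molecule.

test_that("the documented ordering rules hold on hand-built trees", {
  cs <- function(s) canonical_string(parse_iupac_to_tree(s))
  # lower linkage number first on equal chain lengths
  expect_identical(cs("Man(a1-6)[Man(a1-3)]Man"),
                   "Man(a1-3)[Man(a1-6)]Man")
  # integer linkages before wildcards
  expect_identical(cs("Man(a1-?)[Man(a1-3)]Man"),
                   "Man(a1-3)[Man(a1-?)]Man")
  # longest chain continues the main chain
  expect_identical(cs("Neu5Ac(a2-3)[Gal(b1-3)GalNAc(b1-4)]Gal(b1-4)Glc"),
                   "Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc")
  # no branches: identity
  expect_identical(cs("Gal(b1-4)Glc"), "Gal(b1-4)Glc")
  # oligomannose M5: the two-residue arm wins the main chain, equal-length
  # children tie-break on 3 < 6
  expect_identical(
    cs("Man(a1-6)[Man(a1-3)]Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc"),
    "Man(a1-3)[Man(a1-6)]Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc")
  # alphabetical tie-break on the minimum leaf label
  expect_identical(cs("Man(a1-3)[Gal(a1-3)]Hex"),
                   "Gal(a1-3)[Man(a1-3)]Hex")
})

test_that("branch keys expose chain length, link rank and labels", {
  t <- parse_iupac_to_tree("Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal")
  kids <- t$children[[t$root]]
  k1 <- branch_key(t, kids[1])
  k2 <- branch_key(t, kids[2])
  expect_identical(k1$chain_length, 2L)
  expect_identical(k1$link_rank, 4)
  expect_identical(k2$chain_length, 1L)
  expect_identical(k2$link_rank, 3)
  expect_identical(k2$min_leaf, "Neu5Ac")
  # a wildcard ranks below any integer
  tw <- parse_iupac_to_tree("Man(a1-?)Man")
  expect_identical(branch_key(tw, tw$children[[tw$root]][1])$link_rank, Inf)
  # label-isomorphic siblings have identical keys
  ti <- parse_iupac_to_tree("Man(a1-2)Man(a1-3)[Man(a1-2)Man(a1-3)]Man")
  ks <- lapply(ti$children[[ti$root]], function(k) branch_key(ti, k))
  expect_identical(ks[[1]], ks[[2]])
})

test_that("canonical_string is invariant under sibling permutations", {
  set.seed(21)
  corpus_trees <- lapply(glycan_corpus(), parse_iupac_to_tree)
  for (t in corpus_trees) {
    ref <- canonical_string(t)
    branched <- which(lengths(t$children) %in% 2:4)
    for (node in branched) {
      for (perm in all_perms(length(t$children[[node]]))) {
        expect_identical(canonical_string(permute_node(t, node, perm)),
                         ref)
      }
    }
    # random global shuffles on top
    for (r in 1:5) {
      expect_identical(
        canonical_string(glycanbabel:::gt_shuffle_children(t)), ref)
    }
  }
})

test_that("canonicalization is a projection (idempotent)", {
  set.seed(22)
  for (i in 1:30) {
    t <- random_glycan_tree(sample(2:12, 1L))
    once <- canonicalize_branches(t)
    expect_same_tree(canonicalize_branches(once), once)
  }
})

test_that("canonical strings are equal iff trees are label-isomorphic", {
  trees <- lapply(glycan_corpus(), parse_iupac_to_tree)
  small <- trees[vapply(trees, function(t) length(t$nodes) <= 12L,
                        logical(1))]
  canon <- vapply(small, canonical_string, character(1))
  for (i in seq_along(small)) {
    for (j in seq_len(i - 1L)) {
      expect_identical(canon[i] == canon[j],
                       trees_isomorphic(small[[i]], small[[j]]),
                       label = paste(canon[i], "vs", canon[j]))
    }
  }
})

test_that("canonical output ignores node insertion order", {
  set.seed(23)
  for (g in sample(glycan_corpus(), 10L)) {
    t <- parse_iupac_to_tree(g)
    # rebuild the tree by inserting subtrees in random order
    rebuild <- function(t) {
      t2 <- glycan_tree(t$nodes[[t$root]])
      add_rec <- function(orig_parent, new_parent) {
        kids <- t$children[[orig_parent]]
        for (k in kids[sample.int(length(kids))]) {
          res <- gt_add_child(t2, new_parent, t$nodes[[k]], t$links[[k]])
          t2 <<- res$tree
          add_rec(k, res$idx)
        }
      }
      add_rec(t$root, 1L)
      t2
    }
    expect_identical(canonical_string(rebuild(t)), canonical_string(t))
  }
})

test_that("floating parts are sorted alphabetically among themselves", {
  t <- parse_iupac_to_tree("{Neu5Ac(a2-?)}{Fuc(a1-?)}Gal(b1-4)Glc")
  expect_identical(canonical_string(t),
                   "{Fuc(a1-?)}{Neu5Ac(a2-?)}Gal(b1-4)Glc")
})
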