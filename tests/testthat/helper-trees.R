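# Random glycan-tree generator used by the property tests. Trees are
# built over common residues with random (but well-formed) linkages;
# modifications, non-default enantiomers/rings and floating parts appear
# with low probability, mirroring their frequency in real data.

random_mono <- function() {
  bases <- c("Gal", "Glc", "Man", "GlcNAc", "GalNAc", "Fuc", "Xyl",
             "Neu5Ac", "Neu5Gc", "GlcA", "Rha", "Kdn")
  base <- sample(bases, 1L)
  mods <- list()
  if (stats::runif(1) < 0.15 && !base %in% c("Neu5Ac", "Neu5Gc", "Kdn")) {
    pos <- sample(c(3L, 4L, 6L, NA_integer_), 1L)
    mods <- list(list(pos = pos, tag = sample(c("S", "P", "Me", "Ac"), 1L)))
  }
  enant <- if (stats::runif(1) < 0.05 && base %in% c("Gal", "Glc")) "L"
  glycan_mono(base, enantiomer = enant, mods = mods)
}

random_link <- function(base) {
  anomer <- sample(c("a", "b", "?"), 1L, prob = c(0.45, 0.45, 0.1))
  acc <- if (stats::runif(1) < 0.1) NA_integer_ else
    sample(2:8, sample(1:2, 1L, prob = c(0.9, 0.1)))
  glycan_link(anomer, default_donor(base), acc)
}

random_glycan_tree <- function(n_nodes, p_float = 0) {
  m <- random_mono()
  t <- glycan_tree(m)
  while (length(t$nodes) < n_nodes) {
    parent <- sample(seq_along(t$nodes), 1L)
    child <- random_mono()
    t <- gt_add_child(t, parent, child, random_link(child$base))$tree
  }
  if (p_float > 0 && stats::runif(1) < p_float) {
    sub <- random_glycan_tree(sample(1:2, 1L))
    base <- sub$nodes[[sub$root]]$base
    t$floating <- list(list(
      tree = sub,
      link = glycan_link(default_anomer(base), default_donor(base),
                         NA_integer_)))
  }
  t
}

# order-preserving structural equality via the faithful serialization
expect_same_tree <- function(t1, t2) {
  expect_identical(tree_to_string(t1), tree_to_string(t2))
}

# all sibling-order permutations of the children of one node
permute_node <- function(t, node, perm) {
  t$children[[node]] <- t$children[[node]][perm]
  t
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
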