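# Deterministic branch ordering: one serialized string per molecule.
#
# At every node, sibling branches are sorted by (in priority order):
#   1. longest monosaccharide chain in the branch, descending — the longest
#      branch continues the main chain;
#   2. linkage position at the branch point, ascending, with integer
#      positions strictly before wildcards (multi-position sets rank by
#      their minimum member);
#   3. alphabetical comparison of the minimum leaf label, then of the full
#      canonical subtree serialization (walking down the branch until a
#      difference appears).
# Keys are computed post-order (children sorted before their parent's key
# is read), which makes the ordering fully deterministic and idempotent.

#' @keywords internal
link_rank <- function(l) {
  if (any(is.na(l$acceptors))) Inf else as.numeric(min(l$acceptors))
}

#' @keywords internal
min_leaf_label <- function(t, node) {
  kids <- t$children[[node]]
  if (!length(kids)) return(mono_to_string(t$nodes[[node]]))
  min(vapply(kids, function(k) min_leaf_label(t, k), character(1)))
}

# serialization of the subtree rooted at `node` with current child order
#' @keywords internal
subtree_string <- function(t, node) {
  kids <- t$children[[node]]
  res <- mono_to_string(t$nodes[[node]])
  if (!length(kids)) return(res)
  main <- kids[1]
  out <- paste0(subtree_string(t, main), "(",
                link_to_string(t$links[[main]]), ")")
  for (k in kids[-1]) {
    out <- paste0(out, "[", subtree_string(t, k), "(",
                  link_to_string(t$links[[k]]), ")]")
  }
  paste0(out, res)
}

#' Sorting key of a sibling branch
#'
#' @param t A `glycan_tree`.
#' @param child Index of a non-root node; the key is computed from the
#'   child's subtree only.
#' @return List with `chain_length`, `link_rank` (numeric; `Inf` for a
#'   wildcard acceptor), `min_leaf` and `subtree` (tie-break strings).
#' @export
branch_key <- function(t, child) {
  list(chain_length = longest_chain_length(t, child),
       link_rank = link_rank(t$links[[child]]),
       min_leaf = min_leaf_label(t, child),
       subtree = subtree_string(t, child))
}

#' Canonicalize branch order of a glycan tree
#'
#' Recursive post-order pass: children are sorted before their parent so
#' that tie-break keys see already-canonical subtrees. The first-sorted
#' child continues the main chain on serialization; the rest are
#' bracketed. Applying the function twice equals applying it once.
#'
#' @param t A `glycan_tree`.
#' @return The tree with children reordered at every node.
#' @export
canonicalize_branches <- function(t) {
  validate_tree(t)
  canon <- function(node) {
    kids <- t$children[[node]]
    for (k in kids) canon(k)
    kids <- t$children[[node]]  # re-read: recursion rewrote child order
    if (length(kids) > 1L) {
      keys <- lapply(kids, function(k) branch_key(t, k))
      len <- vapply(keys, `[[`, numeric(1), "chain_length")
      rnk <- vapply(keys, `[[`, numeric(1), "link_rank")
      leaf <- vapply(keys, `[[`, character(1), "min_leaf")
      sub <- vapply(keys, `[[`, character(1), "subtree")
      o <- order(-len, rnk, leaf, sub, method = "radix")
      t$children[[node]] <<- kids[o]
    }
    invisible(NULL)
  }
  canon(t$root)
  t$floating <- lapply(t$floating, function(f) {
    f$tree <- canonicalize_branches(f$tree)
    f
  })
  t
}

#' Canonical IUPAC-condensed string of a glycan tree
#'
#' `tree_to_string(canonicalize_branches(t))`: unique per
#' label-isomorphism class of trees.
#'
#' @param t A `glycan_tree`.
#' @return The canonical string.
#' @export
canonical_string <- function(t) {
  tree_to_string(canonicalize_branches(t))
}

# brute-force label-isomorphism matcher (test oracle; trees <= ~12 nodes)
#' @keywords internal
trees_isomorphic <- function(t1, t2, n1 = t1$root, n2 = t2$root) {
  if (mono_to_string(t1$nodes[[n1]]) != mono_to_string(t2$nodes[[n2]])) {
    return(FALSE)
  }
  k1 <- t1$children[[n1]]
  k2 <- t2$children[[n2]]
  if (length(k1) != length(k2)) return(FALSE)
  if (!length(k1)) return(TRUE)
  match_rec <- function(rem1, rem2) {
    if (!length(rem1)) return(TRUE)
    a <- rem1[1]
    for (j in seq_along(rem2)) {
      b <- rem2[j]
      if (link_to_string(t1$links[[a]]) == link_to_string(t2$links[[b]]) &&
          trees_isomorphic(t1, t2, a, b) &&
          match_rec(rem1[-1], rem2[-j])) {
        return(TRUE)
      }
    }
    FALSE
  }
  match_rec(k1, k2)
}
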