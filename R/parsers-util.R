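# Shared plumbing for the format parsers. Block formats are first read
# into a residue/link table (index -> token, child/parent/linkage rows),
# then serialized to a raw IUPAC-like flat string. Parsers are
# deliberately rudimentary: they emit "anything resembling IUPAC" and
# leave namespace cleanup, defaults and bracket conventions to the common
# stem.

#' @keywords internal
unsupported_token <- function(token, format) {
  stop("unsupported ", format, " token: '", token, "'", call. = FALSE)
}

# tokens: character vector (1..n residue tokens, raw)
# links: data.frame(child, parent, anomer, donor, acceptor) where donor is
#   integer or NA and acceptor is a string ("4", "?", "3/4")
#' @keywords internal
rlt_to_string <- function(tokens, links, root_suffix = "") {
  n <- length(tokens)
  if (!n) stop("empty residue table", call. = FALSE)
  is_child <- seq_len(n) %in% links$child
  roots <- which(!is_child)
  if (length(roots) != 1L) {
    stop("residue/link table is not a rooted tree (",
         length(roots), " roots)", call. = FALSE)
  }
  if (nrow(links)) {
    if (any(!links$child %in% seq_len(n)) ||
        any(!links$parent %in% seq_len(n))) {
      stop("link references an undefined residue", call. = FALSE)
    }
    if (anyDuplicated(links$child)) {
      stop("residue with more than one parent", call. = FALSE)
    }
  }
  mk_link <- function(row) {
    acc <- if (row$acceptor %in% c("?", "-1", "")) NA_integer_ else
      as.integer(strsplit(row$acceptor, "/", fixed = TRUE)[[1]])
    glycan_link(anomer = if (row$anomer %in% c("a", "b")) row$anomer else "?",
                donor = row$donor, acceptors = acc)
  }
  t <- glycan_tree(parse_mono(tokens[roots]))
  idx_map <- integer(n)
  idx_map[roots] <- 1L
  grow <- function(orig) {
    rows <- which(links$parent == orig)
    for (r in rows) {
      child <- links$child[r]
      res <- gt_add_child(t, idx_map[orig], parse_mono(tokens[child]),
                          mk_link(links[r, ]))
      t <<- res$tree
      idx_map[child] <<- res$idx
      grow(child)
    }
  }
  grow(roots)
  if (length(t$nodes) != n) {
    stop("disconnected residues in input block", call. = FALSE)
  }
  t$root_suffix <- root_suffix
  tree_to_string(t)
}
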