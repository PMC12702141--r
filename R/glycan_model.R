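# Core data model: a glycan is a rooted directed tree whose root is the
# reducing-end residue. Edges point child -> parent and carry a linkage
# (anomer, donor carbon, acceptor position(s)). Residues known to be present
# but with undetermined attachment live in `floating`, serialized in curly
# brackets before the main chain.

#' Construct a monosaccharide
#'
#' @param base Base token from the controlled namespace (see
#'   [monosaccharide_table()]), or an unknown token (flagged, not rejected,
#'   so parsers can defer errors to the common stem).
#' @param enantiomer `"D"`, `"L"` or `NULL` (= namespace default).
#' @param ring `"p"`, `"f"` or `NULL` (= namespace default).
#' @param mods List of `list(pos =, tag =)` modifications; `pos` is an
#'   integer carbon 1-9 or `NA` for unknown position.
#' @return An object of class `glycan_mono`.
#' @export
glycan_mono <- function(base, enantiomer = NULL, ring = NULL, mods = list()) {
  known <- is_known_base(base)
  pos <- vapply(mods, function(m) as.integer(m$pos %||% NA_integer_),
                integer(1))
  ip <- pos[!is.na(pos)]
  if (anyDuplicated(ip)) {
    stop("duplicate modification position on '", base, "'", call. = FALSE)
  }
  # integer positions first (ascending), unknown-position mods after
  mods <- mods[order(is.na(pos), pos)]
  structure(list(base = base, enantiomer = enantiomer, ring = ring,
                 mods = mods, known = known),
            class = "glycan_mono")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a linkage
#'
#' @param anomer `"a"`, `"b"` or `"?"`.
#' @param donor Donor (anomeric) carbon: 1, 2 or `NA` for unknown.
#' @param acceptors Integer vector of acceptor positions (a multi-member
#'   set such as `c(3, 4)` encodes narrow ambiguity, rendered `3/4`), or
#'   `NA` for a full wildcard. `NA` must be the only member.
#' @return An object of class `glycan_link`.
#' @export
glycan_link <- function(anomer = "?", donor = NA_integer_,
                        acceptors = NA_integer_) {
  stopifnot(anomer %in% c("a", "b", "?"))
  donor <- as.integer(donor)
  acceptors <- as.integer(acceptors)
  if (any(is.na(acceptors)) && length(acceptors) > 1L) {
    stop("wildcard acceptor '?' must be a singleton", call. = FALSE)
  }
  if (!any(is.na(acceptors))) {
    acceptors <- sort(unique(acceptors))
  }
  structure(list(anomer = anomer, donor = donor, acceptors = acceptors),
            class = "glycan_link")
}

#' @keywords internal
link_to_string <- function(l) {
  d <- if (is.na(l$donor)) "?" else as.character(l$donor)
  a <- if (any(is.na(l$acceptors))) "?" else
    paste(l$acceptors, collapse = "/")
  paste0(l$anomer, d, "-", a)
}

#' @keywords internal
mono_to_string <- function(m) {
  pre <- ""
  suf <- ""
  if (m$known) {
    row <- mono_row(m$base)
    if (!is.null(m$enantiomer) && m$enantiomer != row$enantiomer &&
        m$enantiomer %in% c("D", "L")) {
      pre <- paste0(m$enantiomer, "-")
    }
    if (!is.null(m$ring) && m$ring != row$ring && m$ring == "f") suf <- "f"
  } else {
    if (!is.null(m$enantiomer) && m$enantiomer %in% c("D", "L")) {
      pre <- paste0(m$enantiomer, "-")
    }
  }
  mods <- vapply(m$mods, function(x) {
    paste0(if (is.na(x$pos)) "O" else as.character(x$pos), x$tag)
  }, character(1))
  paste0(pre, m$base, suf, paste(mods, collapse = ""))
}

# ---- tree -------------------------------------------------------------------

#' Construct a single-node glycan tree
#'
#' @param mono A [glycan_mono()] for the reducing-end residue.
#' @return An object of class `glycan_tree`.
#' @export
glycan_tree <- function(mono) {
  structure(list(nodes = list(mono), children = list(integer(0)),
                 links = list(NULL), root = 1L, floating = list(),
                 root_suffix = ""),
            class = "glycan_tree")
}

#' Add a child residue to a tree node
#'
#' @param t A `glycan_tree`.
#' @param parent Index of the parent node.
#' @param mono The child [glycan_mono()].
#' @param link The [glycan_link()] labelling the child-to-parent edge.
#' @return List with elements `tree` (updated tree) and `idx` (new node's
#'   index).
#' @export
gt_add_child <- function(t, parent, mono, link) {
  stopifnot(inherits(t, "glycan_tree"), parent >= 1L,
            parent <= length(t$nodes))
  i <- length(t$nodes) + 1L
  t$nodes[[i]] <- mono
  t$children[[i]] <- integer(0)
  t$links[[i]] <- link
  t$children[[parent]] <- c(t$children[[parent]], i)
  list(tree = t, idx = i)
}

# splice `sub` (a glycan_tree) in as a child subtree of `parent` in `t`
#' @keywords internal
gt_attach_subtree <- function(t, parent, sub, link, first = FALSE) {
  off <- length(t$nodes)
  t$nodes <- c(t$nodes, sub$nodes)
  t$children <- c(t$children, lapply(sub$children, function(k) k + off))
  t$links <- c(t$links, sub$links)
  t$links[[sub$root + off]] <- link
  kid <- sub$root + off
  t$children[[parent]] <-
    if (first) c(kid, t$children[[parent]]) else c(t$children[[parent]], kid)
  t
}

#' @keywords internal
all_monos <- function(t) {
  c(t$nodes, unlist(lapply(t$floating, function(f) all_monos(f$tree)),
                    recursive = FALSE))
}

#' Number of residues in a glycan tree (main tree plus floating parts)
#' @param t A `glycan_tree`.
#' @export
gt_size <- function(t) {
  length(t$nodes) + sum(vapply(t$floating,
                               function(f) gt_size(f$tree), integer(1)))
}

#' @keywords internal
gt_parent <- function(t) {
  p <- rep(NA_integer_, length(t$nodes))
  for (i in seq_along(t$children)) p[t$children[[i]]] <- i
  p
}

#' @keywords internal
validate_tree <- function(t) {
  n <- length(t$nodes)
  if (n == 0L) stop("glycan tree is empty", call. = FALSE)
  p <- gt_parent(t)
  if (sum(is.na(p)) != 1L || !is.na(p[t$root])) {
    stop("edge set is not a tree rooted at the reducing end", call. = FALSE)
  }
  # reachability from root (a cycle among non-root nodes leaves them
  # unreachable even though each has one parent)
  seen <- logical(n)
  stack <- t$root
  while (length(stack)) {
    i <- stack[[1]]
    stack <- stack[-1]
    if (seen[i]) stop("cyclic edge set in glycan tree", call. = FALSE)
    seen[i] <- TRUE
    stack <- c(stack, t$children[[i]])
  }
  if (!all(seen)) stop("cyclic or disconnected edge set", call. = FALSE)
  invisible(t)
}

#' Longest monosaccharide chain below (and including) a node
#'
#' Counts monosaccharide nodes only; linkages and modifications do not
#' contribute. A leaf scores 1.
#'
#' @param t A `glycan_tree`.
#' @param node Node index (defaults to the root).
#' @return Integer chain length.
#' @export
longest_chain_length <- function(t, node = t$root) {
  kids <- t$children[[node]]
  if (!length(kids)) return(1L)
  1L + max(vapply(kids, function(k) longest_chain_length(t, k), integer(1)))
}

# ---- serialization ----------------------------------------------------------

#' Serialize a glycan tree to IUPAC-condensed
#'
#' Deterministic writer: sibling order in the tree is emitted verbatim
#' (branch ordering is the canonicalizer's job, not this writer's). The
#' first child of a node continues the main chain; remaining children are
#' bracketed in order. Floating parts are emitted first, each in its own
#' `{...}`, sorted alphabetically.
#'
#' @param t A `glycan_tree`.
#' @return IUPAC-condensed string.
#' @export
tree_to_string <- function(t) {
  validate_tree(t)
  ser <- function(i) {
    kids <- t$children[[i]]
    res <- mono_to_string(t$nodes[[i]])
    if (!length(kids)) return(res)
    main <- kids[1]
    rest <- kids[-1]
    out <- paste0(ser(main), "(", link_to_string(t$links[[main]]), ")")
    for (k in rest) {
      out <- paste0(out, "[", ser(k), "(", link_to_string(t$links[[k]]), ")]")
    }
    paste0(out, res)
  }
  fl <- vapply(t$floating, function(f) {
    paste0("{", tree_to_string(f$tree), "(", link_to_string(f$link), ")}")
  }, character(1))
  paste0(paste(sort(fl), collapse = ""), ser(t$root), t$root_suffix)
}

# ---- parsing ----------------------------------------------------------------

#' @keywords internal
parse_mono <- function(token) {
  rx <- paste0("^(?:([DL])-)?(", base_alternation(), ")(f)?((?:[1-9O](?:",
               tag_alternation(), "))*)$")
  m <- regmatches(token, regexec(rx, token, perl = TRUE))[[1]]
  if (!length(m)) {
    # unknown token: keep it intact but flagged, if it at least looks like a
    # residue name; callers that require known tokens check `known`
    if (grepl("^(?:[DL]-)?[A-Za-z][A-Za-z0-9]*$", token)) {
      return(glycan_mono(token))
    }
    stop("unknown monosaccharide token: '", token, "'", call. = FALSE)
  }
  mods <- list()
  if (nzchar(m[5])) {
    mm <- gregexpr(paste0("([1-9O])(", tag_alternation(), ")"), m[5],
                   perl = TRUE)[[1]]
    parts <- regmatches(m[5], list(mm))[[1]]
    mods <- lapply(parts, function(p) {
      posc <- substr(p, 1, 1)
      list(pos = if (posc == "O") NA_integer_ else as.integer(posc),
           tag = substr(p, 2, nchar(p)))
    })
  }
  glycan_mono(m[3],
              enantiomer = if (nzchar(m[2])) m[2] else NULL,
              ring = if (nzchar(m[4])) "f" else NULL,
              mods = mods)
}

#' @keywords internal
parse_link_text <- function(txt) {
  m <- regmatches(txt, regexec(
    "^([ab?])([12?])-([1-9](?:/[1-9])*|\\?)$", txt))[[1]]
  if (!length(m)) stop("malformed linkage '", txt, "'", call. = FALSE)
  acceptors <- if (m[4] == "?") NA_integer_ else
    as.integer(strsplit(m[4], "/", fixed = TRUE)[[1]])
  glycan_link(anomer = m[2],
              donor = if (m[3] == "?") NA_integer_ else as.integer(m[3]),
              acceptors = acceptors)
}

#' @keywords internal
check_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  stack <- character(0)
  pairs <- c(")" = "(", "]" = "[", "}" = "{")
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[", "{")) {
      stack <- c(stack, ch)
    } else if (ch %in% names(pairs)) {
      if (!length(stack) || stack[length(stack)] != pairs[[ch]]) {
        stop("unbalanced bracket at index ", i, " in '", s, "'",
             call. = FALSE)
      }
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    stop("unbalanced bracket: unclosed '", stack[length(stack)], "' in '",
         s, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# index of the "(" matching the ")" at position `close` (scanning left)
#' @keywords internal
match_open <- function(chars, close, open_ch = "(", close_ch = ")") {
  depth <- 0L
  for (i in seq(close, 1L)) {
    if (chars[i] == close_ch) depth <- depth + 1L
    if (chars[i] == open_ch) {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("unbalanced bracket at index ", close, call. = FALSE)
}

#' Parse a standardized IUPAC-condensed string into a glycan tree
#'
#' Expects a string that has passed the common stem: balanced brackets,
#' parenthesized linkages, square-bracket branches and curly-bracket
#' floating parts. The rightmost residue becomes the root.
#'
#' @param s IUPAC-condensed string.
#' @return A `glycan_tree`.
#' @export
parse_iupac_to_tree <- function(s) {
  if (!nzchar(trimws(s))) stop("empty glycan string", call. = FALSE)
  s <- trimws(s)
  check_balanced(s)

  floating <- list()
  # curly-bracket prefixes -> floating parts
  while (startsWith(s, "{")) {
    chars <- strsplit(s, "")[[1]]
    depth <- 0L
    end <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == "{") depth <- depth + 1L
      if (chars[i] == "}") {
        depth <- depth - 1L
        if (depth == 0L) { end <- i; break }
      }
    }
    inner <- substr(s, 2, end - 1L)
    s <- substr(s, end + 1L, nchar(s))
    # inner = chain + optional trailing "(link)"
    lk <- NULL
    if (endsWith(inner, ")")) {
      chars2 <- strsplit(inner, "")[[1]]
      op <- match_open(chars2, length(chars2))
      cand <- substr(inner, op + 1L, nchar(inner) - 1L)
      if (grepl("^[ab?][12?]-", cand)) {
        lk <- parse_link_text(cand)
        inner <- substr(inner, 1, op - 1L)
      }
    }
    sub <- parse_iupac_to_tree(inner)
    if (is.null(lk)) {
      base <- sub$nodes[[sub$root]]$base
      lk <- glycan_link(default_anomer(base), default_donor(base),
                        NA_integer_)
    }
    floating <- c(floating, list(list(tree = sub, link = lk)))
  }
  if (!nzchar(s)) stop("floating parts without a main chain", call. = FALSE)

  root_suffix <- ""
  sfx <- regmatches(s, regexec("-(ol|OMe)$", s))[[1]]
  if (length(sfx)) {
    root_suffix <- paste0("-", sfx[2])
    s <- substr(s, 1, nchar(s) - nchar(root_suffix))
  }

  t <- parse_chain(s)
  t$floating <- floating
  t$root_suffix <- root_suffix
  validate_tree(t)
}

# recursive descent, right to left: root residue token, then bracketed
# sibling groups, then the main-chain child behind "(link)"
#' @keywords internal
parse_chain <- function(s) {
  if (!nzchar(s)) stop("empty chain segment", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  pos <- n
  while (pos >= 1L && !chars[pos] %in% c(")", "]", "(", "[", "{", "}")) {
    pos <- pos - 1L
  }
  root_tok <- substr(s, pos + 1L, n)
  if (!nzchar(root_tok)) {
    stop("missing residue token at index ", n, " in '", s, "'",
         call. = FALSE)
  }
  t <- glycan_tree(parse_mono(root_tok))
  rest <- substr(s, 1, pos)

  groups <- list()  # bracketed sibling branches, collected right-to-left
  repeat {
    if (!nzchar(rest)) break
    chars <- strsplit(rest, "")[[1]]
    last <- chars[length(chars)]
    if (last == "]") {
      op <- match_open(chars, length(chars), "[", "]")
      inner <- substr(rest, op + 1L, nchar(rest) - 1L)
      groups <- c(groups, list(inner))
      rest <- substr(rest, 1, op - 1L)
    } else if (last == ")") {
      op <- match_open(chars, length(chars))
      lk <- parse_link_text(substr(rest, op + 1L, nchar(rest) - 1L))
      left <- substr(rest, 1, op - 1L)
      if (!nzchar(left)) {
        stop("linkage without a donor residue in '", s, "'", call. = FALSE)
      }
      sub <- parse_chain(left)
      t <- gt_attach_subtree(t, t$root, sub, lk, first = TRUE)
      rest <- ""
    } else {
      stop("unparseable chain remainder '", rest, "'", call. = FALSE)
    }
  }
  # groups were collected right-to-left; reattach in reading order after
  # the main-chain child
  for (inner in rev(groups)) {
    if (!endsWith(inner, ")")) {
      stop("branch '", inner, "' lacks a linkage", call. = FALSE)
    }
    ch2 <- strsplit(inner, "")[[1]]
    op <- match_open(ch2, length(ch2))
    lk <- parse_link_text(substr(inner, op + 1L, nchar(inner) - 1L))
    sub <- parse_chain(substr(inner, 1, op - 1L))
    t <- gt_attach_subtree(t, t$root, sub, lk)
  }
  t
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", tree_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_tree <- function(x, ...) tree_to_string(x)
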