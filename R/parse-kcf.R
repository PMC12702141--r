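# KCF (KEGG Chemical Function): block format with NODE lines
# (index, residue name, x, y drawing coordinates) and EDGE lines
# (index, <node>:<anomer><carbon>, <node>:<position>). The side carrying
# the anomer letter is the donor (child); the root is the node that never
# donates. Sibling order is taken from the drawing coordinates before
# canonicalization overrides it; coordinates are otherwise discarded.

#' Parse a KCF block into a raw IUPAC-like string
#'
#' @param s A KCF block (single string with embedded newlines).
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_kcf <- function(s) {
  lines <- strsplit(s, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  section <- ""
  nodes <- list()
  edges <- list()
  for (ln in lines) {
    t1 <- trimws(ln)
    if (grepl("^NODE\\b", t1)) { section <- "NODE"; next }
    if (grepl("^EDGE\\b", t1)) { section <- "EDGE"; next }
    if (grepl("^(ENTRY|BRACKET|///)", t1)) { section <- ""; next }
    f <- strsplit(t1, "[[:space:]]+")[[1]]
    if (section == "NODE") {
      if (length(f) < 4L) {
        stop("malformed KCF NODE line: '", t1, "'", call. = FALSE)
      }
      nodes[[as.integer(f[1])]] <-
        list(name = f[2], x = as.numeric(f[3]), y = as.numeric(f[4]))
    } else if (section == "EDGE") {
      if (length(f) < 3L) {
        stop("malformed KCF EDGE line: '", t1, "'", call. = FALSE)
      }
      edges[[length(edges) + 1L]] <- list(s1 = f[2], s2 = f[3])
    }
  }
  n <- length(nodes)
  if (!n) stop("KCF block without NODE entries", call. = FALSE)
  for (i in seq_len(n)) {
    if (is.null(nodes[[i]])) {
      stop("missing KCF node index ", i, call. = FALSE)
    }
  }
  parse_side <- function(txt) {
    m <- regmatches(txt, regexec("^(\\d+)(?::([ab?])?([0-9?]+)?)?$",
                                 txt))[[1]]
    if (!length(m)) stop("malformed KCF edge side: '", txt, "'",
                         call. = FALSE)
    list(node = as.integer(m[2]),
         anomer = if (nzchar(m[3])) m[3] else NA_character_,
         pos = if (nzchar(m[4])) m[4] else "?")
  }
  links <- data.frame(child = integer(0), parent = integer(0),
                      anomer = character(0), donor = integer(0),
                      acceptor = character(0), stringsAsFactors = FALSE)
  for (e in edges) {
    a <- parse_side(e$s1)
    b <- parse_side(e$s2)
    donor_is_a <- !is.na(a$anomer)
    ch <- if (donor_is_a) a else b
    pa <- if (donor_is_a) b else a
    if (ch$node > n || pa$node > n) {
      stop("KCF edge references undefined node", call. = FALSE)
    }
    links <- rbind(links, data.frame(
      child = ch$node, parent = pa$node,
      anomer = if (is.na(ch$anomer)) "?" else ch$anomer,
      donor = if (ch$pos %in% c("1", "2")) as.integer(ch$pos) else
        NA_integer_,
      acceptor = pa$pos, stringsAsFactors = FALSE))
  }
  # sibling order from drawing coordinates (top-most branch first)
  if (nrow(links) > 1L) {
    ys <- vapply(links$child, function(i) nodes[[i]]$y, numeric(1))
    links <- links[order(links$parent, -ys), , drop = FALSE]
  }
  tokens <- vapply(nodes, function(nd) nd$name, character(1))
  rlt_to_string(tokens, links)
}
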