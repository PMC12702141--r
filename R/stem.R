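# The common stem: homogenize any IUPAC-like string (from the format
# parsers or direct user input, including CSDB-linear and CarbBank
# dialects) into standard IUPAC-condensed, then repair chemically
# impossible linkage assignments on the parsed tree.
#
# Stages run in a fixed order -- tokens, linkages/brackets,
# modifications/floating -- and each stage is idempotent, so the stem as a
# whole is a projection. Dialect synonyms live in a plain-text rule table
# (inst/extdata/normalization_rules.json); token-case and default
# enantiomer/ring normalization are derived from the namespace table.

#' @keywords internal
load_rules <- function() {
  if (!is.null(.gb_cache$rules)) return(.gb_cache$rules)
  path <- system.file("extdata", "normalization_rules.json",
                      package = "glycanbabel")
  if (!nzchar(path)) {  # load_all() during development
    path <- file.path("inst", "extdata", "normalization_rules.json")
  }
  .gb_cache$rules <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  .gb_cache$rules
}

#' @keywords internal
apply_rules <- function(s, stage) {
  rules <- load_rules()
  rules <- rules[rules$stage == stage, , drop = FALSE]
  for (i in seq_len(nrow(rules))) {
    s <- gsub(rules$pattern[i], rules$replacement[i], s, perl = TRUE)
  }
  s
}

#' Normalize residue tokens
#'
#' Character-level repairs (Greek anomers, exotic dashes, whitespace,
#' trailing separators), synonym replacement from the shipped rule table
#' (`NeuAc` to `Neu5Ac` etc.), case repairs (`GLC` to `Glc`) and removal
#' of default enantiomer/ring markers (`D-Galp` to `Gal`, `L-Fuc` to
#' `Fuc`), all derived from [monosaccharide_table()]. Unknown tokens are
#' left intact for later errors.
#'
#' @param s A glycan string.
#' @return The token-normalized string.
#' @export
normalize_tokens <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  # Greek anomeric letters and typographic dashes
  s <- gsub("α|ɑ|Α", "a", s)
  s <- gsub("β|Β", "b", s)
  s <- gsub("→|–|—|−|->", "-", s)
  s <- sub("[;.,]+$", "", s)
  s <- apply_rules(s, "tokens")

  tab <- monosaccharide_table()
  bases <- tab$base[order(-nchar(tab$base), tab$base)]
  # case repair: whole tokens only (token start = not preceded by a letter).
  # Uronic-acid tokens end in 'A', which collides with a trailing anomer
  # ('Mana-' = Man + alpha); their case fix only fires before a delimiter
  # or a modification, never before linkage-shaped text.
  ambiguous <- grepl("A$", bases)
  guard <- paste0("(?=[\\(\\[\\]\\{\\}]|$|[1-9O](?:", tag_alternation(),
                  "))")
  for (k in seq_along(bases)) {
    b <- bases[k]
    if (b %in% c("LDmanHep", "DDmanHep")) next  # internal lowercase
    s <- gsub(paste0("(?i)(?<![A-Za-z])", b,
                     if (ambiguous[k]) guard else ""),
              b, s, perl = TRUE)
  }
  # default ring marker: Galp -> Gal (furanose 'f' is kept by the parser)
  for (b in bases) {
    s <- gsub(paste0("(?<![A-Za-z])((?:[DL]-)?", b, ")p(?![A-Za-z])"),
              "\\1", s, perl = TRUE)
  }
  # enantiomer: strip the default, keep (and dash) the non-default
  for (i in seq_len(nrow(tab))) {
    b <- tab$base[i]
    def <- tab$enantiomer[i]
    oth <- setdiff(c("D", "L"), def)
    if (def %in% c("D", "L")) {
      s <- gsub(paste0("(?<![A-Za-z])", def, "-?", b, "(?![a-z])"), b, s,
                perl = TRUE)
    }
    for (o in oth) {
      s <- gsub(paste0("(?<![A-Za-z])", o, "-?", b, "(?![a-z])"),
                paste0(o, "-", b), s, perl = TRUE)
    }
  }
  s
}

# residue-token regex used by the chain scanner (anchored by caller)
#' @keywords internal
residue_rx <- function() {
  paste0("(?:[DL]-)?(?:", base_alternation(), ")f?(?:[1-9O](?:",
         tag_alternation(), "))*")
}

#' @keywords internal
normalize_link_content <- function(content, donor_base) {
  content <- gsub(",", "-", content, fixed = TRUE)
  content <- sub("^A", "a", sub("^B", "b", content))
  # a bare trailing digit is an acceptor ("Galb4Glc" = b1-4), so the donor
  # slot only matches when a dash or further position follows
  m <- regmatches(content, regexec(
    "^([ab?])?(?:([12?])(?=-|[1-9?]))?(-)?([1-9?](?:/[1-9])*)?$", content,
    perl = TRUE))[[1]]
  if (!length(m) || !nzchar(paste0(m[2], m[3], m[4], m[5]))) {
    return(content)  # not linkage-shaped; leave for later error reporting
  }
  anomer <- if (nzchar(m[2])) m[2] else "?"
  donor <- if (nzchar(m[3]) && m[3] != "?") m[3] else
    as.character(default_donor(donor_base))
  acceptor <- if (nzchar(m[5])) m[5] else "?"
  paste0(anomer, donor, "-", acceptor)
}

# expand inline (dashless / parenthesis-free) linkages inside one chain
# segment; returns the segment unchanged when it cannot be tokenized
#' @keywords internal
process_segment <- function(seg, at_string_end) {
  if (!nzchar(seg)) return(seg)
  suffix <- ""
  sfx <- regmatches(seg, regexec("-(ol|OMe|OH)$", seg))[[1]]
  if (length(sfx)) {
    suffix <- paste0("-", sfx[2])
    seg <- substr(seg, 1, nchar(seg) - nchar(suffix))
  }
  res_rx <- paste0("^(", residue_rx(), ")")
  link_rx <- "^([abAB?])?(?:([12?])(?=-|[1-9?]))?(-)?([1-9?](?:/[1-9])*)?"
  out <- character(0)
  rest <- seg
  last_base <- NULL
  repeat {
    rm_ <- regmatches(rest, regexec(res_rx, rest, perl = TRUE))[[1]]
    if (!length(rm_)) return(paste0(seg, suffix))  # defer to parse errors
    tok <- rm_[2]
    out <- c(out, tok)
    bm <- regmatches(tok, regexec(
      paste0("^(?:[DL]-)?(", base_alternation(), ")"), tok,
      perl = TRUE))[[1]]
    last_base <- bm[2]
    rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
    if (!nzchar(rest)) break
    lm <- regmatches(rest, regexec(link_rx, rest, perl = TRUE))[[1]]
    ltxt <- lm[1]
    rest <- substr(rest, nchar(ltxt) + 1L, nchar(rest))
    if (!nzchar(rest)) {
      # trailing link: annotation on the reducing end is dropped at the
      # very end of the string, kept before a following branch/residue
      if (!at_string_end) {
        out <- c(out, paste0("(", normalize_link_content(ltxt, last_base),
                             ")"))
      }
      break
    }
    if (!nzchar(ltxt)) {
      # two residues glued together ("ManMan"): fully unknown linkage
      ltxt <- "-"
    }
    out <- c(out, paste0("(", normalize_link_content(ltxt, last_base), ")"))
  }
  paste0(paste(out, collapse = ""), suffix)
}

# convert parentheses used as branch groups into square brackets,
# innermost-last (repeat until stable)
#' @keywords internal
parens_to_brackets <- function(s) {
  link_like <-
    "^[abAB?]?[12?]?[-,]?[1-9?](?:/[1-9])*$|^[abAB?][12?]?[-,]?$"
  repeat {
    chars <- strsplit(s, "")[[1]]
    changed <- FALSE
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "(") {
        depth <- 0L
        j <- i
        while (j <= length(chars)) {
          if (chars[j] == "(") depth <- depth + 1L
          if (chars[j] == ")") {
            depth <- depth - 1L
            if (depth == 0L) break
          }
          j <- j + 1L
        }
        if (j > length(chars)) break
        content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        if (!grepl(link_like, content)) {
          chars[i] <- "["
          chars[j] <- "]"
          changed <- TRUE
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    s <- paste(chars, collapse = "")
    if (!changed) return(s)
  }
}

#' Normalize linkages and bracket usage
#'
#' Wraps every linkage as `(x n-m)`, filling missing anomers with `?` and
#' missing donor carbons with the residue-class default (C2 for sialic
#' acids, C1 otherwise); expands dashless forms (`Galb4Glc`); folds
#' CSDB-linear residue prefixes (`bDGalp(1-4)`); converts
#' parentheses-as-branches to square brackets.
#'
#' @param s A token-normalized glycan string.
#' @return The linkage-normalized string.
#' @export
normalize_linkages_and_brackets <- function(s) {
  # CSDB-linear: anomer+enantiomer prefixed residues with bare (n-m) links
  s <- gsub("(?<![A-Za-z0-9])([ab?])([DL])([A-Z][A-Za-z0-9]*?)p?\\((\\d)[-,](\\d)\\)",
            "\\2-\\3(\\1\\4-\\5)", s, perl = TRUE)
  s <- gsub("(?<![A-Za-z0-9])([ab?])([DL])([A-Z][A-Za-z0-9]*?)p?$",
            "\\2-\\3", s, perl = TRUE)
  # anomer written outside the parentheses: Galb(1-4) -> Gal(b1-4)
  s <- gsub("([ab?])\\(([12?])[-,]([1-9?])\\)", "(\\1\\2-\\3)", s,
            perl = TRUE)
  # linkage without anomer: (1-4) -> (?1-4)
  s <- gsub("\\(([12])[-,]([1-9?])\\)", "(?\\1-\\2)", s, perl = TRUE)
  s <- parens_to_brackets(s)

  # scan: chain segments between structural characters; parenthesized
  # content is linkage text normalized with the preceding residue as donor
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  seg <- character(0)
  last_base <- ""
  n <- length(chars)
  i <- 1L
  flush_seg <- function(at_end) {
    segtxt <- paste(seg, collapse = "")
    res <- process_segment(segtxt, at_end)
    tokm <- regmatches(res, gregexpr(paste0("(?:", base_alternation(), ")"),
                                     res, perl = TRUE))[[1]]
    if (length(tokm)) last_base <<- tokm[length(tokm)]
    res
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      out <- c(out, flush_seg(FALSE))
      seg <- character(0)
      j <- i
      depth <- 0L
      while (j <= n) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
      }
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      out <- c(out, "(", normalize_link_content(content, last_base), ")")
      i <- j + 1L
    } else if (ch %in% c("[", "]", "{", "}")) {
      out <- c(out, flush_seg(FALSE), ch)
      seg <- character(0)
      i <- i + 1L
    } else {
      seg <- c(seg, ch)
      i <- i + 1L
    }
  }
  out <- c(out, flush_seg(TRUE))
  s <- paste(out, collapse = "")
  check_balanced(s)
  s
}

#' Normalize modification dialects and floating substituents
#'
#' Positioned modifications are rendered token-internally as
#' `<pos><Tag>` (`[4S]Gal` to `Gal4S`); position-unknown variants
#' (`SGal`, `S-Gal`, `[S]Gal`, `Gal?S`) get the letter `O` before the tag
#' (`GalOS`). `main + residue` notations for uncertain substituents are
#' rewritten to curly-bracket floating prefixes.
#'
#' @param s A linkage-normalized glycan string.
#' @return The modification-normalized string.
#' @export
normalize_modifications_and_floating <- function(s) {
  tags <- tag_alternation()
  res_tok <- "((?:[DL]-)?[A-Za-z][A-Za-z0-9]*)"
  # [4S]Gal -> Gal4S ; [S]Gal -> GalOS
  s <- gsub(paste0("\\[([1-9])(", tags, ")\\]", res_tok), "\\3\\1\\2", s,
            perl = TRUE)
  s <- gsub(paste0("\\[(", tags, ")\\]", res_tok), "\\2O\\1", s,
            perl = TRUE)
  # 6SGal / SGal / S-Gal prefix styles (only at token-start positions)
  s <- gsub(paste0("(^|[\\[{)\\]])([1-9])(", tags,
                   ")-?((?:[DL]-)?[A-Z][a-z][A-Za-z0-9]*)"),
            "\\1\\4\\2\\3", s, perl = TRUE)
  s <- gsub(paste0("(^|[\\[{)\\]])(", tags,
                   ")-?((?:[DL]-)?[A-Z][a-z][A-Za-z0-9]*)"),
            "\\1\\3O\\2", s, perl = TRUE)
  s <- apply_rules(s, "modifications")

  # "Gal(b1-4)Glc + Neu5Ac": trailing '+' parts become floating prefixes
  if (grepl("+", s, fixed = TRUE) && !startsWith(s, "{")) {
    parts <- strsplit(s, "+", fixed = TRUE)[[1]]
    main <- parts[1]
    for (p in parts[-1]) {
      if (!nzchar(p)) next
      if (!endsWith(p, ")")) {
        root_tok <- regmatches(p, regexec("([A-Za-z0-9]+)$", p))[[1]][2]
        base <- tryCatch(parse_mono(root_tok)$base, error = function(e) "")
        lk <- paste0(default_anomer(base), default_donor(base), "-?")
        p <- paste0(p, "(", lk, ")")
      }
      main <- paste0("{", p, "}", main)
    }
    s <- main
  }
  s
}

# ---- chemical feasibility ---------------------------------------------------

#' @keywords internal
blocked_positions <- function(mono) {
  mod_pos <- vapply(mono$mods, function(m) as.integer(m$pos), integer(1))
  mod_pos <- mod_pos[!is.na(mod_pos)]
  if (!mono$known) return(sort(unique(mod_pos)))
  row <- mono_row(mono$base)
  ring <- mono$ring %||% row$ring
  blocked <- c(row$donor, if (ring == "f") 4L else 5L, mod_pos)
  if (row$sialic) blocked <- c(blocked, 1L, 2L, 3L, 5L)
  sort(unique(blocked))
}

#' @keywords internal
max_position <- function(mono) {
  if (!mono$known) return(9L)
  mono_row(mono$base)$carbons
}

#' Repair chemically impossible linkage assignments
#'
#' For each parent residue an occupancy map is built from its blocked
#' positions (anomeric carbon, ring-oxygen carbon, modification sites;
#' C1-C3 and C5 for sialic acids) plus positions claimed by earlier
#' siblings in reading order. Acceptor positions that violate the map are
#' replaced by `?` (narrow-ambiguity sets drop only their blocked
#' members). The function repairs, it never rejects.
#'
#' @param t A `glycan_tree`.
#' @return The repaired tree.
#' @export
enforce_chemical_feasibility <- function(t) {
  validate_tree(t)
  fix <- function(node) {
    kids <- t$children[[node]]
    parent_mono <- t$nodes[[node]]
    occ <- blocked_positions(parent_mono)
    maxp <- max_position(parent_mono)
    for (k in kids) {
      lk <- t$links[[k]]
      acc <- lk$acceptors
      if (!any(is.na(acc))) {
        feas <- setdiff(acc, occ)
        feas <- feas[feas <= maxp]
        if (!length(feas)) {
          lk$acceptors <- NA_integer_
        } else {
          lk$acceptors <- feas
          if (length(feas) == 1L) occ <- c(occ, feas)
        }
        t$links[[k]] <<- lk
      }
      fix(k)
    }
    invisible(NULL)
  }
  fix(t$root)
  t$floating <- lapply(t$floating, function(f) {
    f$tree <- enforce_chemical_feasibility(f$tree)
    f
  })
  t
}

#' Homogenize a raw IUPAC-like string into standard IUPAC-condensed
#'
#' Applies the normalization stages in order (tokens, linkages/brackets,
#' modifications/floating), parses to a tree, repairs chemical
#' impossibilities, and serializes back. Sibling order is preserved
#' verbatim -- branch canonicalization is a separate, later step.
#'
#' @param s A raw IUPAC-like glycan string.
#' @return A standardized IUPAC-condensed string.
#' @export
common_stem <- function(s) {
  s <- normalize_tokens(s)
  s <- normalize_linkages_and_brackets(s)
  s <- normalize_modifications_and_floating(s)
  # modification rewrites can expose dashless linkages; one more pass
  s <- normalize_tokens(s)
  s <- normalize_linkages_and_brackets(s)
  t <- tryCatch(parse_iupac_to_tree(s), error = function(e) {
    stop("after normalization ('", s, "'): ", conditionMessage(e),
         call. = FALSE)
  })
  unknown <- unique(unlist(lapply(all_monos(t), function(m) {
    if (!m$known) m$base else NULL
  })))
  if (length(unknown)) {
    stop("unknown monosaccharide token: '",
         paste(unknown, collapse = "', '"), "'", call. = FALSE)
  }
  t <- enforce_chemical_feasibility(t)
  tree_to_string(t)
}
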