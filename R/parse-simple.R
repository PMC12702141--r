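# Single-line foreign nomenclatures that map to IUPAC-condensed by
# token-level rewriting: LinearCode, GLYCAM, IUPAC-extended and
# GlycoWorkbench (GWS). All outputs are raw strings for the common stem.

#' @keywords internal
linearcode_map <- function() {
  c(GN = "GlcNAc", AN = "GalNAc", MN = "ManNAc", NN = "Neu5Ac",
    NJ = "Neu5Gc",
    A = "Gal", G = "Glc", M = "Man", F = "Fuc", H = "Rha", X = "Xyl",
    U = "GlcA", I = "IdoA", K = "Kdn")
}

#' Parse a LinearCode string into a raw IUPAC-like string
#'
#' Compact capital residue codes with inline anomer and acceptor position
#' (`Ab4GN;` = Gal(b1-4)GlcNAc); branches in parentheses become square
#' brackets; the donor carbon comes from the residue-class default (C2
#' for `NN`/`NJ`/`K`).
#'
#' @param s A LinearCode string, optional trailing `;`.
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_linearcode <- function(s) {
  s <- sub(";+$", "", gsub("[[:space:]]+", "", s))
  map <- linearcode_map()
  codes <- names(map)[order(-nchar(names(map)))]
  out <- character(0)
  rest <- s
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch == "(") { out <- c(out, "["); rest <- substr(rest, 2, nchar(rest)); next }
    if (ch == ")") { out <- c(out, "]"); rest <- substr(rest, 2, nchar(rest)); next }
    hit <- NULL
    for (cd in codes) {
      if (startsWith(rest, cd)) { hit <- cd; break }
    }
    if (is.null(hit)) unsupported_token(ch, "LinearCode")
    tok <- map[[hit]]
    rest <- substr(rest, nchar(hit) + 1L, nchar(rest))
    lm <- regmatches(rest, regexec("^([ab?])([1-9?])", rest))[[1]]
    if (length(lm)) {
      out <- c(out, paste0(tok, "(", lm[2], default_donor(tok), "-",
                           lm[3], ")"))
      rest <- substr(rest, nchar(lm[1]) + 1L, nchar(rest))
    } else {
      out <- c(out, tok)
    }
  }
  paste(out, collapse = "")
}

#' Parse a GLYCAM condensed string into a raw IUPAC-like string
#'
#' GLYCAM spells every residue with explicit enantiomer and ring letters
#' (`DGlcpNAcb1-4`) and terminates at an aglycon (`-OH`, `-OME`). Default
#' enantiomer/ring markers are dropped downstream by the common stem;
#' `-OME` is kept as a reducing-end methyl annotation, `-OH` is dropped.
#'
#' @param s A GLYCAM string.
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_glycam <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  m <- regmatches(s, regexec("-(OH|OME|OMe|OtBu)$", s))[[1]]
  if (!length(m)) {
    stop("GLYCAM string without -OH/-OME terminus: '", s, "'",
         call. = FALSE)
  }
  suffix <- switch(m[2], OH = "", OME = "-OMe", OMe = "-OMe",
                   OtBu = "-OtBu")
  s <- substr(s, 1, nchar(s) - nchar(m[1]))
  seg <- paste0("([DL])(Neup5Ac|Neup5Gc|Kdnp|[A-Z][a-z][a-z]?[pf]",
                "(?:NAc|NGc|NS|A|N)?(?:[1-9](?:S|P|Me|Ac))*)")
  # inner residues carry their linkage; the reducing-end residue ends bare
  s <- gsub(paste0(seg, "([ab?])([12?])-([1-9?])"),
            "\\1-\\2(\\3\\4-\\5)", s, perl = TRUE)
  s <- gsub(paste0(seg, "([ab?])([12?])-?(?=\\]|$)"), "\\1-\\2", s,
            perl = TRUE)
  if (grepl("[DL][A-Z][a-z]+[pf][ab][12]-", s)) {
    stop("unparseable GLYCAM residue near '", s, "'", call. = FALSE)
  }
  paste0(s, suffix)
}

#' Parse an IUPAC-extended string into a raw IUPAC-like string
#'
#' Full residue qualifications with Greek anomers and arrow linkages
#' (`β-D-Galp-(1→4)-D-Glcp`) are rewritten to condensed tokens; the
#' common stem then drops default enantiomer/ring markers.
#'
#' @param s An IUPAC-extended string.
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_iupac_extended <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  s <- gsub("α", "a", gsub("β", "b", s))
  s <- gsub("→", "-", gsub("->", "-", s, fixed = TRUE))
  # anomer-enantiomer-name-(d-d)- -> enantiomer-name(anomer d-d)
  s <- gsub("([ab?])-([DL])-([A-Za-z0-9]+?)-\\((\\d)-(\\d)\\)-?",
            "\\2-\\3(\\1\\4-\\5)", s, perl = TRUE)
  # reducing-end residue keeps its enantiomer prefix only
  s <- gsub("(^|\\]|\\))([ab?])-([DL])-", "\\1\\3-", s, perl = TRUE)
  s
}

#' Parse a GlycoWorkbench (GWS) string into a raw IUPAC-like string
#'
#' GWS chains residues from the reducing end (`freeEnd`/`redEnd`) as
#' `--<pos><anomer><carbon><enantiomer>-<Name>,<ring>` segments, with
#' branches in parentheses attached to the residue preceding the group
#' and an optional `$MONO...` settings suffix.
#'
#' @param s A GWS string.
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_gws <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  s <- sub("\\$.*$", "", s)
  s <- sub("^(freeEnd|redEnd)", "", s)
  seg_rx <- "^--([0-9?])([ab?])([12?])([DL?])-([A-Za-z0-9]+),([pf?])"
  tokens <- character(0)
  links <- data.frame(child = integer(0), parent = integer(0),
                      anomer = character(0), donor = integer(0),
                      acceptor = character(0), stringsAsFactors = FALSE)
  current <- NA_integer_
  stack <- integer(0)
  rest <- s
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch == "(") {
      stack <- c(stack, current)
      rest <- substr(rest, 2, nchar(rest))
      next
    }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced GWS branch", call. = FALSE)
      current <- stack[length(stack)]
      stack <- stack[-length(stack)]
      rest <- substr(rest, 2, nchar(rest))
      next
    }
    m <- regmatches(rest, regexec(seg_rx, rest))[[1]]
    if (!length(m)) {
      stop("malformed GWS residue segment near '",
           substr(rest, 1, 25), "'", call. = FALSE)
    }
    ent <- m[5]
    tok <- paste0(if (ent %in% c("D", "L")) paste0(ent, "-") else "",
                  m[6], if (m[7] == "f") "f" else "")
    tokens <- c(tokens, tok)
    idx <- length(tokens)
    if (!is.na(current)) {
      links <- rbind(links, data.frame(
        child = idx, parent = current, anomer = m[3],
        donor = if (m[4] %in% c("1", "2")) as.integer(m[4]) else
          NA_integer_,
        acceptor = m[2], stringsAsFactors = FALSE))
    }
    current <- idx
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }
  if (!length(tokens)) stop("empty GWS string", call. = FALSE)
  rlt_to_string(tokens, links)
}
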