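# Monosaccharide compositions: count multisets of residue classes without
# linkage structure, the common output of MS glycomics. All shorthand
# styles (single-letter H5N4F1A2, named Hex5HexNAc4Fuc1Neu5Ac2,
# parenthesized "(Hex)3 (HexNAc)1 ... + (Man)3(GlcNAc)2") map to one
# canonical Composition value.

# canonical class order used by composition_to_string()
#' @keywords internal
composition_classes <- function() {
  c("Hex", "HexNAc", "dHex", "Neu5Ac", "Neu5Gc", "Pen", "HexA", "Kdn",
    "S", "P", "Me", "Ac")
}

# named-token vocabulary -> class folding (Fuc == dHex, Man/Gal/Glc == Hex)
#' @keywords internal
composition_token_map <- function() {
  c(HexNAc = "HexNAc", GlcNAc = "HexNAc", GalNAc = "HexNAc",
    ManNAc = "HexNAc",
    Neu5Ac = "Neu5Ac", NeuAc = "Neu5Ac", NeuNAc = "Neu5Ac", NANA = "Neu5Ac",
    Neu5Gc = "Neu5Gc", NeuGc = "Neu5Gc",
    HexA = "HexA", GlcA = "HexA", GalA = "HexA", IdoA = "HexA",
    dHex = "dHex", Fuc = "dHex", Rha = "dHex", deoxyHex = "dHex",
    Hex = "Hex", Man = "Hex", Gal = "Hex", Glc = "Hex",
    Pen = "Pen", Xyl = "Pen", Ara = "Pen", Rib = "Pen",
    Kdn = "Kdn", KDN = "Kdn",
    Sul = "S", Sulf = "S", Su = "S", S = "S",
    Phos = "P", P = "P", Me = "Me", Ac = "Ac")
}

#' @keywords internal
single_letter_map <- function() {
  c(H = "Hex", N = "HexNAc", F = "dHex", A = "Neu5Ac", G = "Neu5Gc",
    S = "S", P = "P", X = "Pen", K = "Kdn")
}

#' Construct a composition
#'
#' @param counts Named integer vector over [composition_classes()];
#'   zero-count classes are dropped.
#' @return An object of class `glycan_composition`.
#' @export
glycan_composition <- function(counts) {
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), composition_classes())
  if (length(bad)) {
    stop("unknown composition class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(counts)) stop("empty composition", call. = FALSE)
  ord <- match(names(counts), composition_classes())
  counts <- as.integer(counts)[order(ord)]
  names(counts) <- composition_classes()[sort(ord)]
  structure(list(counts = counts), class = "glycan_composition")
}

#' @keywords internal
comp_add <- function(tab, cls, n) {
  tab[cls] <- (if (is.na(tab[cls])) 0L else tab[cls]) + n
  tab
}

#' Parse a monosaccharide composition
#'
#' Accepts single-letter style (`H5N4F1A2`), named style
#' (`Hex5HexNAc4Fuc1Neu5Ac2`), and parenthesized style
#' (`(Hex)3 (HexNAc)1 (NeuAc)1 + (Man)3(GlcNAc)2`); a `+` appendix is
#' summed in with Man folding to Hex and GlcNAc to HexNAc. In
#' single-letter strings that also contain H or N, `S` is read as sialic
#' acid (Neu5Ac); otherwise it counts as sulfate.
#'
#' @param s A composition string.
#' @return A `glycan_composition`.
#' @export
parse_composition <- function(s) {
  s0 <- s
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) stop("empty composition string", call. = FALSE)
  counts <- stats::setNames(integer(length(composition_classes())),
                            composition_classes())
  for (part in strsplit(s, "+", fixed = TRUE)[[1]]) {
    if (!nzchar(part)) next
    counts <- comp_parse_part(part, counts, s0)
  }
  glycan_composition(counts)
}

#' @keywords internal
comp_parse_part <- function(part, counts, original) {
  tokmap <- composition_token_map()
  toks <- names(tokmap)[order(-nchar(names(tokmap)))]
  lmap <- single_letter_map()
  rest <- part
  letters_seen <- character(0)
  sialic_context <- FALSE
  pending_S <- 0L
  while (nzchar(rest)) {
    # parenthesized token: (Hex)3
    m <- regmatches(rest, regexec("^\\(([A-Za-z0-9]+)\\)(\\d*)", rest))[[1]]
    if (length(m)) {
      cls <- tokmap[m[2]]
      if (is.na(cls)) {
        stop("unparseable composition near '", rest, "' in '", original,
             "'", call. = FALSE)
      }
      n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
      counts <- comp_add(counts, cls, n)
      rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
      next
    }
    # named token: Hex5, Neu5Ac2 (longest name first)
    hit <- FALSE
    for (tk in toks) {
      if (nchar(tk) < 2L) next
      if (startsWith(rest, tk)) {
        tail <- substr(rest, nchar(tk) + 1L, nchar(rest))
        nm <- regmatches(tail, regexec("^(\\d*)", tail))[[1]][1]
        n <- if (nzchar(nm)) as.integer(nm) else 1L
        counts <- comp_add(counts, tokmap[tk], n)
        rest <- substr(tail, nchar(nm) + 1L, nchar(tail))
        hit <- TRUE
        break
      }
    }
    if (hit) next
    # single letter + count
    m <- regmatches(rest, regexec("^([A-Z])(\\d+)", rest))[[1]]
    if (length(m) && m[2] %in% names(lmap)) {
      cls <- lmap[m[2]]
      n <- as.integer(m[3])
      letters_seen <- c(letters_seen, m[2])
      if (m[2] == "S") {
        pending_S <- pending_S + n  # resolved after the scan
      } else {
        counts <- comp_add(counts, cls, n)
      }
      rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
      next
    }
    stop("unparseable composition near '", rest, "' in '", original, "'",
         call. = FALSE)
  }
  if (pending_S > 0L) {
    # dialect collision: 'S' is sialic acid in H/N-letter strings
    # (H5N4S2), sulfate otherwise
    cls <- if (any(c("H", "N", "F") %in% letters_seen)) "Neu5Ac" else "S"
    counts <- comp_add(counts, cls, pending_S)
  }
  counts
}

#' Serialize a composition canonically
#'
#' Fixed class order Hex, HexNAc, dHex, Neu5Ac, Neu5Gc, Pen, HexA, Kdn,
#' S, P, Me, Ac; rendered as `<Class><count>` concatenated.
#'
#' @param c A `glycan_composition`.
#' @return Canonical composition string.
#' @export
composition_to_string <- function(c) {
  stopifnot(inherits(c, "glycan_composition"))
  if (!length(c$counts)) stop("empty composition", call. = FALSE)
  paste0(names(c$counts), c$counts, collapse = "")
}

#' Does a string look like a composition?
#'
#' True iff the string parses under the composition grammar, contains a
#' count digit, and has no linkage syntax (the line between sequences and
#' compositions is blurry; bare residue names count as sequences).
#'
#' @param s A string.
#' @return Logical.
#' @export
detect_composition <- function(s) {
  if (grepl("\\([ab?][12?]-", s) || grepl("[-{}]", s)) return(FALSE)
  if (!grepl("[0-9]", s)) return(FALSE)
  !inherits(tryCatch(parse_composition(s), error = function(e) e), "error")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", composition_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) composition_to_string(x)
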